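#' SVCC configuration
#'
#' Thresholds of the stage-1 candidate detection: \code{alpha} is the
#' member-count overlap above which a lower-ranked clique seed is discarded
#' during selection (strictly more than \code{alpha} shared proteins);
#' \code{beta} is the overlap ratio at or above which two overlapping
#' candidates are merged during filtration (below it the lower-ranked one is
#' discarded); \code{min_clique} is the smallest clique seed considered.
#'
#' @param alpha integer >= 1 (default 2).
#' @param beta overlap-ratio threshold in (0, 1] (default 0.8).
#' @param min_clique integer >= 3 (default 3).
#' @return validated list of class \code{svccConfig}.
#' @export
svccConfig <- function(alpha = 2L, beta = 0.8, min_clique = 3L) {
  stopifnot(alpha >= 1, beta > 0, beta <= 1, min_clique >= 3)
  structure(list(alpha = as.integer(alpha), beta = beta,
                 min_clique = as.integer(min_clique)),
            class = "svccConfig")
}

## run expr under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Sample random negative complexes
#'
#' For each positive complex, draws a node set of identical size uniformly
#' without replacement from the network: random node sets are overwhelmingly
#' unlikely to form dense, functionally coherent subgraphs, which makes them
#' the standard negative class for supervised complex prediction. A draw
#' that reproduces a positive member set exactly is rejected and redrawn, up
#' to \code{max_tries} attempts per complex.
#'
#' @param net igraph network to draw nodes from.
#' @param positives [ComplexSet-class] of real complexes.
#' @param seed integer seed (draws are reproducible).
#' @param max_tries redraw bound per complex (default 100).
#' @return [ComplexSet-class] of negatives, labelled \code{"negative"},
#'   sizes matching \code{positives} one for one.
#' @export
sampleNegatives <- function(net, positives, seed, max_tries = 100) {
  nodes <- igraph::V(net)$name
  sizes <- lengths(members(positives))
  if (length(sizes) && max(sizes) > length(nodes))
    stop("network smaller than the largest positive complex")
  poskeys <- canonicalKeys(positives)
  withSeed(seed, {
    draws <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      for (try in seq_len(max_tries)) {
        cand <- sort(sample(nodes, sizes[i]))
        if (!(paste(cand, collapse = "\t") %in% poskeys)) break
        if (try == max_tries)
          stop("could not draw a negative distinct from the positives")
      }
      draws[[i]] <- cand
    }
    ComplexSet(draws, label = rep("negative", length(draws)),
               provenance = "sampled negatives")
  })
}

#' Build the stage-1 training set
#'
#' One feature row per complex (positives then negatives), labels 1/0.
#'
#' @param positives,negatives [ComplexSet-class]; all members must be nodes
#'   of both networks and every complex must have >= 3 members.
#' @param unet,wnet unweighted and weighted igraph networks.
#' @return list of class \code{trainingSet} with \code{features} (n x 16
#'   matrix), \code{labels} (integer 0/1) and \code{complexes}.
#' @export
buildTrainingSet <- function(positives, negatives, unet, wnet) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes are required to build a training set")
  all_m <- c(members(positives), members(negatives))
  if (any(lengths(all_m) < 3))
    stop("training complexes must have at least 3 members")
  feats <- featureMatrix(all_m, unet, wnet)
  structure(list(
    features = feats,
    labels = rep(c(1L, 0L), c(length(positives), length(negatives))),
    complexes = all_m), class = "trainingSet")
}

#' Train the stage-1 subgraph scorer
#'
#' Fits a polynomial-kernel support vector classifier with probability
#' calibration on the 16-feature training matrix: cost C = 3, degree 4,
#' coef0 = 0, gamma = 1/(16 * Var(features)), tolerance 0.001. The
#' probability model is calibrated by internal cross-validation, so a seed
#' fixes the fit exactly.
#'
#' @param ts a \code{trainingSet} from [buildTrainingSet()].
#' @param seed integer seed (default 1).
#' @param cost,degree,coef0,tolerance SVC hyperparameters.
#' @return an [SVMSubgraphScorer-class].
#' @export
trainSubgraphScorer <- function(ts, seed = 1L, cost = 3, degree = 4,
                                coef0 = 0, tolerance = 0.001) {
  if (length(unique(ts$labels)) < 2L)
    stop("training set must contain both classes")
  x <- ts$features
  v <- popVar(as.numeric(x))
  gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  fit <- withSeed(seed, suppressWarnings(
    e1071::svm(x = x, y = factor(ts$labels, levels = c(0, 1)),
               kernel = "polynomial", degree = degree, cost = cost,
               coef0 = coef0, gamma = gamma, probability = TRUE,
               tolerance = tolerance, scale = FALSE)))
  new("SVMSubgraphScorer", model = fit,
      hyperparameters = list(cost = cost, kernel = "polynomial",
                             degree = degree, gamma = gamma, coef0 = coef0,
                             probability = TRUE, tolerance = tolerance),
      seed = as.integer(seed))
}

#' Score candidate subgraphs
#'
#' Probability that each subgraph is a genuine complex, in \code{[0, 1]}.
#'
#' @param scorer a [SubgraphScorer-class].
#' @param subs list of character member vectors.
#' @param unet,wnet unweighted and weighted networks (igraph or internal
#'   snapshot).
#' @return numeric vector parallel to \code{subs}.
#' @export
setGeneric("scoreSubgraphs",
           function(scorer, subs, unet, wnet) standardGeneric("scoreSubgraphs"))

#' @rdname scoreSubgraphs
#' @export
setMethod("scoreSubgraphs", "SVMSubgraphScorer",
  function(scorer, subs, unet, wnet) {
    if (!length(subs)) return(numeric(0))
    feats <- featureMatrix(subs, unet, wnet)
    pred <- predict(scorer@model, feats, probability = TRUE)
    pr <- attr(pred, "probabilities")
    unname(pr[, "1"])
  })

#' @rdname scoreSubgraphs
#' @export
setMethod("scoreSubgraphs", "FunctionScorer",
  function(scorer, subs, unet, wnet) {
    vapply(subs, function(m) scorer@fun(m, unet, wnet), 0)
  })

#' @rdname scoreSubgraphs
#' @param fun function \code{(members, unet, wnet) -> probability}.
#' @export
functionScorer <- function(fun) new("FunctionScorer", fun = fun)

## total order used everywhere candidates are ranked: probability desc,
## then larger size, then lexicographic canonical member tuple
rankOrder <- function(prob, mems) {
  keys <- vapply(mems, paste, "", collapse = "\t")
  order(-prob, -lengths(mems), keys)
}

#' Enumerate clique seeds
#'
#' All maximal cliques of the network with at least \code{min_clique}
#' nodes (Bron–Kerbosch via igraph), in a deterministic canonical order.
#'
#' @param net igraph network.
#' @param min_clique minimum clique size (default 3).
#' @return [ComplexSet-class] of clique seeds.
#' @export
enumerateInitialSubgraphs <- function(net, min_clique = 3) {
  if (igraph::vcount(net) == 0)
    return(ComplexSet(provenance = "maximal cliques"))
  cl <- igraph::max_cliques(net, min = min_clique)
  mems <- lapply(cl, function(v) sort(igraph::V(net)$name[as.integer(v)]))
  keys <- vapply(mems, paste, "", collapse = "\t")
  ComplexSet(mems[order(keys)], provenance = "maximal cliques")
}

#' Select seeds by member-count overlap
#'
#' Seeds are ranked by scorer probability (descending); scanning down the
#' ranking, a seed sharing strictly more than \code{alpha} members with any
#' already-kept seed is discarded.
#'
#' @param initial [ComplexSet-class] of seeds.
#' @param scorer [SubgraphScorer-class].
#' @param alpha member-count overlap threshold (default 2).
#' @param unet,wnet networks for feature extraction.
#' @return [ComplexSet-class] of surviving seeds with probabilities.
#' @export
selectSubgraphs <- function(initial, scorer, alpha = 2, unet, wnet) {
  n <- length(initial)
  if (!n) return(initial)
  mems <- members(initial)
  prob <- scoreSubgraphs(scorer, mems, unet, wnet)
  ord <- rankOrder(prob, mems)
  kept <- list(); kept_p <- numeric(0)
  for (i in ord) {
    cand <- mems[[i]]
    clash <- FALSE
    for (k in kept) {
      if (sum(cand %in% k) > alpha) { clash <- TRUE; break }
    }
    if (!clash) {
      kept[[length(kept) + 1L]] <- cand
      kept_p <- c(kept_p, prob[i])
    }
  }
  ComplexSet(kept, probability = kept_p, provenance = "selected seeds")
}

#' Greedy probability-guided expansion of one seed
#'
#' Repeatedly scores every external neighbor of the current subgraph added
#' to it; the neighbor giving the largest strictly positive probability
#' increase joins (lexicographic tie-break), until no neighbor improves the
#' score. Neighbors are taken from \code{net}'s topology; scoring sees both
#' networks through the 16 features.
#'
#' @param seed_members character vector of seed member names.
#' @param net igraph network providing the expansion topology.
#' @param scorer [SubgraphScorer-class].
#' @param unet,wnet networks for feature extraction.
#' @return list with \code{members} and final \code{probability}.
#' @export
expandSubgraph <- function(seed_members, net, scorer, unet, wnet) {
  ar <- asAdjRep(net)
  uar <- asAdjRep(unet)
  war <- asAdjRep(wnet)
  cur <- sort(seed_members)
  p_cur <- scoreSubgraphs(scorer, list(cur), uar, war)
  repeat {
    idx <- nodeIndices(ar, cur)
    nb <- unique(unlist(ar$adj[idx]))
    nb <- setdiff(ar$nodes[nb], cur)
    if (!length(nb)) break
    nb <- sort(nb)
    cands <- lapply(nb, function(v) sort(c(cur, v)))
    p <- scoreSubgraphs(scorer, cands, uar, war)
    best <- which.max(p)   # first max = lexicographically smallest neighbor
    if (p[best] > p_cur) {
      cur <- cands[[best]]
      p_cur <- p[best]
    } else break
  }
  list(members = cur, probability = p_cur)
}

#' Filter expanded candidates by overlap ratio
#'
#' Candidates are ranked by probability (descending). The top candidate is
#' compared with every lower-ranked one sharing members: those with overlap
#' ratio at or above \code{beta} are merged into it (union of members,
#' rescored, re-ranked), those overlapping below \code{beta} are discarded;
#' disjoint candidates are untouched. The scan repeats until the ranking is
#' exhausted, so exact duplicates collapse and every surviving pair of
#' candidates either is disjoint or was deliberately kept apart.
#'
#' @param cands [ComplexSet-class] of expanded candidates.
#' @param scorer [SubgraphScorer-class].
#' @param beta overlap-ratio merge threshold (default 0.8).
#' @param unet,wnet networks for feature extraction.
#' @return [ComplexSet-class] of final stage-1 candidates.
#' @export
filterCandidates <- function(cands, scorer, beta = 0.8, unet, wnet) {
  n <- length(cands)
  if (!n) return(cands)
  uar <- asAdjRep(unet)
  war <- asAdjRep(wnet)
  mems <- members(cands)
  prob <- probabilities(cands)
  if (anyNA(prob)) prob <- scoreSubgraphs(scorer, mems, uar, war)
  ord <- rankOrder(prob, mems)
  pend_m <- mems[ord]
  pend_p <- prob[ord]
  kept_m <- list(); kept_p <- numeric(0)
  while (length(pend_m)) {
    cur <- pend_m[[1]]; curp <- pend_p[1]
    pend_m <- pend_m[-1]; pend_p <- pend_p[-1]
    if (length(pend_m)) {
      ov <- vapply(pend_m, function(m)
        length(intersect(cur, m)) / length(union(cur, m)), 0)
      mergers <- ov >= beta
      drops <- ov > 0 & ov < beta
      if (any(mergers)) {
        merged <- sort(unique(c(cur, unlist(pend_m[mergers]))))
        pend_m <- pend_m[!(mergers | drops)]
        pend_p <- pend_p[!(mergers | drops)]
        if (identical(merged, cur)) {
          kept_m[[length(kept_m) + 1L]] <- cur
          kept_p <- c(kept_p, curp)
        } else {
          mp <- scoreSubgraphs(scorer, list(merged), uar, war)
          ins <- rankOrder(c(pend_p, mp), c(pend_m, list(merged)))
          pend_m <- c(pend_m, list(merged))[ins]
          pend_p <- c(pend_p, mp)[ins]
        }
        next
      }
      pend_m <- pend_m[!drops]
      pend_p <- pend_p[!drops]
    }
    kept_m[[length(kept_m) + 1L]] <- cur
    kept_p <- c(kept_p, curp)
  }
  ComplexSet(kept_m, probability = kept_p, provenance = "SVCC candidates")
}

#' Run the full stage-1 SVCC pipeline
#'
#' Maximal-clique seeding, overlap selection, greedy probability-guided
#' expansion and overlap-ratio filtration, in that order. Every returned
#' candidate has at least \code{min_clique} members and carries its scorer
#' probability.
#'
#' @param net igraph network used for clique seeding and expansion topology
#'   (typically the confidence-filtered weighted network).
#' @param unet,wnet unweighted and weighted networks for feature extraction.
#' @param scorer trained [SubgraphScorer-class].
#' @param cfg an [svccConfig()].
#' @return [ComplexSet-class] of stage-1 candidate complexes.
#' @export
runSVCC <- function(net, unet, wnet, scorer, cfg = svccConfig()) {
  seeds <- enumerateInitialSubgraphs(net, cfg$min_clique)
  if (!length(seeds)) return(ComplexSet(provenance = "SVCC candidates"))
  sel <- selectSubgraphs(seeds, scorer, cfg$alpha, unet, wnet)
  uar <- asAdjRep(unet)
  war <- asAdjRep(wnet)
  exp_m <- vector("list", length(sel))
  exp_p <- numeric(length(sel))
  for (i in seq_len(length(sel))) {
    ex <- expandSubgraph(members(sel, i), net, scorer, uar, war)
    exp_m[[i]] <- ex$members
    exp_p[i] <- ex$probability
  }
  expanded <- ComplexSet(exp_m, probability = exp_p)
  filterCandidates(expanded, scorer, cfg$beta, uar, war)
}
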