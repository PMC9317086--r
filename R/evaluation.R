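#' Overlap ratio and neighborhood affinity between two complexes
#'
#' \code{overlapRatio} is the Jaccard overlap
#' \eqn{|C_i \cap C_k| / |C_i \cup C_k|}. \code{neighborhoodAffinity} is
#' \eqn{NA(b,p) = |V_b \cap V_p|^2 / (|V_b| \cdot |V_p|)}; a predicted and
#' a reference complex are conventionally considered matched when
#' \eqn{NA > 0.25}.
#'
#' @param c1,c2 non-empty character vectors of member ids (or single
#'   complexes extracted with [members()]).
#' @return numeric in \code{[0, 1]}.
#' @examples
#' neighborhoodAffinity(c("a","b","c","d"), c("a","b","x"))  # 4/12
#' @export
overlapRatio <- function(c1, c2) {
  if (!length(c1) || !length(c2)) stop("complexes must be non-empty")
  length(intersect(c1, c2)) / length(union(c1, c2))
}

#' @rdname overlapRatio
#' @export
neighborhoodAffinity <- function(c1, c2) {
  if (!length(c1) || !length(c2)) stop("complexes must be non-empty")
  length(intersect(c1, c2))^2 / (length(c1) * length(c2))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall numerics in \code{[0, 1]}.
#' @return the F-score; 0 when both inputs are 0.
#' @examples
#' fScore(0.7684, 0.4330)  # 0.5539 to 4 decimals
#' @export
fScore <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Match predicted complexes against a reference catalog
#'
#' A predicted complex counts towards precision when its neighborhood
#' affinity with at least one reference complex exceeds
#' \code{na_threshold}; a reference complex counts towards recall when at
#' least one prediction matches it. \code{Ncp} and \code{Ncb} are those two
#' counts; precision is \code{Ncp/|P|}, recall \code{Ncb/|B|} and the
#' F-score their harmonic mean.
#'
#' @param predicted [ComplexSet-class] P (may be empty: precision 0).
#' @param reference non-empty [ComplexSet-class] B.
#' @param na_threshold match threshold on neighborhood affinity, strict
#'   (default 0.25).
#' @return list with \code{n_predicted}, \code{n_reference}, \code{Ncp},
#'   \code{Ncb}, \code{precision}, \code{recall}, \code{fscore}.
#' @export
evaluateComplexes <- function(predicted, reference, na_threshold = 0.25) {
  if (!length(reference)) stop("reference set must be non-empty")
  P <- members(predicted)
  B <- members(reference)
  matched_p <- logical(length(P))
  matched_b <- logical(length(B))
  for (i in seq_along(P)) {
    for (j in seq_along(B)) {
      if (neighborhoodAffinity(B[[j]], P[[i]]) > na_threshold) {
        matched_p[i] <- TRUE
        matched_b[j] <- TRUE
      }
    }
  }
  Ncp <- sum(matched_p)
  Ncb <- sum(matched_b)
  precision <- if (length(P)) Ncp / length(P) else 0
  recall <- Ncb / length(B)
  list(n_predicted = length(P), n_reference = length(B),
       Ncp = Ncp, Ncb = Ncb,
       precision = precision, recall = recall,
       fscore = fScore(precision, recall))
}

#' Hypergeometric enrichment p-value of a complex for one GO term
#'
#' Probability of observing at least \code{k} members annotated by the term
#' when \code{|C|} proteins are drawn at random from a universe of
#' \code{|V|} proteins of which \code{|F|} carry the term:
#' \deqn{P = 1 - \sum_{i=0}^{k-1}
#'   \binom{|F|}{i}\binom{|V|-|F|}{|C|-i} / \binom{|V|}{|C|}.}
#' Computed as the explicit finite sum. \code{k = 0} returns 1 by
#' convention (no annotated member, nothing to enrich).
#'
#' @param cx character vector of complex members.
#' @param ann an [AnnotationIndex-class].
#' @param term GO term id.
#' @param universe_size number of proteins in the species universe
#'   (typically the network's node count); must be >= \code{length(cx)}.
#' @return p-value in \code{[0, 1]}.
#' @export
enrichmentPvalue <- function(cx, ann, term, universe_size) {
  csize <- length(unique(cx))
  if (universe_size < csize) stop("universe smaller than the complex")
  annotated <- ann@termProteins[[term]]
  F <- length(annotated)
  k <- sum(unique(cx) %in% annotated)
  hyperUpperTail(k, F, universe_size, csize)
}

## P(X >= k) for X ~ Hypergeom(|V|, |F|, |C|), as the paper's finite sum
hyperUpperTail <- function(k, F, V, C) {
  if (k == 0L) return(1)
  i <- 0:(k - 1)
  p <- 1 - sum(choose(F, i) * choose(V - F, C - i)) / choose(V, C)
  min(max(p, 0), 1)
}

#' Best-enriched GO term of a complex, per ontology aspect
#'
#' Scans every term annotating at least one member and reports, for each of
#' BP, CC and MF, the term with the smallest hypergeometric p-value (ties
#' broken by term id). Aspects with no annotated term report p = 1 and no
#' term.
#'
#' @inheritParams enrichmentPvalue
#' @param universe_size defaults to the number of annotated proteins when
#'   NULL; pass the network node count for the usual universe.
#' @return data.frame with one row per aspect: \code{aspect}, \code{term},
#'   \code{p_value}, \code{k} (annotated members).
#' @export
bestEnrichment <- function(cx, ann, universe_size = NULL) {
  if (is.null(universe_size)) universe_size <- length(ann@proteinTerms)
  cx <- unique(cx)
  terms <- unique(unlist(ann@proteinTerms[intersect(cx, names(ann@proteinTerms))]))
  out <- data.frame(aspect = c("BP", "CC", "MF"),
                    term = NA_character_, p_value = 1, k = 0L,
                    stringsAsFactors = FALSE)
  if (length(terms)) {
    terms <- sort(terms)
    pv <- vapply(terms, function(t)
      enrichmentPvalue(cx, ann, t, universe_size), 0)
    kk <- vapply(terms, function(t)
      sum(cx %in% ann@termProteins[[t]]), 0L)
    asp <- ann@termAspect[terms]
    for (a in c("BP", "CC", "MF")) {
      sel <- which(asp == a)
      if (length(sel)) {
        best <- sel[which.min(pv[sel])]
        out[out$aspect == a, c("term", "p_value", "k")] <-
          list(terms[best], pv[best], kk[best])
      }
    }
  }
  out
}

#' Enrichment report for a set of complexes
#'
#' @param cs [ComplexSet-class] of predictions.
#' @param ann [AnnotationIndex-class].
#' @param universe_size see [bestEnrichment()].
#' @return data.frame with columns complex (index), members, aspect, term,
#'   p_value, k.
#' @export
enrichmentReport <- function(cs, ann, universe_size = NULL) {
  rows <- lapply(seq_len(length(cs)), function(i) {
    b <- bestEnrichment(members(cs, i), ann, universe_size)
    cbind(complex = i,
          members = paste(members(cs, i), collapse = " "), b,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cross-validation configuration
#'
#' @param folds number of folds (default 5).
#' @param train_overlap predictions overlapping a training complex at or
#'   above this ratio are discarded per fold (default 0.9).
#' @param merge_overlap after pooling folds, a lower-ranked prediction
#'   overlapping a kept one strictly above this ratio is removed
#'   (default 0.6).
#' @param na_threshold match threshold for evaluation (default 0.25).
#' @return validated list of class \code{cvConfig}.
#' @export
cvConfig <- function(folds = 5L, train_overlap = 0.9, merge_overlap = 0.6,
                     na_threshold = 0.25) {
  stopifnot(folds >= 2, train_overlap > 0, train_overlap <= 1,
            merge_overlap > 0, merge_overlap <= 1,
            na_threshold > 0, na_threshold <= 1)
  structure(list(folds = as.integer(folds), train_overlap = train_overlap,
                 merge_overlap = merge_overlap, na_threshold = na_threshold),
            class = "cvConfig")
}

## ranked-scan deduplication: keep higher-probability complexes, drop any
## later one overlapping a kept one strictly above `threshold`; exact
## duplicates always collapse, whatever the threshold
dedupeByOverlap <- function(cs, threshold) {
  n <- length(cs)
  if (n < 2) return(cs)
  mems <- members(cs)
  prob <- probabilities(cs)
  prob[is.na(prob)] <- 0
  ord <- rankOrder(prob, mems)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      ov <- overlapRatio(mems[[i]], mems[[k]])
      if (ov > threshold || ov == 1) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  cs[sort(kept)]
}

#' Five-fold cross-validated prediction and evaluation
#'
#' Shuffles the reference catalog into \code{cfg$folds} folds. For each
#' fold, both stages are trained on the remaining folds (with freshly
#' sampled size-matched negatives), the full pipeline predicts complexes on
#' the network, and predictions overlapping any training complex at ratio
#' \code{>= cfg$train_overlap} are discarded, so every retained prediction
#' is tested out of its training sample. The per-fold survivors are pooled,
#' deduplicated by ranked overlap scan (strictly \code{> cfg$merge_overlap}
#' removes the lower-scoring one), and the survivors are evaluated against
#' the full catalog. The node embedding is trained once and shared across
#' folds: it uses no complex labels, only the network.
#'
#' @param net igraph network for seeding/expansion (weighted-filtered).
#' @param unet,wnet unweighted and weighted networks for features.
#' @param standard reference [ComplexSet-class] (>= folds complexes).
#' @param cfg a [cvConfig()].
#' @param svcc_cfg an [svccConfig()].
#' @param walk_cfg a [walkConfig()]; its seed is overridden by \code{seed}.
#' @param seed master seed; all per-fold randomness derives from it.
#' @return list with \code{predictions} (final [ComplexSet-class]) and
#'   \code{eval} (see [evaluateComplexes()]).
#' @export
crossValidate <- function(net, unet, wnet, standard, cfg = cvConfig(),
                          svcc_cfg = svccConfig(), walk_cfg = walkConfig(),
                          seed = 1L) {
  n <- length(standard)
  if (n < cfg$folds) stop("need at least as many complexes as folds")
  walk_cfg$seed <- saltSeed(seed, "embedding")
  emb <- embedNodes(generateWalks(net, walk_cfg), walk_cfg)

  fold_of <- withSeed(saltSeed(seed, "folds"),
                      sample(rep_len(seq_len(cfg$folds), n)))
  pooled <- NULL
  for (f in seq_len(cfg$folds)) {
    train <- standard[which(fold_of != f)]
    if (!length(train)) stop("degenerate fold: empty training set")
    negs <- sampleNegatives(net, train, saltSeed(seed, paste0("neg", f)))
    ts <- buildTrainingSet(train, negs, unet, wnet)
    scorer <- trainSubgraphScorer(ts, seed = saltSeed(seed, paste0("svm", f)))
    cands <- runSVCC(net, unet, wnet, scorer, svcc_cfg)
    clf <- trainComplexClassifier(train, negs, emb,
                                  seed = saltSeed(seed, paste0("rf", f)))
    preds <- classifyCandidates(cands, clf, emb)
    if (length(preds)) {
      train_m <- members(train)
      keep <- vapply(members(preds), function(m)
        all(vapply(train_m, function(t)
          overlapRatio(m, t) < cfg$train_overlap, TRUE)), TRUE)
      preds <- preds[keep]
    }
    pooled <- if (is.null(pooled)) preds else c(pooled, preds)
  }
  final <- dedupeByOverlap(pooled, cfg$merge_overlap)
  list(predictions = final,
       eval = evaluateComplexes(final, standard, cfg$na_threshold))
}
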