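#' Random-walk embedding configuration
#'
#' Hyperparameters of the biased second-order random walks and the skip-gram
#' training that turns the walk corpus into node vectors. The return
#' parameter \code{p} controls how strongly a walk avoids revisiting the
#' node it just came from (large \code{p} = depth-first-like exploration);
#' \code{q} trades off inward versus outward moves. The defaults
#' (\code{p = 8}, \code{q = 1}, 10 walks of length 80 per node, 64
#' dimensions) are the settings used throughout this package's pipeline.
#'
#' @param p return parameter > 0 (default 8).
#' @param q in-out parameter > 0 (default 1).
#' @param walk_length steps per walk (default 80).
#' @param num_walks walks per node (default 10).
#' @param dimensions embedding dimension (default 64).
#' @param window skip-gram context window (default 10).
#' @param epochs training passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param use_weights bias walk steps by edge weight (default FALSE:
#'   unweighted topology).
#' @param seed integer seed.
#' @return validated list of class \code{walkConfig}.
#' @export
walkConfig <- function(p = 8, q = 1, walk_length = 80, num_walks = 10,
                       dimensions = 64, window = 10, epochs = 5,
                       negative = 5, use_weights = FALSE, seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 2, num_walks >= 1, dimensions >= 1,
            window >= 1, epochs >= 1, negative >= 0)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 num_walks = as.integer(num_walks),
                 dimensions = as.integer(dimensions),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative),
                 use_weights = isTRUE(use_weights),
                 seed = as.integer(seed)),
            class = "walkConfig")
}

#' Generate biased second-order random walks
#'
#' Starts \code{num_walks} walks from every node. The first step is
#' proportional to edge weight (uniform when unweighted); later steps from
#' node \eqn{c} arrived at from \eqn{t} weight each neighbor \eqn{x} by
#' \eqn{1/p} if \eqn{x = t}, 1 if \eqn{x} is also a neighbor of \eqn{t},
#' and \eqn{1/q} otherwise. Walks stop early at dead ends; an isolated node
#' yields walks of length 1.
#'
#' @param net igraph network.
#' @param cfg a [walkConfig()].
#' @return list of character vectors (node-name sequences).
#' @export
generateWalks <- function(net, cfg = walkConfig()) {
  ar <- asAdjRep(net)
  n <- length(ar$nodes)
  if (n == 0) stop("cannot walk an empty network")
  adj <- ar$adj
  wts <- if (cfg$use_weights) ar$w else lapply(adj, function(a) rep(1, length(a)))
  inv_p <- 1 / cfg$p
  inv_q <- 1 / cfg$q
  walks <- vector("list", n * cfg$num_walks)
  k <- 0L
  withSeed(saltSeed(cfg$seed, "walks"), {
    for (r in seq_len(cfg$num_walks)) {
      for (v in seq_len(n)) {
        walk <- integer(cfg$walk_length)
        walk[1] <- v
        len <- 1L
        if (length(adj[[v]])) {
          nb <- adj[[v]]
          cur <- if (length(nb) == 1L) nb else
            sample(nb, 1L, prob = wts[[v]])
          walk[2] <- cur
          len <- 2L
          prev <- v
          while (len < cfg$walk_length) {
            nb <- adj[[cur]]
            if (!length(nb)) break
            bias <- ifelse(nb == prev, inv_p,
                           ifelse(nb %in% adj[[prev]], 1, inv_q))
            pr <- wts[[cur]] * bias
            nxt <- if (length(nb) == 1L) nb else sample(nb, 1L, prob = pr)
            len <- len + 1L
            walk[len] <- nxt
            prev <- cur
            cur <- nxt
          }
        }
        k <- k + 1L
        walks[[k]] <- ar$nodes[walk[seq_len(len)]]
      }
    }
  })
  walks
}

#' Learn node vectors from a walk corpus
#'
#' Skip-gram with negative sampling over the walks, single-threaded and
#' seeded, so identical input reproduces the embedding exactly. Every node
#' appearing in the corpus receives one vector of length
#' \code{cfg$dimensions}.
#'
#' @param walks list of character node sequences from [generateWalks()].
#' @param cfg a [walkConfig()].
#' @param learning_rate initial learning rate (default 0.025).
#' @return numeric matrix, one named row per node.
#' @export
embedNodes <- function(walks, cfg = walkConfig(), learning_rate = 0.025) {
  if (!length(walks) || !sum(lengths(walks)))
    stop("empty walk corpus")
  vocab <- sort(unique(unlist(walks)))
  iwalks <- lapply(walks, function(w) match(w, vocab) - 1L)
  emb <- .sgnsTrain(iwalks, length(vocab), cfg$dimensions, cfg$window,
                    cfg$epochs, cfg$negative, learning_rate,
                    saltSeed(cfg$seed, "sgns"))
  rownames(emb) <- vocab
  emb
}

#' Average member vectors into a complex vector
#'
#' The vector of a complex is the coordinate-wise arithmetic mean of its
#' members' node vectors.
#'
#' @param mems character vector of member node names.
#' @param emb embedding matrix from [embedNodes()].
#' @return numeric vector of length \code{ncol(emb)}.
#' @export
complexVector <- function(mems, emb) {
  miss <- setdiff(mems, rownames(emb))
  if (length(miss))
    stop("members without an embedding vector: ",
         paste(utils::head(miss, 3), collapse = ", "))
  v <- emb[mems, , drop = FALSE]
  colMeans(v)
}

complexVectorMatrix <- function(cs, emb) {
  mems <- members(cs)
  out <- matrix(0, nrow = length(mems), ncol = ncol(emb))
  for (i in seq_along(mems)) out[i, ] <- complexVector(mems[[i]], emb)
  colnames(out) <- paste0("e", seq_len(ncol(emb)))
  out
}

#' Train the stage-2 complex classifier
#'
#' Random forest (1000 trees) on the averaged embedding vectors of positive
#' (real) and negative (random) complexes.
#'
#' @param positives,negatives [ComplexSet-class] training sets.
#' @param emb embedding matrix from [embedNodes()].
#' @param seed integer seed (default 1).
#' @param ntree number of trees (default 1000).
#' @param threshold decision threshold on the positive-class probability
#'   (default 0.5).
#' @return a [ComplexClassifier-class].
#' @export
trainComplexClassifier <- function(positives, negatives, emb, seed = 1L,
                                   ntree = 1000, threshold = 0.5) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes are required to train the classifier")
  x <- rbind(complexVectorMatrix(positives, emb),
             complexVectorMatrix(negatives, emb))
  y <- factor(rep(c(1L, 0L), c(length(positives), length(negatives))),
              levels = c(0, 1))
  fit <- withSeed(saltSeed(seed, "rf"),
                  randomForest::randomForest(x = x, y = y, ntree = ntree))
  new("ComplexClassifier", forest = fit, threshold = threshold,
      seed = as.integer(seed))
}

#' Classify stage-1 candidates
#'
#' Scores each candidate with the stage-2 random forest and keeps those
#' whose positive-class probability exceeds the classifier's threshold;
#' kept candidates carry that probability.
#'
#' @param cands [ComplexSet-class] of stage-1 candidates.
#' @param clf a [ComplexClassifier-class].
#' @param emb embedding matrix covering every candidate member.
#' @return [ComplexSet-class] of final predictions (subset of \code{cands}).
#' @export
classifyCandidates <- function(cands, clf, emb) {
  if (!length(cands))
    return(ComplexSet(provenance = "final predictions"))
  x <- complexVectorMatrix(cands, emb)
  pr <- predict(clf@forest, x, type = "prob")[, "1"]
  keep <- pr > clf@threshold
  ComplexSet(members(cands)[keep], probability = unname(pr[keep]),
             provenance = "final predictions")
}
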