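## Internal light-weight graph representation used by the scoring loops.
## Feature extraction is called thousands of times during subgraph expansion;
## going through igraph for every candidate is dominated by call overhead, so
## the hot paths work on a plain adjacency-list snapshot taken once per run.

## adjRep: list(nodes, index (env name->int), adj (list of int vectors),
##              w (list of numeric parallel to adj))
asAdjRep <- function(net) {
  if (inherits(net, "adjRep")) return(net)
  stopifnot(inherits(net, "igraph"))
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep(1, nrow(el))
  n <- length(nodes)
  adj <- vector("list", n)
  ww <- vector("list", n)
  if (nrow(el)) {
    ## build adjacency by accumulating both directions
    from <- c(el[, 1], el[, 2])
    to <- c(el[, 2], el[, 1])
    wts <- c(w, w)
    ord <- order(from, to)
    from <- from[ord]; to <- to[ord]; wts <- wts[ord]
    runs <- rle(from)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      v <- runs$values[k]
      adj[[v]] <- to[starts[k]:ends[k]]
      ww[[v]] <- wts[starts[k]:ends[k]]
    }
  }
  for (k in seq_len(n)) {
    if (is.null(adj[[k]])) { adj[[k]] <- integer(0); ww[[k]] <- numeric(0) }
  }
  idx <- new.env(parent = emptyenv())
  for (k in seq_len(n)) assign(nodes[k], k, envir = idx)
  structure(list(nodes = nodes, index = idx, adj = adj, w = ww),
            class = "adjRep")
}

nodeIndices <- function(rep, ids) {
  out <- integer(length(ids))
  for (k in seq_along(ids)) {
    v <- get0(ids[k], envir = rep$index, inherits = FALSE)
    if (is.null(v)) stop("unknown node: ", ids[k])
    out[k] <- v
  }
  out
}

## deterministic per-stage seed fan-out: one user seed, salted by stage name,
## kept below 2^31
saltSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
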