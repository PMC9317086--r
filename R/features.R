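#' The sixteen-feature topological description of a candidate subgraph
#'
#' A candidate complex is described by 16 statistics of its induced subgraph
#' in the unweighted and the weighted network:
#' \itemize{
#'   \item unweighted (5): density, max/mean/median degree, population
#'     variance of the node clustering coefficient;
#'   \item weighted (9): weighted density, max/mean/median weighted degree,
#'     mean and population variance of internal edge weights, modularity,
#'     mean and max of the weighted clustering coefficient;
#'   \item degree-related (2): mean and population variance across nodes of
#'     the average degree of each node's neighbors.
#' }
#' All statistics except modularity are computed on the induced subgraph;
#' modularity is the one feature that sees the host network, since it
#' compares internal edge weight against the weight crossing the boundary.
#' Degenerate cases (too few nodes, isolated nodes, zero weighted degree)
#' contribute 0, so vectors never contain NaN.
#'
#' @name features
NULL

#' @rdname features
#' @export
featureNames <- function() {
  c("density_u", "degree_max_u", "degree_avg_u", "degree_med_u",
    "clustcoef_var_u",
    "density_w", "degree_max_w", "degree_avg_w", "degree_med_w",
    "edgeweight_mean", "edgeweight_var", "modularity", "ccw_mean", "ccw_max",
    "avg_nbr_degree_mean", "avg_nbr_degree_var")
}

popVar <- function(x) {
  n <- length(x)
  if (n < 1L) return(0)
  m <- sum(x) / n
  sum((x - m)^2) / n
}

## induced subgraph of an adjRep restricted to member indices `idx`
## returns list(nbr = list of positions 1..n within sub, w = parallel weights)
inducedRep <- function(ar, idx) {
  n <- length(idx)
  pos <- integer(length(ar$nodes))
  pos[idx] <- seq_len(n)
  inside <- logical(length(ar$nodes))
  inside[idx] <- TRUE
  nbr <- vector("list", n)
  w <- vector("list", n)
  for (k in seq_len(n)) {
    a <- ar$adj[[idx[k]]]
    keep <- inside[a]
    nbr[[k]] <- pos[a[keep]]
    w[[k]] <- ar$w[[idx[k]]][keep]
  }
  list(nbr = nbr, w = w)
}

#' Weighted density of a node set
#'
#' Sum of edge weights over ordered node pairs of the induced subgraph (each
#' internal edge counted in both directions) divided by \eqn{|V|(|V|-1)}, so
#' a clique of unit-weight edges has density exactly 1. Returns 0 for fewer
#' than 2 nodes.
#'
#' @param sub character vector of member node names.
#' @param wnet weighted igraph graph (unit weights assumed if absent).
#' @export
weightedDensity <- function(sub, wnet) {
  ar <- asAdjRep(wnet)
  idx <- nodeIndices(ar, sub)
  n <- length(idx)
  if (n < 2L) return(0)
  ind <- inducedRep(ar, idx)
  sum(unlist(ind$w)) / (n * (n - 1))
}

#' Subgraph modularity
#'
#' \eqn{d_{in} / (d_{in} + d_{out})}: the total weight of internal edges
#' (each once) over internal plus boundary weight, measuring how
#' self-contained the subgraph is within its host network. 0 when the
#' subgraph touches no edges at all.
#'
#' @inheritParams weightedDensity
#' @export
subgraphModularity <- function(sub, wnet) {
  ar <- asAdjRep(wnet)
  idx <- nodeIndices(ar, sub)
  inside <- logical(length(ar$nodes))
  inside[idx] <- TRUE
  d_in2 <- 0; d_out <- 0
  for (i in idx) {
    a <- ar$adj[[i]]; w <- ar$w[[i]]
    isin <- inside[a]
    d_in2 <- d_in2 + sum(w[isin])   # internal edges counted twice
    d_out <- d_out + sum(w[!isin])
  }
  d_in <- d_in2 / 2
  if (d_in + d_out == 0) 0 else d_in / (d_in + d_out)
}

#' Node clustering coefficients
#'
#' \code{clusteringCoef} is the unweighted coefficient
#' \eqn{2T(v)/(k(k-1))} with \eqn{T(v)} the number of triangles through
#' \eqn{v}; \code{weightedClusteringCoef} sums \eqn{w(v,j)+w(v,h)} over
#' adjacent neighbor pairs \eqn{(j,h)} (pairs closing a triangle with
#' \eqn{v}, each unordered pair once) and divides by \eqn{w(v)(k_v-1)},
#' where \eqn{w(v)} is the weighted degree. Both return 0 for degree < 2
#' (or zero weighted degree).
#'
#' @param v node name.
#' @param net igraph graph (the subgraph of interest, already induced).
#' @export
clusteringCoef <- function(v, net) {
  ar <- asAdjRep(net)
  i <- nodeIndices(ar, v)
  ccuIdx(ar$adj, i)
}

#' @rdname clusteringCoef
#' @export
weightedClusteringCoef <- function(v, net) {
  ar <- asAdjRep(net)
  i <- nodeIndices(ar, v)
  ccwIdx(ar$adj, ar$w, i)
}

ccuIdx <- function(adj, i) {
  nb <- adj[[i]]
  k <- length(nb)
  if (k < 2L) return(0)
  tri <- 0L
  for (a in seq_len(k - 1L)) {
    tri <- tri + sum(adj[[nb[a]]] %in% nb[(a + 1L):k])
  }
  2 * tri / (k * (k - 1))
}

ccwIdx <- function(adj, wl, i) {
  nb <- adj[[i]]
  w <- wl[[i]]
  k <- length(nb)
  wv <- sum(w)
  if (k < 2L || wv == 0) return(0)
  s <- 0
  for (a in seq_len(k - 1L)) {
    closing <- nb[(a + 1L):k] %in% adj[[nb[a]]]
    if (any(closing))
      s <- s + sum(w[a] + w[(a + 1L):k][closing])
  }
  s / (wv * (k - 1))
}

#' @rdname features
#' @param sub character vector of member node names (size >= 2).
#' @param unet unweighted igraph graph (or its internal snapshot).
#' @param wnet weighted igraph graph (or its internal snapshot).
#' @return named numeric vector of length 16, order fixed as
#'   \code{featureNames()}.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' wtri <- tri; igraph::E(wtri)$weight <- 1
#' extractFeatures(c("a", "b", "c"), tri, wtri)
#' @export
extractFeatures <- function(sub, unet, wnet) {
  uar <- asAdjRep(unet)
  war <- asAdjRep(wnet)
  uidx <- nodeIndices(uar, sub)
  widx <- nodeIndices(war, sub)
  n <- length(sub)
  if (n < 2L) stop("subgraph must have at least 2 members")
  uind <- inducedRep(uar, uidx)
  wind <- inducedRep(war, widx)

  deg_u <- lengths(uind$nbr)
  deg_w <- vapply(wind$w, sum, 0)
  n_edges <- sum(deg_u) / 2

  density_u <- n_edges / (n * (n - 1) / 2)
  density_w <- sum(deg_w) / (n * (n - 1))

  ## internal edge weights, each unordered edge once
  ew <- numeric(0)
  for (k in seq_len(n)) {
    sel <- wind$nbr[[k]] > k
    if (any(sel)) ew <- c(ew, wind$w[[k]][sel])
  }
  ew_mean <- if (length(ew)) mean(ew) else 0
  ew_var <- if (length(ew) >= 2L) popVar(ew) else 0

  ccu <- vapply(seq_len(n), function(k) ccuIdx(uind$nbr, k), 0)
  ccw <- vapply(seq_len(n), function(k) ccwIdx(wind$nbr, wind$w, k), 0)

  annd <- vapply(seq_len(n), function(k) {
    nb <- uind$nbr[[k]]
    if (!length(nb)) 0 else mean(deg_u[nb])
  }, 0)

  out <- c(
    density_u,
    max(deg_u), mean(deg_u), stats::median(deg_u),
    popVar(ccu),
    density_w,
    max(deg_w), mean(deg_w), stats::median(deg_w),
    ew_mean, ew_var,
    subgraphModularityIdx(war, widx),
    mean(ccw), max(ccw),
    mean(annd), popVar(annd))
  names(out) <- featureNames()
  out
}

## modularity on a prepared adjRep (hot path)
subgraphModularityIdx <- function(war, idx) {
  inside <- logical(length(war$nodes))
  inside[idx] <- TRUE
  d_in2 <- 0; d_out <- 0
  for (i in idx) {
    isin <- inside[war$adj[[i]]]
    w <- war$w[[i]]
    d_in2 <- d_in2 + sum(w[isin])
    d_out <- d_out + sum(w[!isin])
  }
  d_in <- d_in2 / 2
  if (d_in + d_out == 0) 0 else d_in / (d_in + d_out)
}

#' Feature matrix for a list of subgraphs
#'
#' @param subs list of character member vectors.
#' @inheritParams extractFeatures
#' @return numeric matrix, one row per subgraph, 16 named columns.
#' @export
featureMatrix <- function(subs, unet, wnet) {
  uar <- asAdjRep(unet)
  war <- asAdjRep(wnet)
  out <- matrix(0, nrow = length(subs), ncol = 16L,
                dimnames = list(NULL, featureNames()))
  for (i in seq_along(subs)) out[i, ] <- extractFeatures(subs[[i]], uar, war)
  out
}
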