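#' Edge similarity scores for PPI network weighting
#'
#' High-throughput interaction data are noisy, so each edge is assigned a
#' confidence weight combining two independent signals:
#' \describe{
#'   \item{topological}{a high-order common-neighbor score (HOCN) built from
#'     the Jaccard similarity of the endpoint neighborhoods and the
#'     connectivity of the shared neighborhood itself;}
#'   \item{biological}{an annotation-overlap score driven by how many GO
#'     terms the two proteins share and how specific (rarely annotated) the
#'     most specific shared term is.}
#' }
#' The final edge weight is \eqn{\sqrt{sim + HOCN}}.
#'
#' \code{jaccardSimilarity(v,u)} is \eqn{|CN(v,u)| / |N(v) \cup N(u)|}, where
#' \eqn{CN} is the common-neighbor set. \code{cnsScore} sums, over each common
#' neighbor \eqn{w}, the product \eqn{JCS(v,w) \cdot JCS(w,u)}, measuring how
#' strongly the shared neighborhood is tied to both endpoints. Then
#' \deqn{HOCN(v,u) = \frac{JCS(v,u) + CNS(v,u) + |CN(v,u)|}{|CN(v,u)| + 1}.}
#'
#' @param net undirected igraph graph.
#' @param v,u node names (must be vertices of \code{net}).
#' @return a single numeric score.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' jaccardSimilarity(tri, "a", "b")  # 1/3
#' hocnScore(tri, "a", "b")          # 13/18
#' @name edge-similarity
NULL

## neighbor index sets from an adjRep
nbrsOf <- function(rep, i) rep$adj[[i]]

jcsIdx <- function(rep, i, j) {
  ni <- rep$adj[[i]]; nj <- rep$adj[[j]]
  if (!length(ni) || !length(nj)) return(0)
  cn <- sum(ni %in% nj)
  un <- length(ni) + length(nj) - cn
  if (un == 0) 0 else cn / un
}

cnsIdx <- function(rep, i, j) {
  ni <- rep$adj[[i]]; nj <- rep$adj[[j]]
  cn <- ni[ni %in% nj]
  if (!length(cn)) return(0)
  s <- 0
  for (w in cn) s <- s + jcsIdx(rep, i, w) * jcsIdx(rep, w, j)
  s
}

hocnIdx <- function(rep, i, j) {
  ni <- rep$adj[[i]]; nj <- rep$adj[[j]]
  ncn <- sum(ni %in% nj)
  (jcsIdx(rep, i, j) + cnsIdx(rep, i, j) + ncn) / (ncn + 1)
}

#' @rdname edge-similarity
#' @export
jaccardSimilarity <- function(net, v, u) {
  rep <- asAdjRep(net)
  ij <- nodeIndices(rep, c(v, u))
  jcsIdx(rep, ij[1], ij[2])
}

#' @rdname edge-similarity
#' @export
cnsScore <- function(net, v, u) {
  rep <- asAdjRep(net)
  ij <- nodeIndices(rep, c(v, u))
  cnsIdx(rep, ij[1], ij[2])
}

#' @rdname edge-similarity
#' @export
hocnScore <- function(net, v, u) {
  rep <- asAdjRep(net)
  ij <- nodeIndices(rep, c(v, u))
  hocnIdx(rep, ij[1], ij[2])
}

#' GO annotation-overlap similarity between two proteins
#'
#' \deqn{sim(v,u) = |C(v,u)| \cdot \left(\log_b \frac{\min_i |S_i(v,u)|}{S_{max}}\right)^2}
#' where \eqn{C(v,u)} is the set of GO terms annotating both proteins,
#' \eqn{S_i(v,u)} the protein set annotated by the i-th shared term, and
#' \eqn{S_{max}} the largest annotation count over all terms. Sharing many
#' terms, at least one of which is specific (small \eqn{|S_i|} relative to
#' \eqn{S_{max}}), yields a high score. Returns 0 when no term is shared; a
#' shared term annotating \eqn{S_{max}} proteins contributes nothing
#' (log of 1). The log base only rescales the score globally; base 10 is the
#' default and is configurable.
#'
#' @param ann an [AnnotationIndex-class] with at least one annotation.
#' @param v,u protein ids (may be absent from the index: score 0).
#' @param log_base base of the logarithm (default 10).
#' @return nonnegative numeric score.
#' @export
goSimilarity <- function(ann, v, u, log_base = 10) {
  if (ann@Smax < 1L) stop("AnnotationIndex is empty (Smax = 0)")
  tv <- ann@proteinTerms[[v]]
  tu <- ann@proteinTerms[[u]]
  if (is.null(tv) || is.null(tu)) return(0)
  shared <- intersect(tv, tu)
  if (!length(shared)) return(0)
  smin <- min(lengths(ann@termProteins[shared]))
  length(shared) * (log(smin / ann@Smax, base = log_base))^2
}

#' Weight a PPI network with combined GO and topological similarity
#'
#' Scores every existing edge \eqn{(v,u)} with
#' \eqn{Weight(v,u) = \sqrt{sim(v,u) + HOCN(v,u)}} and removes low-confidence
#' edges. With the default \code{min_weight = 0} only edges of exactly zero
#' confidence drop (no shared annotation, no shared neighborhood structure);
#' higher thresholds filter more aggressively. The node set is unchanged.
#' With \code{ann = NULL} the biological term is 0 and weights reduce to
#' \eqn{\sqrt{HOCN}}.
#'
#' @param net undirected igraph graph.
#' @param ann optional [AnnotationIndex-class]; NULL = topology only.
#' @param min_weight edges with weight \code{<= min_weight} are removed
#'   (default 0); must be nonnegative.
#' @param log_base log base of [goSimilarity()].
#' @return \code{net} with a \code{weight} edge attribute, low-confidence
#'   edges removed.
#' @export
weightNetwork <- function(net, ann = NULL, min_weight = 0, log_base = 10) {
  if (min_weight < 0) stop("min_weight must be nonnegative")
  rep <- asAdjRep(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  m <- nrow(el)
  wt <- numeric(m)
  for (k in seq_len(m)) {
    i <- el[k, 1]; j <- el[k, 2]
    s <- hocnIdx(rep, i, j)
    if (!is.null(ann))
      s <- s + goSimilarity(ann, rep$nodes[i], rep$nodes[j], log_base)
    wt[k] <- sqrt(s)
  }
  g <- net
  igraph::E(g)$weight <- wt
  igraph::delete_edges(g, which(wt <= min_weight))
}

#' Per-edge score table
#'
#' All component scores for every edge of \code{net}, mostly useful for
#' inspection and testing.
#'
#' @inheritParams weightNetwork
#' @return data.frame with columns u, v, jcs, cns, hocn, go_sim, merge,
#'   weight.
#' @export
edgeScoreTable <- function(net, ann = NULL, log_base = 10) {
  rep <- asAdjRep(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  m <- nrow(el)
  jcs <- cns <- hocn <- gos <- numeric(m)
  for (k in seq_len(m)) {
    i <- el[k, 1]; j <- el[k, 2]
    jcs[k] <- jcsIdx(rep, i, j)
    cns[k] <- cnsIdx(rep, i, j)
    hocn[k] <- hocnIdx(rep, i, j)
    if (!is.null(ann))
      gos[k] <- goSimilarity(ann, rep$nodes[i], rep$nodes[j], log_base)
  }
  data.frame(
    u = rep$nodes[el[, 1]], v = rep$nodes[el[, 2]],
    jcs = jcs, cns = cns, hocn = hocn, go_sim = gos,
    merge = gos + hocn, weight = sqrt(gos + hocn),
    stringsAsFactors = FALSE)
}
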