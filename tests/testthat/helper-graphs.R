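## Shared fixtures and naive oracle implementations. Oracles work directly
## on adjacency matrices so they share no code with the package's
## adjacency-list scoring paths.

namedGraph <- function(edges, nodes = NULL) {
  ## edges: character vector like c("a-b", "b-c")
  if (length(edges)) {
    parts <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
    df <- data.frame(from = parts[, 1], to = parts[, 2],
                     stringsAsFactors = FALSE)
    nodes <- sort(unique(c(nodes, parts[, 1], parts[, 2])))
    igraph::graph_from_data_frame(df, directed = FALSE, vertices = nodes)
  } else {
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    g
  }
}

unitWeights <- function(g) {
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

triGraph <- function() namedGraph(c("a-b", "b-c", "a-c"))
k4Graph <- function() namedGraph(c("a-b", "a-c", "a-d", "b-c", "b-d", "c-d"))

## random simple graph with character names, deterministic
randomNamedGraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    g
  })
}

randomWeighted <- function(g, seed) {
  withr::with_seed(seed,
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 3), 3))
  g
}

adjMat <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  storage.mode(A) <- "double"
  A
}

weightMat <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  else adjMat(g)
}

## ---- naive per-definition edge scores on an adjacency matrix ----

oracleJCS <- function(A, i, j) {
  cn <- sum(A[i, ] * A[j, ])
  un <- sum(pmax(A[i, ], A[j, ]))
  if (un == 0) 0 else cn / un
}

oracleCNS <- function(A, i, j) {
  cn <- which(A[i, ] == 1 & A[j, ] == 1)
  if (!length(cn)) return(0)
  sum(vapply(cn, function(w) oracleJCS(A, i, w) * oracleJCS(A, w, j), 0))
}

oracleHOCN <- function(A, i, j) {
  ncn <- sum(A[i, ] * A[j, ])
  (oracleJCS(A, i, j) + oracleCNS(A, i, j) + ncn) / (ncn + 1)
}

## ---- naive subgraph statistics on (A, W) matrices ----

oracleFeatures <- function(sub_idx, A, W) {
  n <- length(sub_idx)
  As <- A[sub_idx, sub_idx, drop = FALSE]
  Ws <- W[sub_idx, sub_idx, drop = FALSE]
  deg_u <- rowSums(As)
  deg_w <- rowSums(Ws)
  pv <- function(x) if (length(x)) mean((x - mean(x))^2) else 0
  ccu <- vapply(seq_len(n), function(v) {
    nb <- which(As[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    2 * (sum(As[nb, nb]) / 2) / (k * (k - 1))
  }, 0)
  ccw <- vapply(seq_len(n), function(v) {
    nb <- which(As[v, ] == 1)
    k <- length(nb)
    wv <- sum(Ws[v, nb])
    if (k < 2 || wv == 0) return(0)
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (As[nb[a], nb[b]] == 1) s <- s + Ws[v, nb[a]] + Ws[v, nb[b]]
    }
    s / (wv * (k - 1))
  }, 0)
  annd <- vapply(seq_len(n), function(v) {
    nb <- which(As[v, ] == 1)
    if (!length(nb)) 0 else mean(deg_u[nb])
  }, 0)
  ew <- Ws[upper.tri(Ws)][As[upper.tri(As)] == 1]
  d_in <- sum(Ws) / 2
  d_out <- sum(W[sub_idx, -sub_idx, drop = FALSE])
  c(density_u = sum(As) / 2 / (n * (n - 1) / 2),
    degree_max_u = max(deg_u), degree_avg_u = mean(deg_u),
    degree_med_u = stats::median(deg_u),
    clustcoef_var_u = pv(ccu),
    density_w = sum(Ws) / (n * (n - 1)),
    degree_max_w = max(deg_w), degree_avg_w = mean(deg_w),
    degree_med_w = stats::median(deg_w),
    edgeweight_mean = if (length(ew)) mean(ew) else 0,
    edgeweight_var = if (length(ew) >= 2) pv(ew) else 0,
    modularity = if (d_in + d_out == 0) 0 else d_in / (d_in + d_out),
    ccw_mean = mean(ccw), ccw_max = max(ccw),
    avg_nbr_degree_mean = mean(annd), avg_nbr_degree_var = pv(annd))
}

## all 2^(n(n-1)/2) simple graphs on n labelled nodes, as adjacency matrices
allGraphsAdj <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(mask) {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.integer(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0)
    A + t(A)
  })
}

benchCache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateBenchmark(synthConfig(seed = 3))
    cache
  }
})
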