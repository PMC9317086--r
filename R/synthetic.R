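#' Synthetic planted-complex benchmark configuration
#'
#' The generator emulates the statistical structure the pipeline assumes of
#' real interactomes: a sparse random background, dense planted node sets
#' standing in for complexes, and GO annotations in which most planted
#' complexes share a dedicated coherent term while every protein also picks
#' up random noise terms. Defaults are sized so the entire two-stage
#' pipeline (and its five-fold cross-validation) runs in well under a
#' minute.
#'
#' @param n_background_nodes total number of proteins (default 300).
#' @param p_background Erdos-Renyi background edge probability (0.01).
#' @param n_complexes planted complexes (20), disjoint node sets.
#' @param size_range integer (min >= 3, max) complex size range (3..8).
#' @param p_in within-complex edge probability (0.9).
#' @param n_go_terms total GO terms, dedicated ones first (50).
#' @param p_term_coherent probability a planted complex shares its dedicated
#'   term (0.9).
#' @param annotation_noise per-(protein, noise-term) annotation probability
#'   (0.05).
#' @param seed integer seed.
#' @return validated list of class \code{synthConfig}.
#' @export
synthConfig <- function(n_background_nodes = 300, p_background = 0.01,
                        n_complexes = 20, size_range = c(3L, 8L),
                        p_in = 0.9, n_go_terms = 50, p_term_coherent = 0.9,
                        annotation_noise = 0.05, seed = 1L) {
  stopifnot(p_background >= 0, p_background <= 1, p_in >= 0, p_in <= 1,
            p_term_coherent >= 0, p_term_coherent <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            size_range[1] >= 3, size_range[2] >= size_range[1],
            n_go_terms >= n_complexes)
  if (size_range[2] > n_background_nodes)
    stop("size_range max exceeds the total node count")
  structure(list(n_background_nodes = as.integer(n_background_nodes),
                 p_background = p_background,
                 n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range), p_in = p_in,
                 n_go_terms = as.integer(n_go_terms),
                 p_term_coherent = p_term_coherent,
                 annotation_noise = annotation_noise,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

#' Generate a planted-complex benchmark
#'
#' Draws an Erdos-Renyi background over all nodes, plants
#' \code{n_complexes} disjoint node sets wired internally at \code{p_in},
#' and annotates: each coherent complex (probability
#' \code{p_term_coherent}) shares a dedicated GO term over all its members;
#' noise terms are sprinkled per protein at \code{annotation_noise}. Term
#' aspects cycle through BP, MF, CC. Deterministic under the config seed.
#'
#' @param cfg a [synthConfig()].
#' @return list with \code{network} (igraph), \code{truth}
#'   ([ComplexSet-class]), \code{annotations} ([AnnotationIndex-class]) and
#'   \code{config}.
#' @export
generateBenchmark <- function(cfg = synthConfig()) {
  n <- cfg$n_background_nodes
  nodes <- sprintf("P%04d", seq_len(n))
  withSeed(cfg$seed, {
    ## planted disjoint member sets
    sizes <- if (cfg$n_complexes)
      sample(cfg$size_range[1]:cfg$size_range[2], cfg$n_complexes,
             replace = TRUE) else integer(0)
    if (sum(sizes) > n) stop("cannot plant that many disjoint complexes")
    pool <- sample(nodes, sum(sizes))
    truth <- vector("list", cfg$n_complexes)
    at <- 1L
    for (i in seq_len(cfg$n_complexes)) {
      truth[[i]] <- pool[at:(at + sizes[i] - 1L)]
      at <- at + sizes[i]
    }
    ## background edges
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- stats::runif(nrow(pairs)) < cfg$p_background
    a <- nodes[pairs[on, 1]]
    b <- nodes[pairs[on, 2]]
    ## planted internal edges
    for (m in truth) {
      k <- length(m)
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        if (stats::runif(1) < cfg$p_in) {
          a <- c(a, m[i]); b <- c(b, m[j])
        }
      }
    }
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    keep <- !duplicated(key)
    net <- igraph::graph_from_data_frame(
      data.frame(from = pmin(a, b)[keep], to = pmax(a, b)[keep],
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = nodes)

    ## annotations: dedicated terms first, then noise terms
    terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
    aspects <- rep_len(c("BP", "MF", "CC"), cfg$n_go_terms)
    ap <- character(0); at_ <- character(0); aa <- character(0)
    for (i in seq_len(cfg$n_complexes)) {
      if (stats::runif(1) < cfg$p_term_coherent) {
        ap <- c(ap, truth[[i]])
        at_ <- c(at_, rep(terms[i], length(truth[[i]])))
        aa <- c(aa, rep(aspects[i], length(truth[[i]])))
      }
    }
    ## noise: each protein gains one uniformly drawn noise term at the
    ## per-protein rate
    noise_terms <- terms[setdiff(seq_len(cfg$n_go_terms),
                                 seq_len(cfg$n_complexes))]
    if (length(noise_terms) && cfg$annotation_noise > 0) {
      hit <- stats::runif(n) < cfg$annotation_noise
      if (any(hit)) {
        tsel <- sample(noise_terms, sum(hit), replace = TRUE)
        ap <- c(ap, nodes[hit])
        at_ <- c(at_, tsel)
        aa <- c(aa, aspects[match(tsel, terms)])
      }
    }
    ann <- annotationIndex(ap, at_, aa)
    list(network = net,
         truth = ComplexSet(truth, provenance = "planted truth"),
         annotations = ann, config = cfg)
  })
}

#' Write a benchmark to disk
#'
#' Emits \code{edges.tsv}, \code{truth.txt} and \code{ann.gaf} (GAF 2.1)
#' plus a \code{manifest.tsv} recording the generator configuration, so the
#' fixture can be regenerated bit for bit. The three files round-trip
#' through [readEdgeList()], [readComplexes()] and [readGAF()].
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, the generated benchmark (see [generateBenchmark()]).
#' @export
makeBenchmark <- function(cfg = synthConfig(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bench <- generateBenchmark(cfg)
  writeEdgeList(bench$network, file.path(dir, "edges.tsv"))
  writeComplexes(bench$truth, file.path(dir, "truth.txt"))
  writeGAF(bench$annotations, file.path(dir, "ann.gaf"))
  man <- vapply(names(cfg), function(k)
    paste(k, paste(cfg[[k]], collapse = ","), sep = "\t"), "")
  writeLines(c("# benchmark generator manifest", man),
             file.path(dir, "manifest.tsv"))
  invisible(bench)
}

#' Write an AnnotationIndex as GAF 2.1
#'
#' @param ann an [AnnotationIndex-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGAF <- function(ann, path) {
  letter <- c(BP = "P", CC = "C", MF = "F")
  lines <- c("!gaf-version: 2.1")
  terms <- sort(names(ann@termProteins))
  for (t in terms) {
    for (p in sort(ann@termProteins[[t]])) {
      lines <- c(lines, paste(
        "SYN", p, p, "", t, "SYN:0000001", "IEA", "",
        letter[[ann@termAspect[[t]]]], "", "", "protein", "taxon:0",
        "20260101", "SYN", "", "", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
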