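#' Read a PPI network from a two- or three-column edge list
#'
#' Reads an undirected interaction network from a whitespace- or
#' tab-separated file with one interaction per line (`proteinA proteinB
#' [weight]`). Lines starting with `#` are ignored. Raw interactome dumps
#' routinely contain self-interactions and duplicated pairs; both are removed
#' so the result is a simple undirected graph. When duplicate pairs carry
#' conflicting weights the first-seen weight is kept and a warning is issued.
#'
#' @param path edge-list file.
#' @param dedupe collapse duplicate pairs and drop self-loops (default TRUE;
#'   FALSE only errors if the file is not already simple).
#' @return an undirected, simple \code{igraph} graph; edges carry a
#'   \code{weight} attribute when the file has a third column.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\ta", "a\ta", "b\tc"), f)
#' g <- readEdgeList(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
readEdgeList <- function(path, dedupe = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop("malformed edge-list line ", bad[1], ": expected 2-3 fields, got ",
         nf[bad[1]])
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- rep(NA_real_, length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    w[has_w] <- suppressWarnings(
      as.numeric(vapply(fields[has_w], `[[`, "", 3L)))
    if (anyNA(w[has_w]))
      stop("malformed edge-list line ", which(has_w & is.na(w))[1],
           ": non-numeric weight")
    if (any(w[has_w] < 0))
      stop("negative edge weight on line ", which(has_w & w < 0)[1])
  }
  weighted <- any(has_w)
  loops <- a == b
  if (any(loops)) {
    if (!dedupe) stop("self-loop present and dedupe = FALSE")
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  ## canonical unordered orientation, then first-seen wins
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (!dedupe) stop("duplicate edge present and dedupe = FALSE")
    if (weighted) {
      firstw <- w[match(key[dup], key)]
      if (any(!is.na(firstw) & !is.na(w[dup]) & firstw != w[dup]))
        warning("duplicate edges with conflicting weights: keeping first seen")
    }
    a <- a[!dup]; b <- b[!dup]; w <- w[!dup]
  }
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  if (weighted) igraph::E(g)$weight <- ifelse(is.na(w), 1, w)
  g
}

#' Write a (possibly weighted) network as a TSV edge list
#'
#' @param net igraph graph.
#' @param path output file.
#' @param digits decimal places for weights (default 6).
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path, digits = 6) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if ("weight" %in% igraph::edge_attr_names(net)) {
    lines <- sprintf(paste0("%s\t%s\t%.", digits, "f"),
                     el[, 1], el[, 2], igraph::E(net)$weight)
  } else if (nrow(el)) {
    lines <- paste(el[, 1], el[, 2], sep = "\t")
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Summarize a network
#'
#' Node count, edge count and the average neighbor count
#' \eqn{2|E|/|V|} (the mean degree), the headline statistic used to
#' characterise interactomes.
#'
#' @param net igraph graph.
#' @return list with \code{n_nodes}, \code{n_edges}, \code{avg_neighbors}.
#' @examples
#' g <- igraph::make_ring(5)
#' networkSummary(g)$avg_neighbors  # 2
#' @export
networkSummary <- function(net) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  list(n_nodes = n, n_edges = m,
       avg_neighbors = if (n == 0) 0 else 2 * m / n)
}

#' Read a reference complex catalog
#'
#' One complex per line, whitespace-separated protein ids (the MIPS/SGD-style
#' flat format). Duplicate ids within a line collapse. When a network is
#' supplied, members absent from it are dropped first — reference catalogs
#' are compiled independently of any one interactome, so they routinely list
#' proteins the network does not contain — and complexes left with fewer than
#' \code{min_size} members are discarded.
#'
#' @param path catalog file.
#' @param min_size minimum surviving complex size (default 3).
#' @param restrict_to optional igraph network to restrict members to.
#' @return a [ComplexSet-class].
#' @export
readComplexes <- function(path, min_size = 3, restrict_to = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keep_nodes <- if (!is.null(restrict_to)) igraph::V(restrict_to)$name
  cxs <- list()
  probs <- numeric(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    prob <- NA_real_
    memfield <- parts[1]
    if (length(parts) >= 2) {
      p <- suppressWarnings(as.numeric(parts[length(parts)]))
      if (!is.na(p)) {
        prob <- p
        memfield <- paste(parts[-length(parts)], collapse = " ")
      } else memfield <- paste(parts, collapse = " ")
    }
    mem <- unique(strsplit(trimws(memfield), "[ \t]+")[[1]])
    if (!is.null(keep_nodes)) mem <- mem[mem %in% keep_nodes]
    if (length(mem) >= min_size) {
      cxs[[length(cxs) + 1L]] <- mem
      probs <- c(probs, prob)
    }
  }
  ComplexSet(cxs, probability = probs, provenance = basename(path))
}

#' Write a ComplexSet
#'
#' One complex per line, members sorted lexicographically and separated by
#' single spaces; when a complex carries a probability it is appended as a
#' tab-separated field with 4 decimals. Round-trips through [readComplexes()].
#'
#' @param cs a [ComplexSet-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeComplexes <- function(cs, path) {
  lines <- vapply(seq_len(length(cs)), function(i) {
    base <- paste(cs@complexes[[i]], collapse = " ")
    p <- cs@probability[i]
    if (is.na(p)) base else sprintf("%s\t%.4f", base, p)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Parses a Gene Association File into an [AnnotationIndex-class]. Comment
#' lines (`!`) are skipped, rows whose qualifier contains \code{NOT} are
#' excluded, and only the requested ontology aspects are kept. The protein
#' identifier is taken from column 3 (DB object symbol) by default, matching
#' flat complex catalogs keyed by gene symbol; set \code{id_column = 2} for
#' database accessions. \code{Smax} is recomputed from the retained rows.
#'
#' @param path GAF file.
#' @param aspects subset of \code{c("BP","CC","MF")} to keep (default all).
#' @param exclude_evidence evidence codes to drop (default none).
#' @param id_column GAF column holding the protein identifier (2 or 3).
#' @return an [AnnotationIndex-class].
#' @export
readGAF <- function(path, aspects = c("BP", "CC", "MF"),
                    exclude_evidence = character(0), id_column = 3) {
  aspects <- match.arg(aspects, c("BP", "CC", "MF"), several.ok = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  aspect_code <- c(P = "BP", C = "CC", F = "MF")
  prot <- character(0); term <- character(0); asp <- character(0)
  if (length(lines)) {
    fields <- strsplit(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 15L))
      stop("GAF data row ", which(nf < 15L)[1], " has ", nf[nf < 15L][1],
           " columns; 15+ required")
    qual <- vapply(fields, `[[`, "", 4L)
    ev <- vapply(fields, `[[`, "", 7L)
    aletter <- vapply(fields, `[[`, "", 9L)
    keep <- !grepl("(^|\\|)NOT(\\||$)", qual) &
      aletter %in% names(aspect_code) &
      aspect_code[aletter] %in% aspects &
      !(ev %in% exclude_evidence)
    prot <- vapply(fields, `[[`, "", as.integer(id_column))[keep]
    term <- vapply(fields, `[[`, "", 5L)[keep]
    asp <- unname(aspect_code[aletter[keep]])
  }
  annotationIndex(prot, term, asp)
}

#' Build an AnnotationIndex from annotation triples
#'
#' @param protein,term,aspect parallel character vectors, one annotation per
#'   element; aspect in \code{c("BP","CC","MF")}.
#' @return an [AnnotationIndex-class].
#' @export
annotationIndex <- function(protein, term, aspect) {
  stopifnot(length(protein) == length(term), length(term) == length(aspect))
  dup <- duplicated(paste(protein, term, sep = "\r"))
  protein <- protein[!dup]; term <- term[!dup]; aspect <- aspect[!dup]
  pt <- lapply(split(term, protein), unique)
  tp <- lapply(split(protein, term), unique)
  ta <- vapply(split(aspect, term), `[[`, "", 1L)
  new("AnnotationIndex", proteinTerms = pt, termProteins = tp,
      termAspect = ta,
      Smax = if (length(tp)) max(lengths(tp)) else 0L)
}

#' @describeIn annotationIndex the largest per-term annotation count.
#' @param ann an [AnnotationIndex-class]
#' @export
smax <- function(ann) ann@Smax

#' @export
setMethod("show", "AnnotationIndex", function(object) {
  cat(sprintf(
    "AnnotationIndex: %d proteins, %d terms (Smax = %d)\n",
    length(object@proteinTerms), length(object@termProteins), object@Smax))
  if (length(object@termAspect)) {
    tab <- table(object@termAspect)
    cat("  terms by aspect:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(object)
})
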