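#' Construct a ComplexSet
#'
#' @param complexes list of character vectors of member protein ids (or a
#'   single character vector for a one-complex set). Members are sorted and
#'   de-duplicated.
#' @param probability optional numeric vector of classifier scores in
#'   \code{[0, 1]}, recycled NA otherwise.
#' @param label optional character vector of \code{"positive"}/\code{"negative"}.
#' @param provenance free-text origin of the set.
#' @return a [ComplexSet-class] object.
#' @examples
#' cs <- ComplexSet(list(c("b", "a", "c"), c("d", "e", "f")))
#' members(cs, 1)
#' @export
ComplexSet <- function(complexes = list(), probability = NULL, label = NULL,
                       provenance = NA_character_) {
  if (is.character(complexes)) complexes <- list(complexes)
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  n <- length(complexes)
  if (is.null(probability)) probability <- rep(NA_real_, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  new("ComplexSet", complexes = unname(complexes),
      probability = as.numeric(probability), label = as.character(label),
      provenance = provenance)
}

#' @export
setMethod("length", "ComplexSet", function(x) length(x@complexes))

#' @export
setMethod("show", "ComplexSet", function(object) {
  n <- length(object)
  cat(sprintf("ComplexSet with %d complex%s", n, if (n == 1) "" else "es"))
  if (!is.na(object@provenance)) cat(" [", object@provenance, "]", sep = "")
  cat("\n")
  if (n) {
    sz <- lengths(object@complexes)
    cat(sprintf("  sizes: min %d / median %g / max %d\n",
                min(sz), stats::median(sz), max(sz)))
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      m <- object@complexes[[i]]
      shown <- paste(utils::head(m, 6L), collapse = " ")
      if (length(m) > 6L) shown <- paste(shown, "...")
      p <- object@probability[i]
      cat(sprintf("  [%d] {%s}%s\n", i, shown,
                  if (is.na(p)) "" else sprintf(" p=%.3f", p)))
    }
    if (n > k) cat("  ...\n")
  }
  invisible(object)
})

#' @export
setMethod("[", "ComplexSet", function(x, i, j, ..., drop = TRUE) {
  new("ComplexSet", complexes = x@complexes[i],
      probability = x@probability[i], label = x@label[i],
      provenance = x@provenance)
})

#' Accessors for ComplexSet
#'
#' \code{members} returns the list of member vectors (or one vector when
#' \code{i} is given); \code{probabilities} and \code{labels} the parallel
#' metadata vectors.
#'
#' @param x a [ComplexSet-class]
#' @param i optional single index
#' @return list / character vector / numeric vector as appropriate.
#' @export
members <- function(x, i = NULL) {
  stopifnot(is(x, "ComplexSet"))
  if (is.null(i)) x@complexes else x@complexes[[i]]
}

#' @rdname members
#' @export
probabilities <- function(x) {
  stopifnot(is(x, "ComplexSet"))
  x@probability
}

#' @rdname members
#' @export
labels.ComplexSet <- function(x) x@label

#' Concatenate complex sets
#' @param x,... ComplexSet objects
#' @export
setMethod("c", "ComplexSet", function(x, ...) {
  rest <- list(...)
  cx <- x@complexes; pr <- x@probability; lb <- x@label
  for (y in rest) {
    cx <- c(cx, y@complexes)
    pr <- c(pr, y@probability)
    lb <- c(lb, y@label)
  }
  new("ComplexSet", complexes = cx, probability = pr, label = lb,
      provenance = x@provenance)
})

## canonical string form used for duplicate detection and stable ordering
canonicalKeys <- function(cs) {
  vapply(cs@complexes, paste, "", collapse = "\t")
}
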