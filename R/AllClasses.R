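#' @import methods
#' @importFrom stats median var phyper runif predict setNames
#' @importFrom utils head
NULL

#' Ordered collection of protein complexes
#'
#' A \code{ComplexSet} holds an ordered list of protein complexes, each a set
#' of protein identifiers, optionally carrying a classifier probability and a
#' positive/negative training label. Member vectors are stored sorted and
#' unique, so two complexes with the same members compare identical.
#'
#' @slot complexes list of character vectors (sorted, unique, non-empty).
#' @slot probability numeric vector parallel to \code{complexes}; \code{NA}
#'   where no score has been assigned, otherwise in \code{[0, 1]}.
#' @slot label character vector parallel to \code{complexes}; \code{NA},
#'   \code{"positive"} or \code{"negative"}.
#' @slot provenance single string describing where the set came from.
#'
#' @seealso [ComplexSet()] the constructor, [members()], [probabilities()]
#' @export
setClass("ComplexSet",
  representation(
    complexes = "list",
    probability = "numeric",
    label = "character",
    provenance = "character"
  ),
  prototype(
    complexes = list(),
    probability = numeric(0),
    label = character(0),
    provenance = NA_character_
  )
)

setValidity("ComplexSet", function(object) {
  cx <- object@complexes
  n <- length(cx)
  if (length(object@probability) != n || length(object@label) != n)
    return("probability and label must be parallel to complexes")
  for (m in cx) {
    if (!is.character(m) || length(m) == 0L)
      return("each complex must be a non-empty character vector")
    if (anyDuplicated(m) || is.unsorted(m))
      return("complex members must be sorted and unique")
  }
  p <- object@probability
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) return("probabilities must lie in [0, 1]")
  lab <- object@label
  if (!all(is.na(lab) | lab %in% c("positive", "negative")))
    return("labels must be 'positive', 'negative' or NA")
  TRUE
})

#' Bidirectional protein/GO-term annotation index
#'
#' Maps proteins to the GO terms annotating them and back, records each
#' term's ontology aspect (BP, CC or MF), and caches \code{Smax}, the largest
#' number of proteins annotated by any single term. \code{Smax} normalises
#' the annotation-overlap similarity used for edge weighting.
#'
#' @slot proteinTerms named list: protein id -> character vector of term ids.
#' @slot termProteins named list: term id -> character vector of protein ids.
#' @slot termAspect named character: term id -> one of "BP", "CC", "MF".
#' @slot Smax integer, \code{max(lengths(termProteins))} (0 when empty).
#'
#' @seealso [readGAF()], [goSimilarity()]
#' @export
setClass("AnnotationIndex",
  representation(
    proteinTerms = "list",
    termProteins = "list",
    termAspect = "character",
    Smax = "integer"
  ),
  prototype(
    proteinTerms = list(), termProteins = list(),
    termAspect = character(0), Smax = 0L
  )
)

setValidity("AnnotationIndex", function(object) {
  tp <- object@termProteins
  pt <- object@proteinTerms
  if (length(tp) != length(object@termAspect) ||
      !identical(sort(names(tp)), sort(names(object@termAspect))))
    return("every term needs exactly one aspect")
  if (!all(object@termAspect %in% c("BP", "CC", "MF")))
    return("aspects must be BP, CC or MF")
  smax <- if (length(tp)) max(lengths(tp)) else 0L
  if (object@Smax != smax)
    return("Smax must equal the largest term annotation count")
  ## inverse consistency: total pair count must agree and spot pairs match
  if (sum(lengths(tp)) != sum(lengths(pt)))
    return("proteinTerms and termProteins are not mutual inverses")
  TRUE
})

#' Stage-1 subgraph scorer (abstract)
#'
#' A scorer maps a candidate subgraph (a set of member proteins, viewed in
#' the unweighted and the weighted network) to the probability that it is a
#' genuine complex. Two concrete scorers exist: the trained support-vector
#' scorer of [trainSubgraphScorer()] and the plug-in [functionScorer()] used
#' for controlled experiments.
#'
#' @export
setClass("SubgraphScorer", representation("VIRTUAL"))

#' Support-vector subgraph scorer
#'
#' Concrete [SubgraphScorer-class] over the 16 topological features;
#' \code{model} is the fitted \code{e1071::svm} object.
#'
#' @slot model fitted svm with probability calibration.
#' @slot hyperparameters list of the SVC settings used.
#' @slot seed integer seed the fit was made reproducible with.
#' @export
setClass("SVMSubgraphScorer", contains = "SubgraphScorer",
  representation(model = "ANY", hyperparameters = "list", seed = "integer"))

#' Function-backed subgraph scorer
#'
#' Concrete [SubgraphScorer-class] wrapping an arbitrary function
#' \code{fun(members, unet, wnet) -> numeric in [0,1]}; used to study the
#' grow/filter machinery under a controlled scoring rule.
#'
#' @slot fun scoring function.
#' @export
setClass("FunctionScorer", contains = "SubgraphScorer",
  representation(fun = "function"))

#' Stage-2 complex classifier
#'
#' Random forest over averaged node-embedding vectors, with a decision
#' threshold: candidates whose positive-class probability exceeds the
#' threshold are kept as final predictions.
#'
#' @slot forest fitted \code{randomForest} object.
#' @slot threshold decision threshold on the positive-class probability.
#' @slot seed integer seed used for the fit.
#' @export
setClass("ComplexClassifier",
  representation(forest = "ANY", threshold = "numeric", seed = "integer"))

setValidity("ComplexClassifier", function(object) {
  if (length(object@threshold) != 1 || object@threshold < 0 ||
      object@threshold > 1)
    return("threshold must be a single value in [0, 1]")
  TRUE
})
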