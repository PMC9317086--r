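#' One-shot two-stage complex prediction
#'
#' Trains both stages on a reference catalog and predicts complexes on the
#' network: weight the edges, sample size-matched negatives, train the
#' stage-1 SVC scorer, run SVCC (clique seeding on the confidence-filtered
#' weighted network, expansion, filtration), then — unless
#' \code{two_stage = FALSE} — embed nodes, train the stage-2 random forest
#' and keep only candidates it classifies as genuine.
#'
#' This is the building block [runPipeline()] and [crossValidate()] are
#' assembled from; use [crossValidate()] when predictions must be evaluated
#' out of their training sample.
#'
#' @param net unweighted igraph network.
#' @param positives reference [ComplexSet-class] used for training (members
#'   must be network nodes, sizes >= 3).
#' @param ann optional [AnnotationIndex-class]; NULL weights by topology
#'   only.
#' @param seed master seed.
#' @param min_weight confidence filter of [weightNetwork()].
#' @param svcc_cfg an [svccConfig()].
#' @param walk_cfg a [walkConfig()]; its seed is overridden by \code{seed}.
#' @param two_stage apply the stage-2 classifier (default TRUE).
#' @return list with \code{predictions}, stage-1 \code{candidates},
#'   \code{wnet}, \code{scorer}, and (two-stage only) \code{embedding},
#'   \code{classifier}.
#' @export
predictComplexes <- function(net, positives, ann = NULL, seed = 1L,
                             min_weight = 0, svcc_cfg = svccConfig(),
                             walk_cfg = walkConfig(), two_stage = TRUE) {
  wnet <- weightNetwork(net, ann, min_weight)
  negs <- sampleNegatives(net, positives, saltSeed(seed, "negatives"))
  ts <- buildTrainingSet(positives, negs, net, wnet)
  scorer <- trainSubgraphScorer(ts, seed = saltSeed(seed, "svm"))
  cands <- runSVCC(wnet, net, wnet, scorer, svcc_cfg)
  out <- list(candidates = cands, wnet = wnet, scorer = scorer)
  if (two_stage) {
    walk_cfg$seed <- saltSeed(seed, "embedding")
    emb <- embedNodes(generateWalks(net, walk_cfg), walk_cfg)
    clf <- trainComplexClassifier(positives, negs, emb,
                                  seed = saltSeed(seed, "rf"))
    out$embedding <- emb
    out$classifier <- clf
    out$predictions <- classifyCandidates(cands, clf, emb)
  } else {
    out$predictions <- cands
  }
  out
}

#' Run the full pipeline from files to artifacts
#'
#' Reads the network, annotations and reference catalog, runs the five-fold
#' cross-validated two-stage prediction, and writes all artifacts to
#' \code{out_dir}: the weighted network (\code{weighted.tsv}), the final
#' predictions (\code{predicted.txt}), the evaluation report
#' (\code{eval.tsv}), the per-complex enrichment report
#' (\code{enrichment.tsv}) and a manifest recording seeds and settings.
#' Rerunning with the same inputs and seed reproduces \code{predicted.txt}
#' byte for byte. A missing GAF is allowed: weighting then falls back to
#' topology only, with a warning.
#'
#' @param network_path edge-list TSV.
#' @param reference_path complex catalog.
#' @param out_dir output directory (created).
#' @param gaf_path optional GAF 2.x file (NULL = topology-only weights).
#' @param seed master seed.
#' @param min_weight confidence filter of [weightNetwork()].
#' @param cv_cfg a [cvConfig()].
#' @param svcc_cfg an [svccConfig()].
#' @param walk_cfg a [walkConfig()].
#' @return invisibly, the [crossValidate()] result.
#' @export
runPipeline <- function(network_path, reference_path, out_dir,
                        gaf_path = NULL, seed = 1L, min_weight = 0,
                        cv_cfg = cvConfig(), svcc_cfg = svccConfig(),
                        walk_cfg = walkConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- readEdgeList(network_path)
  ann <- NULL
  if (!is.null(gaf_path)) {
    ann <- readGAF(gaf_path)
  } else {
    warning("no GAF given: weighting by topology only")
  }
  standard <- readComplexes(reference_path, min_size = 3, restrict_to = net)
  wnet <- weightNetwork(net, ann, min_weight)
  writeEdgeList(wnet, file.path(out_dir, "weighted.tsv"))
  res <- crossValidate(wnet, net, wnet, standard, cv_cfg, svcc_cfg,
                       walk_cfg, seed = seed)
  writeComplexes(res$predictions, file.path(out_dir, "predicted.txt"))
  ev <- res$eval
  writeLines(c(paste(names(ev), collapse = "\t"),
               paste(unlist(ev), collapse = "\t")),
             file.path(out_dir, "eval.tsv"))
  if (!is.null(ann)) {
    rep_df <- enrichmentReport(res$predictions, ann,
                               universe_size = igraph::vcount(net))
    utils::write.table(rep_df, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(
    "# pipeline manifest",
    paste0("package_version\t", as.character(utils::packageVersion("complexpred"))),
    paste0("seed\t", seed),
    paste0("min_weight\t", min_weight),
    paste0("network\t", basename(network_path)),
    paste0("reference\t", basename(reference_path)),
    paste0("gaf\t", if (is.null(gaf_path)) "none" else basename(gaf_path)),
    paste0("folds\t", cv_cfg$folds),
    paste0("alpha\t", svcc_cfg$alpha),
    paste0("beta\t", svcc_cfg$beta),
    paste0("walk_p\t", walk_cfg$p),
    paste0("walk_q\t", walk_cfg$q),
    paste0("dimensions\t", walk_cfg$dimensions)),
    file.path(out_dir, "manifest.tsv"))
  invisible(res)
}
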