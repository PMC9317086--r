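test_that("overlap ratio and neighborhood affinity follow set arithmetic", {
  expect_equal(overlapRatio(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(overlapRatio(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(overlapRatio(c("a", "b"), c("x", "y")), 0)
  expect_error(overlapRatio(character(0), "a"), "non-empty")

  expect_equal(neighborhoodAffinity(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(neighborhoodAffinity(c("a", "b", "c", "d"), c("a", "b", "x")),
               4 / 12)
  expect_equal(neighborhoodAffinity(c("a", "b"), c("x", "y")), 0)
  expect_error(neighborhoodAffinity("a", character(0)), "non-empty")
})

test_that("F-score is the harmonic mean with the conventional zero case", {
  expect_equal(round(fScore(0.7684, 0.4330), 4), 0.5539)
  expect_equal(round(fScore(0.6057, 0.4631), 4), 0.5249)
  expect_equal(fScore(0, 0), 0)
  expect_equal(fScore(0.3, 0.7), fScore(0.7, 0.3))
  ## bounded by twice the smaller component
  for (p in c(0.1, 0.5, 0.9)) for (r in c(0.2, 0.6, 1)) {
    expect_lte(fScore(p, r), 2 * min(p, r))
  }
})

test_that("matching-based precision/recall behave at the extremes", {
  B <- ComplexSet(list(c("a", "b", "c"), c("d", "e", "f"),
                       c("g", "h", "i")))
  self <- evaluateComplexes(B, B)
  expect_equal(self$precision, 1)
  expect_equal(self$recall, 1)
  expect_equal(self$fscore, 1)

  none <- evaluateComplexes(ComplexSet(list(c("x", "y", "z"))), B)
  expect_equal(none$precision, 0)
  expect_equal(none$fscore, 0)

  empty <- evaluateComplexes(ComplexSet(), B)
  expect_equal(empty$precision, 0)
  expect_equal(empty$recall, 0)
  expect_error(evaluateComplexes(B, ComplexSet()), "non-empty")
})

test_that("matching threshold is strict and counts are monotone", {
  B <- ComplexSet(list(c("a", "b", "c", "d")))
  ## NA = 4/12 > 0.25 matches; NA = 1/4 does not (strict)
  p_match <- ComplexSet(list(c("a", "b", "x")))
  p_border <- ComplexSet(list(c("a", "x", "y", "z")))  # NA = 1/16
  expect_equal(evaluateComplexes(p_match, B)$Ncp, 1)
  expect_equal(evaluateComplexes(p_border, B)$Ncp, 0)
  ## exactly at the threshold: |int|=1, sizes 1x4 -> NA = 0.25, not matched
  p_exact <- ComplexSet(list("a"))
  expect_equal(evaluateComplexes(p_exact, B)$Ncp, 0)

  ## adding a matching prediction never decreases the match counts
  ev1 <- evaluateComplexes(p_match, B)
  ev2 <- evaluateComplexes(c(p_match, ComplexSet(list(c("a", "b", "c")))), B)
  expect_gte(ev2$Ncp, ev1$Ncp)
  expect_gte(ev2$Ncb, ev1$Ncb)
})

test_that("hypergeometric p-value matches enumeration and phyper", {
  ann <- annotationIndex(
    c("p1", "p2", "p3", "p4", "p5"), rep("t", 5), rep("BP", 5))
  ## |V|=10, |F|=5, |C|=3, k=3: exhaustive enumeration over C(10,3) subsets
  ## of a 10-protein universe gives P = C(5,3)/C(10,3) = 1/12
  universe <- c(sprintf("p%d", 1:5), sprintf("q%d", 1:5))
  cnt <- 0
  for (s in utils::combn(10, 3, simplify = FALSE))
    if (all(universe[s] %in% c("p1", "p2", "p3", "p4", "p5"))) cnt <- cnt + 1
  expect_equal(cnt / choose(10, 3), 1 / 12)
  expect_equal(enrichmentPvalue(c("p1", "p2", "p3"), ann, "t", 10), 1 / 12)

  ## |F| = |V|: every draw is fully annotated
  expect_equal(enrichmentPvalue(c("p1", "p2"), ann, "t", 5), 1)
  ## k = 0 convention
  expect_equal(enrichmentPvalue(c("q1", "q2", "q3"), ann, "t", 10), 1)
  expect_error(enrichmentPvalue(sprintf("p%d", 1:6), ann, "t", 5), "smaller")

  ## equality with the survival function of the hypergeometric for all
  ## universes up to 30
  worst <- 0
  for (V in 3:30) for (F in 0:V) for (C in 1:min(V, 6)) for (k in 0:C) {
    mine <- complexpred:::hyperUpperTail(k, F, V, C)
    ref <- stats::phyper(k - 1, F, V - F, C, lower.tail = FALSE)
    worst <- max(worst, abs(mine - ref))
  }
  expect_lt(worst, 1e-9)
})

test_that("best enrichment finds the minimum p-value term per aspect", {
  bench <- benchCache()
  ann <- bench$annotations
  V <- igraph::vcount(bench$network)
  cx <- members(bench$truth, 1)
  best <- bestEnrichment(cx, ann, V)
  expect_setequal(best$aspect, c("BP", "CC", "MF"))
  expect_true(all(best$p_value >= 0 & best$p_value <= 1))
  ## brute-force scan over every annotating term
  terms <- unique(unlist(ann@proteinTerms[intersect(cx, names(ann@proteinTerms))]))
  for (a in c("BP", "CC", "MF")) {
    ta <- terms[ann@termAspect[terms] == a]
    if (length(ta)) {
      pmin_ref <- min(vapply(ta, function(t)
        enrichmentPvalue(cx, ann, t, V), 0))
      expect_equal(best$p_value[best$aspect == a], pmin_ref)
    }
  }
  ## unannotated complex: all aspects p = 1, no terms
  none <- bestEnrichment(c("zz1", "zz2", "zz3"), ann, V)
  expect_equal(none$p_value, rep(1, 3))
  expect_true(all(is.na(none$term)))
})

test_that("ranked-scan deduplication enforces the overlap bound", {
  cs <- ComplexSet(list(c("a", "b", "c", "d"), c("a", "b", "c", "e"),
                        c("x", "y", "z"), c("a", "b", "c", "d")),
                   probability = c(0.9, 0.8, 0.7, 0.6))
  out <- complexpred:::dedupeByOverlap(cs, 0.6)
  m <- members(out)
  ## the duplicate collapses; overlap exactly 0.6 is kept (strict rule)
  expect_equal(length(out), 3)
  for (i in seq_along(m)) for (j in seq_along(m)) {
    if (i != j) expect_lte(overlapRatio(m[[i]], m[[j]]), 0.6)
  }
  out05 <- complexpred:::dedupeByOverlap(cs, 0.5)
  expect_equal(members(out05),
               list(c("a", "b", "c", "d"), c("x", "y", "z")))
  ## threshold 1 removes only exact duplicates
  out2 <- complexpred:::dedupeByOverlap(cs, 1)
  expect_equal(length(out2), 3)
})

test_that("cross-validation yields well-separated, evaluable predictions", {
  cfg <- synthConfig(n_background_nodes = 150, p_background = 0.01,
                     n_complexes = 12, size_range = c(4L, 6L), seed = 17)
  bench <- generateBenchmark(cfg)
  wnet <- weightNetwork(bench$network, bench$annotations)
  wcfg <- walkConfig(walk_length = 30, num_walks = 5, dimensions = 16,
                     epochs = 3)
  res <- crossValidate(wnet, bench$network, wnet, bench$truth,
                       walk_cfg = wcfg, seed = 42)
  expect_s4_class(res$predictions, "ComplexSet")
  ev <- res$eval
  expect_equal(ev$n_reference, length(bench$truth))
  expect_lte(ev$Ncp, ev$n_predicted)
  expect_lte(ev$Ncb, ev$n_reference)
  expect_equal(ev$fscore, fScore(ev$precision, ev$recall))
  ## every surviving pair respects the merge-overlap bound
  m <- members(res$predictions)
  if (length(m) > 1) {
    for (i in 1:(length(m) - 1)) for (j in (i + 1):length(m))
      expect_lte(overlapRatio(m[[i]], m[[j]]), 0.6)
  }
  expect_error(crossValidate(wnet, bench$network, wnet,
                             bench$truth[1:3], seed = 1),
               "at least as many")
})
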