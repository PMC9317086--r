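## scorer stubs for exercising the grow/filter machinery in isolation
constScorer <- function(p) functionScorer(function(m, u, w) p)
tableScorer <- function(map) functionScorer(function(m, u, w) {
  key <- paste(sort(m), collapse = " ")
  if (!is.null(map[[key]])) map[[key]] else 0
})
densityScorer <- function() functionScorer(function(m, u, w)
  min(1, weightedDensity(m, u)))

test_that("negative sampling matches positive sizes and is reproducible", {
  bench <- benchCache()
  pos <- bench$truth
  neg <- sampleNegatives(bench$network, pos, seed = 11)
  expect_equal(sort(lengths(members(neg))), sort(lengths(members(pos))))
  neg2 <- sampleNegatives(bench$network, pos, seed = 11)
  expect_identical(members(neg), members(neg2))
  neg3 <- sampleNegatives(bench$network, pos, seed = 12)
  expect_false(identical(members(neg), members(neg3)))
  ## no negative reproduces a positive member set
  expect_length(intersect(
    vapply(members(neg), paste, "", collapse = " "),
    vapply(members(pos), paste, "", collapse = " ")), 0)

  tiny <- namedGraph(c("a-b", "b-c"))
  big <- ComplexSet(list(c("a", "b", "c", "d")))
  expect_error(sampleNegatives(tiny, big, 1), "smaller")
  ## the only size-3 draw from a 3-node network equals the positive
  only <- ComplexSet(list(c("a", "b", "c")))
  expect_error(sampleNegatives(tiny, only, 1), "distinct")
})

test_that("training sets pair features with labels", {
  g <- unitWeights(namedGraph(c("a-b", "b-c", "a-c", "c-d", "d-e", "e-f",
                                "d-f")))
  pos <- ComplexSet(list(c("a", "b", "c")))
  neg <- ComplexSet(list(c("d", "e", "f"), c("b", "c", "d")))
  ts <- buildTrainingSet(pos, neg, g, g)
  expect_equal(dim(ts$features), c(3L, 16L))
  expect_equal(ts$labels, c(1L, 0L, 0L))
  expect_equal(ts$features[1, ], extractFeatures(c("a", "b", "c"), g, g))
  expect_error(buildTrainingSet(ComplexSet(), neg, g, g), "both classes")
  expect_error(
    buildTrainingSet(pos, ComplexSet(list(c("a", "b"))), g, g),
    "at least 3")
})

test_that("the SVC scorer separates dense from sparse subgraphs", {
  ## 20 dense planted cliques vs 20 random sparse node sets
  bench <- generateBenchmark(synthConfig(p_in = 1, seed = 6))
  wnet <- weightNetwork(bench$network, bench$annotations)
  pos <- bench$truth
  neg <- sampleNegatives(bench$network, pos, seed = 5)
  ts <- buildTrainingSet(pos, neg, bench$network, wnet)
  scorer <- trainSubgraphScorer(ts, seed = 2)
  p_pos <- scoreSubgraphs(scorer, members(pos), bench$network, wnet)
  ## held-out negatives: a fresh random draw
  hold <- sampleNegatives(bench$network, pos, seed = 99)
  p_neg <- scoreSubgraphs(scorer, members(hold), bench$network, wnet)
  expect_true(all(c(p_pos, p_neg) >= 0 & c(p_pos, p_neg) <= 1))
  pred <- c(predict(scorer@model, featureMatrix(members(pos),
                                                bench$network, wnet)),
            predict(scorer@model, featureMatrix(members(hold),
                                                bench$network, wnet)))
  acc <- mean(pred == factor(rep(c(1, 0), each = 20), levels = c(0, 1)))
  expect_gt(acc, 0.9)
  ## probabilities rank real complexes above random sets
  expect_gt(mean(p_pos), mean(p_neg))
  ## refit under the same seed reproduces the predictions exactly
  scorer2 <- trainSubgraphScorer(ts, seed = 2)
  expect_equal(p_pos, scoreSubgraphs(scorer2, members(pos),
                                     bench$network, wnet))
  expect_error(
    trainSubgraphScorer(structure(list(features = ts$features,
                                       labels = rep(1L, nrow(ts$features)),
                                       complexes = list()),
                                  class = "trainingSet")),
    "both classes")
})

test_that("maximal clique seeding is exact and deterministic", {
  g <- namedGraph(c("a-b", "b-c", "a-c", "c-d"))
  cs <- enumerateInitialSubgraphs(g)
  expect_equal(members(cs), list(c("a", "b", "c")))

  k4 <- k4Graph()
  expect_equal(members(enumerateInitialSubgraphs(k4)),
               list(c("a", "b", "c", "d")))

  tf <- namedGraph(c("a-b", "b-c", "c-d", "d-a"))  # triangle-free
  expect_length(enumerateInitialSubgraphs(tf), 0)
  expect_length(enumerateInitialSubgraphs(igraph::make_empty_graph(0)), 0)
})

test_that("seed selection drops heavy member overlap in rank order", {
  g <- unitWeights(namedGraph(c("a-b", "a-c", "a-d", "b-c", "b-d", "c-d",
                                "a-e", "b-e", "c-e", "x-y", "x-z", "y-z")))
  seeds <- ComplexSet(list(c("a", "b", "c", "d"), c("a", "b", "c", "e"),
                           c("x", "y", "z")))
  sc <- tableScorer(list(`a b c d` = 0.9, `a b c e` = 0.8, `x y z` = 0.7))
  kept <- selectSubgraphs(seeds, sc, alpha = 2, g, g)
  expect_equal(members(kept), list(c("a", "b", "c", "d"), c("x", "y", "z")))

  ## overlap of exactly alpha members is allowed ("exceeds" is strict)
  seeds2 <- ComplexSet(list(c("a", "b", "c"), c("b", "c", "e")))
  sc2 <- tableScorer(list(`a b c` = 0.9, `b c e` = 0.8))
  expect_length(selectSubgraphs(seeds2, sc2, alpha = 2, g, g), 2)
  ## disjoint seeds all survive any alpha
  expect_length(selectSubgraphs(
    ComplexSet(list(c("a", "b", "c"), c("x", "y", "z"))),
    constScorer(0.5), 1, g, g), 2)
})

test_that("expansion adds the best strictly improving neighbor", {
  ## triangle + node d adjacent to all three members: modularity 0.5 -> 1
  g <- unitWeights(namedGraph(c("a-b", "b-c", "a-c",
                                "a-d", "b-d", "c-d")))
  modScorer <- functionScorer(function(m, u, w) subgraphModularity(m, w))
  ex <- expandSubgraph(c("a", "b", "c"), g, modScorer, g, g)
  expect_equal(ex$members, c("a", "b", "c", "d"))
  expect_equal(ex$probability, 1)

  ## no neighbors: unchanged
  iso <- unitWeights(namedGraph(c("a-b", "b-c", "a-c"),
                                nodes = c("a", "b", "c", "z")))
  ex2 <- expandSubgraph(c("a", "b", "c"), iso, modScorer, iso, iso)
  expect_equal(ex2$members, c("a", "b", "c"))

  ## constant score: no strict increase, no growth
  ex3 <- expandSubgraph(c("a", "b", "c"), g, constScorer(0.5), g, g)
  expect_equal(ex3$members, c("a", "b", "c"))
})

test_that("filtration merges high overlap, drops partial, keeps disjoint", {
  g <- unitWeights(namedGraph(c("a-b", "a-c", "a-d", "b-c", "b-d", "c-d",
                                "a-e", "b-e", "c-e", "x-y", "x-z", "y-z")))
  ## overlap 3/5 = 0.6 < beta: lower-ranked candidate is filtered out
  cands <- ComplexSet(list(c("a", "b", "c", "d"), c("a", "b", "c", "e")),
                      probability = c(0.9, 0.8))
  out <- filterCandidates(cands, constScorer(0.5), beta = 0.8, g, g)
  expect_equal(members(out), list(c("a", "b", "c", "d")))

  ## identical member sets collapse to one
  dup <- ComplexSet(list(c("a", "b", "c"), c("a", "b", "c")),
                    probability = c(0.7, 0.7))
  expect_length(filterCandidates(dup, constScorer(0.5), 0.8, g, g), 1)

  ## overlap above beta merges into the union
  near <- ComplexSet(list(c("a", "b", "c", "d"), c("a", "b", "c", "d", "e")),
                     probability = c(0.9, 0.8))
  merged <- filterCandidates(near, constScorer(0.5), beta = 0.8, g, g)
  expect_equal(members(merged), list(c("a", "b", "c", "d", "e")))

  ## disjoint candidates are exempt from "otherwise filtered out"
  disj <- ComplexSet(list(c("a", "b", "c"), c("x", "y", "z")),
                     probability = c(0.9, 0.8))
  expect_length(filterCandidates(disj, constScorer(0.5), 0.8, g, g), 2)
})

test_that("threshold limits behave as pass-through and aggressive merge", {
  bench <- benchCache()
  wnet <- weightNetwork(bench$network, bench$annotations)
  seeds <- enumerateInitialSubgraphs(wnet)
  sc <- densityScorer()
  ## alpha -> infinity: selection is a pass-through
  all_kept <- selectSubgraphs(seeds, sc, alpha = 10^6, bench$network, wnet)
  expect_equal(length(all_kept), length(seeds))
  ## small beta: every overlapping pair merges, none dropped outright;
  ## survivors are pairwise disjoint
  m <- members(filterCandidates(all_kept, sc, beta = 1e-9,
                                bench$network, wnet))
  if (length(m) > 1) {
    for (i in 1:(length(m) - 1)) for (j in (i + 1):length(m))
      expect_length(intersect(m[[i]], m[[j]]), 0)
  }
  expect_setequal(unique(unlist(members(all_kept))), unique(unlist(m)))
})

test_that("the full stage-1 pipeline recovers planted cliques", {
  cfg <- synthConfig(n_background_nodes = 80, p_background = 0.02,
                     n_complexes = 5, size_range = c(5L, 5L), p_in = 1,
                     seed = 9)
  bench <- generateBenchmark(cfg)
  g <- unitWeights(bench$network)
  out <- runSVCC(bench$network, bench$network, g, densityScorer())
  expect_true(all(lengths(members(out)) >= 3))
  ev <- evaluateComplexes(out, bench$truth)
  expect_gte(ev$recall, 0.8)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(runSVCC(empty, empty, empty, densityScorer()), 0)
})

test_that("stage outputs shrink monotonically and stay inside the network", {
  bench <- benchCache()
  wnet <- weightNetwork(bench$network, bench$annotations)
  sc <- densityScorer()
  seeds <- enumerateInitialSubgraphs(wnet)
  sel <- selectSubgraphs(seeds, sc, 2, bench$network, wnet)
  expect_lte(length(sel), length(seeds))
  out <- runSVCC(wnet, bench$network, wnet, sc)
  nodes <- igraph::V(bench$network)$name
  for (m in members(out)) expect_true(all(m %in% nodes))
  ## expansion never removes seed members
  ex <- expandSubgraph(members(sel, 1), wnet, sc, bench$network, wnet)
  expect_true(all(members(sel, 1) %in% ex$members))
})
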