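test_that("Weir-Cockerham F_ST matches the variance-component oracle", {
  # fixture 1: the p = 0.9 / 0.1, observed heterozygosity 0.2 case
  gA <- makeGeno(10, 18, 2)   # p = 0.9, h = 0.2
  gB <- makeGeno(10, 2, 2)    # p = 0.1, h = 0.2
  expect_equal(wcFstPair(gA, gB), wcOracle(gA, gB), tolerance = 1e-9)
  expect_gt(wcFstPair(gA, gB), 0.5)  # strong differentiation

  # fixture 2: unequal sample sizes, three loci
  gA2 <- cbind(makeGeno(6, 5, 3), makeGeno(6, 8, 2), makeGeno(6, 1, 1))
  gB2 <- cbind(makeGeno(10, 12, 4), makeGeno(10, 3, 3), makeGeno(10, 9, 5))
  expect_equal(wcFstPair(gA2, gB2), wcOracle(gA2, gB2), tolerance = 1e-9)

  # fixture 3: nearly undifferentiated Hardy-Weinberg-ish samples
  gA3 <- cbind(makeGeno(8, 8, 4), makeGeno(8, 4, 4))
  gB3 <- cbind(makeGeno(8, 7, 5), makeGeno(8, 5, 3))
  expect_equal(wcFstPair(gA3, gB3), wcOracle(gA3, gB3), tolerance = 1e-9)
})

test_that("F_ST endpoints behave as expected", {
  # identical genotype arrays: estimate at or below zero
  g <- cbind(makeGeno(10, 8, 4), makeGeno(10, 12, 6))
  expect_lte(wcFstPair(g, g), 0)
  # fixed difference with HWE within demes: exactly 1
  expect_equal(wcFstPair(matrix(2L, 10, 1), matrix(0L, 10, 1)), 1)
  # no polymorphic locus: undefined
  expect_true(is.na(wcFstPair(matrix(0L, 5, 1), matrix(0L, 5, 1))))
  expect_error(wcFstPair(matrix(0L, 1, 1), matrix(0L, 5, 1)), "2 diploids")
})

test_that("F_ST matrices are symmetric, zero-diagonal, clamped non-negative", {
  map <- tinyMap()
  cfg <- tinyConfig()
  st <- initState(map, cfg, "neutral", seed = 21)
  for (g in 1:15) st <- stepGeneration(st, map, cfg)
  smp <- sampleAndFilter(st, map, cfg, seed = 22)
  fm <- fstMatrix(smp, "genome")
  v <- offsetValues(fm)
  expect_equal(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_true(all(v >= 0, na.rm = TRUE))
  expect_true(is.numeric(fm@metadata$clampedNegative))
  # causal subset on a neutral run errors
  expect_error(fstMatrix(smp, "causal"), "causal")
})

test_that("environmental distances follow the standard formulas", {
  expect_equal(envDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(envDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(envDistance(c(1, 2), c(1, 2), "mahalanobis",
                           covariance = diag(2)), 0)
  # identity covariance: Mahalanobis equals Euclidean
  a <- c(0.3, -1.2); b <- c(2.5, 0.4)
  expect_equal(envDistance(a, b, "mahalanobis", covariance = diag(2)),
               envDistance(a, b), tolerance = 1e-12)
  expect_error(envDistance(a, b, "mahalanobis"), "covariance")
  # singular covariance falls back to a ridge instead of failing
  S <- matrix(1, 2, 2)
  expect_true(is.finite(envDistance(a, b, "mahalanobis", covariance = S)))
})

test_that("pairwise environmental distance matrices honor subsets", {
  map <- metapopMap(5, 5, 20, m = 0.2)
  e1 <- linearGradient(-1, 1, "columns", map, "env1")
  e2 <- linearGradient(-1, 1, "rows", map, "env2")
  fields <- c(list(e1, e2), makeDecoyEnvs(list(e1, e2), seed = 4))
  edAll <- envDistanceMatrix(fields, "euclidean", "all")
  edCausal <- envDistanceMatrix(fields, "euclidean", "causal")
  expect_identical(dim(offsetValues(edAll)), c(25L, 25L))
  expect_equal(offsetValues(edAll), t(offsetValues(edAll)))
  expect_true(all(diag(offsetValues(edCausal)) == 0))
  # causal distance between opposite corners: sqrt(2^2 + 2^2)
  expect_equal(offsetValues(edCausal)[1, 25], sqrt(8))
  # Mahalanobis with the across-deme covariance matches the per-pair form
  md <- envDistanceMatrix(fields, "mahalanobis", "causal")
  X <- envMatrix(fields)[, 1:2]
  expect_equal(offsetValues(md)[3, 17],
               envDistance(X[3, ], X[17, ], "mahalanobis",
                           covariance = cov(X)), tolerance = 1e-9)
})

test_that("variance standardization biases Mahalanobis distance when one causal gradient is narrow", {
  # with one causal environment spanning -1..1 and the other only
  # -0.25..0.25, the per-variance rescaling inflates the narrow axis, so
  # the Mahalanobis causal distance tracks transplant fitness worse than
  # the plain Euclidean causal distance at edge gardens
  reps <- caseRunsLight("case3", 10L)
  worse <- vapply(reps, function(r) {
    fields <- r$run$envFields
    ed <- envDistanceMatrix(fields, "euclidean", "causal")
    md <- envDistanceMatrix(fields, "mahalanobis", "causal")
    ev <- evaluateOffsets(list(ed = ed, md = md), r$cg, r$run$map)
    edge <- ev[ev$class == "edge", ]
    mr <- tapply(abs(edge$rho), edge$metric, mean, na.rm = TRUE)
    mr[["md"]] < mr[["ed"]]
  }, logical(1))
  expect_gte(sum(worse), 6L)
})
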