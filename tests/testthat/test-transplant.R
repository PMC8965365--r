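test_that("local adaptation is diagonal mean minus off-diagonal mean", {
  expect_equal(localAdaptation(diag(5)), 1)
  expect_equal(localAdaptation(matrix(0.7, 4, 4)), 0)
  m <- matrix(0.2, 3, 3); diag(m) <- 0.9
  expect_equal(localAdaptation(m), 0.7)
  expect_error(localAdaptation(matrix(1, 2, 3)), "square")
})

test_that("CG fitness under perfect adaptation matches the closed form", {
  # sampled individuals whose phenotypes sit exactly on their home optima
  map <- metapopMap(5, 5, 20, m = 0.2)
  e1 <- linearGradient(-1, 1, "columns", map, "env1")
  e2 <- linearGradient(-1, 1, "rows", map, "env2")
  cfg <- simConfig(sigmaK = c(1.25, 1.25))
  demeOfS <- rep(seq_len(25), each = 2L)
  P <- cbind(envValues(e1)[demeOfS], envValues(e2)[demeOfS])
  smp <- new("DemeSample",
             genotypes = matrix(0L, 50, 1), demeOf = demeOfS,
             freqs = matrix(0.5, 25, 1), keptLoci = 1L,
             metapopFreqAll = 0.5,
             siteTableAll = data.frame(site_id = 1L, lg = 1L, pos = 0,
                                       type = "neutral", alpha1 = 0,
                                       alpha2 = 0, origin_generation = 0L),
             phenotypes = P, selGenotype = NULL)
  state <- new("PopulationState", haplotypes = matrix(0L, 100, 1),
               siteTable = smp@siteTableAll, demeOf = rep(1:25, each = 2),
               sex = rep(c(1L, 2L), 25), generation = 0L,
               fixedEffect = c(0, 0), architecture = "multilocus")
  run <- list(state = state, map = map, envFields = list(e1, e2),
              config = cfg)
  cg <- cgFitnessMatrix(run, smp)
  th1 <- envValues(e1); th2 <- envValues(e2)
  for (mSrc in c(1, 7, 25)) {
    for (g in c(1, 13, 25)) {
      expected <- exp(-0.5 * (((th1[mSrc] - th1[g]) / 1.25)^2 +
                                ((th2[mSrc] - th2[g]) / 1.25)^2))
      expect_equal(fitnessValues(cg)[mSrc, g], expected, tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(fitnessValues(cg))), rep(1, 25))
  expect_equal(localAdaptation(cg), 1 - mean(fitnessValues(cg)[
    row(fitnessValues(cg)) != col(fitnessValues(cg))]))
})

test_that("garden correlations behave on constructed offsets", {
  v <- matrix(0, 10, 10)
  f <- matrix(0, 10, 10)
  set.seed(5)
  f[, 3] <- runif(10)
  v[, 3] <- 1 - f[, 3]          # strictly anti-monotone
  om <- new("OffsetMatrix", metric = "gf", subset = "x", values = v * 0)
  om@values <- v; om@values[row(v) == col(v)] <- 0
  cgv <- pmin(pmax(f, 0.01), 1)
  cg <- new("CGFitnessMatrix", values = cgv, architecture = "multilocus")
  subset <- setdiff(1:10, 3)
  expect_equal(gardenCorrelation(om, cg, 3, 1:10), -1)
  # offsets equal to fitness ranks: +1
  om2 <- om; om2@values[, 3] <- rank(cgv[, 3]); om2@values[3, 3] <- 0
  expect_equal(gardenCorrelation(om2, cg, 3, subset), 1)
  # constant offset: undefined
  om3 <- om; om3@values[, 3] <- 1; om3@values[3, 3] <- 0
  expect_true(is.na(gardenCorrelation(om3, cg, 3, subset)))
})

test_that("evaluation subset and core/edge classification are fixed conventions", {
  map10 <- metapopMap(10, 10, 100, m = 0.2)
  sub <- evaluationSubset(map10)
  expect_length(sub, 32L)
  expect_identical(anyDuplicated(sub), 0L)
  expect_true(all(sub >= 1 & sub <= 100))
  # identical on recomputation (fixed convention)
  expect_identical(sub, evaluationSubset(map10))

  cls <- coreEdgeClass(map10)
  expect_identical(sum(cls == "edge"), 36L)
  expect_identical(cls[1], "edge")    # corner
  expect_identical(cls[12], "core")   # (1,1) interior
  map5 <- metapopMap(5, 5, 20, m = 0.2)
  expect_identical(evaluationSubset(map5), 1:25)
  expect_identical(sum(coreEdgeClass(map5) == "core"), 9L)
})

test_that("core/edge summary averages per metric and class", {
  res <- data.frame(metric = rep(c("gf", "fst"), each = 4),
                    subset = "x",
                    garden = rep(1:4, 2),
                    class = rep(c("core", "edge"), 4),
                    rho = c(-0.5, -0.5, -0.5, -0.5, -0.2, -0.4, -0.2, -0.4))
  s <- coreEdgeSummary(res)
  expect_equal(s$meanRho[s$metric == "gf" & s$class == "core"], -0.5)
  expect_equal(s$meanRho[s$metric == "fst" & s$class == "edge"], -0.4)
  one <- res[res$metric == "gf" & res$class == "core", ]
  expect_equal(coreEdgeSummary(one)$meanRho, -0.5)
  expect_error(coreEdgeSummary(res[0, ]), "empty")
})

test_that("constant adjacent-shift offsets leave the deme-size correlation undefined", {
  map <- metapopMap(10, 10, buildDemeSizes("increasing"), m = 0.05)
  # an empty model transforms every environment to zero: offsets constant
  envs <- matrix(seq(-1, 1, length.out = 10), ncol = 1,
                 dimnames = list(NULL, "env1"))
  freqs <- matrix(0.5, 10, 1, dimnames = list(NULL, "snp"))
  m <- fitGF(freqs, envs, gfParams(nTrees = 5L), seed = 1)
  e <- linearGradient(-1, 1, "columns", map, "env1")
  q <- q1OffsetVsDemesize(m, e, map)
  expect_true(is.na(q$r))
  expect_true(all(q$offsets == 0))
})
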