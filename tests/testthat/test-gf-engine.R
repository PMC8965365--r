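# deterministic engine settings for exact oracle checks: one tree, no
# bootstrap, all predictors candidates at every split
oracleParams <- function(nTrees = 1L) {
  gfParams(nTrees = nTrees, mtry = 99L, minLeaf = 2L, bootstrap = FALSE)
}

test_that("a single permitted split reproduces the impurity oracle exactly", {
  # clean two-level response: one split at 2.5 explains all variance
  envs <- matrix(1:4, ncol = 1, dimnames = list(NULL, "env"))
  freqs <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "snp"))
  m <- fitGF(freqs, envs, oracleParams(), seed = 1)
  tf <- aggregateTurnover(m, "env")
  expect_equal(unname(snpR2(m)), 1, tolerance = 1e-9)
  expect_equal(tf@knots, c(1, 2.5), tolerance = 1e-9)
  # step height = between-group variance explained = R^2 * share = 1
  expect_equal(tf@ci, c(0, 1), tolerance = 1e-9)
  expect_equal(evalTurnover(tf, 2.4), 0)
  expect_equal(evalTurnover(tf, 2.5), 1)

  # residual within-group variance: improvement and R^2 from first principles
  y <- c(0, 0.2, 0.8, 1.0)
  freqs2 <- matrix(y, ncol = 1, dimnames = list(NULL, "snp"))
  m2 <- fitGF(freqs2, envs, oracleParams(), seed = 1)
  ssTot <- sum((y - mean(y))^2)                     # 0.68
  sse <- sum((y - rep(c(0.1, 0.9), each = 2))^2)    # 0.04
  r2Hand <- 1 - sse / ssTot
  expect_equal(unname(snpR2(m2)), r2Hand, tolerance = 1e-9)
  tf2 <- aggregateTurnover(m2, "env")
  expect_equal(max(tf2@ci), r2Hand, tolerance = 1e-9)  # share = 1
  expect_equal(tf2@knots[2], 2.5, tolerance = 1e-9)
})

test_that("a causal predictor outranks a noise predictor", {
  set.seed(99)
  wins <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    env1 <- seq(-1, 1, length.out = 20)
    env2 <- rnorm(20)
    envs <- cbind(env1 = env1, env2 = env2)
    freqs <- matrix(plogis(5 * env1), ncol = 1,
                    dimnames = list(NULL, "snp"))
    m <- fitGF(freqs, envs, gfParams(nTrees = 50L), seed = s)
    unname(totalImportance(m)["env1"] > totalImportance(m)["env2"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("degenerate inputs are handled as specified", {
  envs <- cbind(env1 = 1:10, env2 = rep(1, 10))  # env2 constant
  freqs <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1,
                  dimnames = list(NULL, "snp"))
  m <- fitGF(freqs, envs, oracleParams(), seed = 1)
  expect_equal(unname(totalImportance(m)["env2"]), 0)  # no exception
  expect_gt(unname(totalImportance(m)["env1"]), 0)

  # all SNPs constant: empty model
  fc <- matrix(0.5, 10, 2, dimnames = list(NULL, c("a", "b")))
  me <- fitGF(fc, envs, oracleParams(), seed = 1)
  expect_true(me@empty)
  expect_error(rankPredictors(me), "empty")

  expect_error(fitGF(freqs[1:2, , drop = FALSE],
                     envs[1:2, , drop = FALSE]), "3 demes")
  freqs[1] <- NA
  expect_error(fitGF(freqs, envs), "missing")
})

test_that("turnover curves are monotone, zero at the left end, and clamp", {
  set.seed(7)
  envs <- cbind(env1 = runif(30, -1, 1), env2 = runif(30, 0, 10))
  freqs <- matrix(runif(30 * 5), 30, 5,
                  dimnames = list(NULL, paste0("s", 1:5)))
  m <- fitGF(freqs, envs, gfParams(nTrees = 30L), seed = 2)
  for (p in predictors(m)) {
    tf <- aggregateTurnover(m, p)
    expect_true(all(diff(tf@ci) >= -1e-12))
    expect_equal(tf@ci[1], 0)
    expect_equal(tf@knots[1], min(envs[, p]))
    # clamped evaluation outside the fitted range
    expect_equal(evalTurnover(tf, min(envs[, p]) - 5), 0)
    expect_equal(evalTurnover(tf, max(envs[, p]) + 5), max(tf@ci))
    # monotone evaluation
    xs <- sort(runif(10, -2, 12))
    expect_true(all(diff(evalTurnover(tf, xs)) >= 0))
  }
  # transform at the fitted minimum is the zero vector
  expect_equal(unname(transformEnv(m, apply(envs, 2, min))), c(0, 0))
  expect_error(aggregateTurnover(m, "nope"), "unknown")
})

test_that("gfOffset satisfies the metric axioms in transformed space", {
  set.seed(12)
  envs <- cbind(env1 = runif(25, -1, 1), env2 = runif(25, -1, 1))
  freqs <- matrix(plogis(4 * envs[, 1] + rnorm(25, 0, 0.2)), ncol = 1,
                  dimnames = list(NULL, "snp"))
  m <- fitGF(freqs, envs, gfParams(nTrees = 50L), seed = 3)
  for (i in 1:20) {
    a <- runif(2, -1, 1); b <- runif(2, -1, 1); c0 <- runif(2, -1, 1)
    names(a) <- names(b) <- names(c0) <- c("env1", "env2")
    expect_equal(gfOffset(m, a, a), 0)
    expect_equal(gfOffset(m, a, b), gfOffset(m, b, a))
    expect_lte(gfOffset(m, a, c0),
               gfOffset(m, a, b) + gfOffset(m, b, c0) + 1e-12)
    expect_gte(gfOffset(m, a, b), 0)
  }
  expect_equal(gfOffset(m, c(env1 = -1, env2 = 0), c(env1 = 1, env2 = 0),
                        squared = TRUE),
               gfOffset(m, c(env1 = -1, env2 = 0), c(env1 = 1, env2 = 0))^2)
})

test_that("deterministic fits are invariant to a joint deme permutation", {
  set.seed(4)
  envs <- cbind(env1 = seq(-1, 1, length.out = 16),
                env2 = runif(16))
  freqs <- matrix(plogis(3 * envs[, 1]) + c(outer(rnorm(16, 0, 0.05),
                                                  rep(1, 2))), 16, 2,
                  dimnames = list(NULL, c("a", "b")))
  freqs <- pmin(pmax(freqs, 0), 1)
  m1 <- fitGF(freqs, envs, oracleParams(), seed = 5)
  perm <- sample(16)
  m2 <- fitGF(freqs[perm, ], envs[perm, ], oracleParams(), seed = 5)
  expect_equal(totalImportance(m1), totalImportance(m2), tolerance = 1e-12)
  expect_equal(aggregateTurnover(m1, "env1")@ci,
               aggregateTurnover(m2, "env1")@ci, tolerance = 1e-12)
})

test_that("predictor ranking is by weighted importance with lexical ties", {
  envs <- matrix(1:8, ncol = 1, dimnames = list(NULL, "only"))
  freqs <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 1,
                  dimnames = list(NULL, "snp"))
  m <- fitGF(freqs, envs, oracleParams(), seed = 1)
  expect_identical(rankPredictors(m), "only")

  # per-SNP substream seeds: refitting a subset reproduces the same R^2
  set.seed(31)
  envs2 <- cbind(env1 = runif(15), env2 = runif(15))
  freqs2 <- matrix(runif(45), 15, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  mAll <- fitGF(freqs2, envs2, gfParams(nTrees = 20L), seed = 9)
  mSub <- fitGF(freqs2[, "y", drop = FALSE], envs2,
                gfParams(nTrees = 20L), seed = 9)
  expect_equal(snpR2(mAll)[["y"]], snpR2(mSub)[["y"]], tolerance = 1e-12)
})
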