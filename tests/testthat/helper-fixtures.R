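# Shared fixtures. Heavy simulation replicates are cached in a session
# environment so several test files can reuse the same runs.

.runCache <- new.env(parent = emptyenv())

cachedRuns <- function(key, expr) {
  if (!exists(key, envir = .runCache)) assign(key, force(expr),
                                              envir = .runCache)
  get(key, envir = .runCache)
}

# a tiny configuration for fast unit-level simulations
tinyConfig <- function(...) {
  simConfig(mu = 5e-6, r = 1e-4, muQTN = 1e-4, nLG = 2L, sitesPerLG = 2000L,
            phaseGens = c(homogeneous = 20L, transition = 20L, stable = 20L),
            neutralGens = 40L, samplePerDeme = 5L, ...)
}

tinyMap <- function(nx = 4L, ny = 3L, size = 10L, m = 0.1) {
  metapopMap(nx, ny, size, m = m)
}

# light-weight case replicates: simulate, sample, CG fitness (no forest
# fits, no offset matrices) -- enough for local-adaptation checks
caseRunsLight <- function(scenario, n, masterSeed = 101L) {
  cachedRuns(sprintf("light_%s_%d_%d", scenario, n, masterSeed), {
    lapply(seq_len(n), function(rep) {
      sd <- replicateSeed(masterSeed, rep)
      run <- runScenario(scenario, "desk", seed = sd)
      smp <- sampleAndFilter(run, seed = sd + 1L)
      list(run = run, sample = smp, cg = cgFitnessMatrix(run, smp))
    })
  })
}

# full case1 pipelines (forest fits + all offset matrices + evaluation)
case1FullReps <- function(n, masterSeed = 101L) {
  cachedRuns(sprintf("full_case1_%d_%d", n, masterSeed), {
    lapply(seq_len(n), function(rep) {
      runScenarioPipeline("case1", "desk",
                          seed = replicateSeed(masterSeed, rep))
    })
  })
}

# neutral deme-size pipelines (forest fit on the causal gradient + the
# adjacent-shift offset / deme-size correlation)
q1Reps <- function(scheme, n, masterSeed = 202L) {
  cachedRuns(sprintf("q1_%s_%d_%d", scheme, n, masterSeed), {
    lapply(seq_len(n), function(rep) {
      runScenarioPipeline(paste0("q1_", scheme), "desk",
                          seed = replicateSeed(masterSeed, rep))
    })
  })
}

# maximum relative deviation of an aggregate turnover curve from the
# straight line through its endpoints, on a fixed evaluation grid
turnoverLinearDeviation <- function(tf, lo = -1, hi = 1) {
  x <- seq(lo, hi, length.out = 101L)
  ci <- evalTurnover(tf, x)
  total <- ci[length(ci)]
  line <- total * (x - lo) / (hi - lo)
  max(abs(ci - line)) / total
}
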