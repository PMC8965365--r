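# helper to build a minimal PopulationState by hand
makeState <- function(map, H, st, architecture = "neutral",
                      fixedEffect = c(0, 0)) {
  demeOf <- rep(seq_len(nDemes(map)), times = demeSizes(map))
  sizes <- demeSizes(map)
  sex <- unlist(lapply(sizes, function(n) rep_len(c(1L, 2L), n)))
  new("PopulationState", haplotypes = H, siteTable = st, demeOf = demeOf,
      sex = sex, generation = 0L, fixedEffect = fixedEffect,
      architecture = architecture)
}

siteRow <- function(id, lg, pos, type = "neutral", a1 = 0, a2 = 0) {
  data.frame(site_id = id, lg = lg, pos = as.numeric(pos), type = type,
             alpha1 = a1, alpha2 = a2, origin_generation = 0L,
             stringsAsFactors = FALSE)
}

test_that("stabilizing-selection fitness matches the Gaussian form", {
  expect_equal(fitnessMultilocus(0.3, -0.2, 0.3, -0.2, 1.25, 1.25), 1)
  expect_equal(fitnessMultilocus(1.25, 0, 0, 0, 1.25, 1.25), exp(-0.5))
  expect_equal(fitnessMultilocus(1.25, 4, 0, 0, 1.25, 4), exp(-1))
  expect_error(fitnessMultilocus(0, 0, 0, 0, 0, 1), "positive")
  # strength: smaller sigma means lower fitness at the same deviation
  expect_lt(fitnessMultilocus(1, 0, 0, 0, 1.25, 1.25),
            fitnessMultilocus(1, 0, 0, 0, 4, 4))
})

test_that("single-locus fitness is linear, antagonistic, and normalizable", {
  expect_equal(fitnessSingleLocus(2, 1, 0.45, normalize = FALSE), 1.45)
  expect_equal(fitnessSingleLocus(0, 1, 0.45, normalize = FALSE), 0.55)
  expect_equal(fitnessSingleLocus(1, 1, 0.45, normalize = FALSE), 1)
  expect_equal(fitnessSingleLocus(0:2, 0, 0.45), rep(1, 3))  # cline center
  E <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fitnessSingleLocus(2, E, 0.45, normalize = FALSE),
               fitnessSingleLocus(0, -E, 0.45, normalize = FALSE))
  expect_equal(fitnessSingleLocus(2, 0.5, 0.45), 1)  # best genotype = 1
  expect_error(fitnessSingleLocus(2, 1, 1.1), "non-positive")
})

test_that("initialization seeds the neutral frequency spectrum and exact occupancy", {
  map <- metapopMap(5, 2, 10, m = 0.1)
  cfg <- simConfig(mu = 1e-4, nLG = 2L, sitesPerLG = 2000L)
  st <- initState(map, cfg, "neutral", seed = 5)
  expect_identical(tabulate(demeOf(st), nDemes(map)), demeSizes(map))
  expect_identical(nrow(haplotypes(st)), 200L)

  # SFS shape: frequency of i-copy sites decreases roughly as 1/i
  counts <- colSums(haplotypes(st))
  tab <- tabulate(counts, nbins = 199L)
  i <- seq_len(60)
  expect_gt(cor(tab[i], 1 / i, method = "spearman"), 0.5)

  # zero mutation and empty init: no segregating sites ever
  cfg0 <- simConfig(mu = 0, nLG = 2L, sitesPerLG = 2000L)
  st0 <- initState(map, cfg0, "neutral", seed = 1)
  expect_identical(ncol(haplotypes(st0)), 0L)
  st0 <- stepGeneration(st0, map, cfg0)
  expect_identical(ncol(haplotypes(st0)), 0L)
})

test_that("drift without migration or selection preserves expected frequency", {
  map <- metapopMap(1, 1, 20, m = 0)
  st <- siteRow(1L, 1L, 100)
  H <- matrix(rep(c(0L, 1L), 20), 40, 1)  # frequency 1/2
  cfg <- simConfig(mu = 0, r = 1e-4, nLG = 1L, sitesPerLG = 1000L)
  base <- makeState(map, H, st)
  set.seed(42)
  freqs <- replicate(150, {
    nxt <- stepGeneration(base, map, cfg)
    if (ncol(haplotypes(nxt))) mean(haplotypes(nxt)) else 0.0
  })
  expect_equal(mean(freqs), 0.5, tolerance = 0.05)
  expect_identical(tabulate(demeOf(stepGeneration(base, map, cfg)), 1L), 20L)
})

test_that("reproduction fails loudly when a deme lacks one sex", {
  map <- metapopMap(1, 1, 4, m = 0)
  st <- siteRow(1L, 1L, 10)
  H <- matrix(0L, 8, 1)
  bad <- makeState(map, H, st)
  bad@sex <- rep(1L, 4)  # all female
  cfg <- simConfig(mu = 0, nLG = 1L, sitesPerLG = 100L)
  expect_error(stepGeneration(bad, map, cfg), "no members of one sex")
})

test_that("QTN mutations have the right effect distribution and never hit the reference group", {
  map <- metapopMap(2, 1, 50, m = 0.1)
  cfg <- simConfig(mu = 0, muQTN = 2.5e-3, sigmaQTN = 0.1, nLG = 2L,
                   sitesPerLG = 20000L)
  st0 <- initState(map, cfg, "multilocus", seed = 2)
  st1 <- stepGeneration(st0, map, cfg,
                        list(mode = "multilocus",
                             optima = matrix(0, 2, 2),
                             sigmaK = c(4, 4)))
  tab <- siteTable(st1)
  q <- tab[tab$type == "qtn", ]
  expect_gt(nrow(q), 3000)
  expect_true(all(q$lg == 1L))  # linkage group 2 is the neutral reference
  expect_lt(abs(sd(q$alpha1) - 0.1), 0.005)
  expect_lt(abs(sd(q$alpha2) - 0.1), 0.005)
  expect_lt(abs(cor(q$alpha1, q$alpha2)), 0.05)  # no covariance

  # muQTN = 0: no QTN ever arises
  cfg0 <- simConfig(mu = 1e-5, muQTN = 0, nLG = 2L, sitesPerLG = 2000L)
  s <- initState(map, cfg0, "multilocus", seed = 3)
  for (g in 1:5) s <- stepGeneration(s, map, cfg0,
                                     list(mode = "multilocus",
                                          optima = matrix(0, 2, 2),
                                          sigmaK = c(4, 4)))
  expect_identical(sum(siteTable(s)$type == "qtn"), 0L)
})

test_that("sampling and MAF filtering match a hand-enumerated fixture", {
  map <- metapopMap(5, 1, 2, m = 0)  # 10 diploids, 20 haplotypes, 5 demes
  H <- matrix(0L, 20, 3)
  H[1, 1] <- 1L                     # singleton: frequency 0.05
  H[c(3, 7), 2] <- 1L               # doubleton: frequency 0.10
  H[seq(1, 20, 2), 3] <- 1L         # frequency 0.50
  st <- rbind(siteRow(1L, 1L, 5), siteRow(2L, 1L, 50), siteRow(3L, 1L, 500))
  state <- makeState(map, H, st)
  cfg <- simConfig(mu = 0, nLG = 1L, sitesPerLG = 1000L,
                   mafThreshold = 0.05, samplePerDeme = 2L)
  smp <- sampleAndFilter(state, map, cfg, seed = 1)
  # 0.05 is at the threshold (dropped); 0.10 and 0.50 survive
  expect_identical(length(keptLoci(smp)), 2L)
  expect_equal(unname(smp@metapopFreqAll), c(0.05, 0.10, 0.50))
  expect_identical(dim(alleleFreqs(smp)), c(5L, 2L))
  expect_identical(nrow(genotypes(smp)), 10L)
  # every individual carries one copy at the 0.5-frequency site
  expect_true(all(genotypes(smp)[, 2] == 1L))

  cfg@samplePerDeme <- 5L
  expect_error(sampleAndFilter(state, map, cfg, seed = 1), "smaller")
})

test_that("additive-variance share matches hand arithmetic", {
  st <- rbind(siteRow(1L, 1L, 1, "qtn", a1 = 1, a2 = 1),
              siteRow(2L, 1L, 2, "qtn", a1 = 2, a2 = 2))
  sh <- additiveVarianceShare(st, p = c(0.5, 0.1), kept = 1L)
  # 0.25 / (0.25 + 0.36)
  expect_equal(unname(sh), rep(0.25 / 0.61, 2), tolerance = 1e-12)
  expect_equal(1^2 * 0.5 * 0.5, 0.25)  # per-locus contribution at p = 1/2
  expect_error(additiveVarianceShare(st, p = c(0, 1), kept = 1L), "zero")
})

test_that("the single-locus scenario evolves a monotone allele-frequency cline", {
  run <- cachedRuns("single_locus_7", runScenario("single_locus", "desk",
                                                  seed = 7))
  sel <- which(run$state@siteTable$type == "selected")
  expect_length(sel, 1L)
  H <- haplotypes(run$state)
  hapDeme <- rep(demeOf(run$state), each = 2L)
  p <- tapply(H[, sel], hapDeme, mean)
  env <- envValues(run$envFields[[1]])
  expect_gt(abs(cor(p, env, method = "spearman")), 0.9)
  # derived allele at high frequency where beneficial, low where harmful
  expect_gt(mean(p[env > 0.5]), mean(p[env < -0.5]))
})

test_that("VCF export round-trips through a standard reader", {
  map <- tinyMap()
  cfg <- tinyConfig()
  st <- initState(map, cfg, "neutral", seed = 11)
  for (g in 1:10) st <- stepGeneration(st, map, cfg)
  smp <- sampleAndFilter(st, map, cfg, seed = 12)
  path <- tempfile(fileext = ".vcf")
  writeVCF(smp, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_identical(nrow(v@gt), length(keptLoci(smp)))
  expect_identical(ncol(v@gt) - 1L, nrow(genotypes(smp)))
  gt <- v@gt[, -1, drop = FALSE]
  dos <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt))
  expect_equal(unname(rowSums(dos)), unname(colSums(genotypes(smp))))
})

test_that("neutral heterozygosity sits at mutation-drift balance with no late trend", {
  map <- metapopMap(5, 2, 10, m = 0.1)
  cfg <- simConfig(mu = 5e-5, r = 1e-4, nLG = 2L, sitesPerLG = 2000L)
  slopes <- vapply(1:6, function(rep) {
    st <- initState(map, cfg, "neutral", seed = 300 + rep)
    H <- numeric(0)
    for (g in 1:100) {
      st <- stepGeneration(st, map, cfg)
      if (g > 90) {
        p <- colMeans(haplotypes(st))
        H <- c(H, sum(2 * p * (1 - p)))
      }
    }
    unname(coef(lm(H ~ seq_along(H)))[2] / mean(H))  # relative trend
  }, numeric(1))
  # stationary: across replicates the mean late trend is zero
  expect_gt(stats::t.test(slopes)$p.value, 0.05)
  expect_lt(abs(mean(slopes)), 0.02)  # < 2% change in H per generation
})
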