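#' Scenario setup: map, configuration, and environments
#'
#' Assembles everything a scenario run needs. Two presets are shipped:
#' `"full"` is the full-scale reference configuration (10x10 grid, 100
#' per deme or the deme-size schemes, 10 linkage groups of 50,000 sites,
#' 3 x 1000-generation multilocus phases) and `"desk"` a reduced
#' configuration for interactive work and continuous testing (multilocus:
#' 5x5 grid, 20 per deme, 2 linkage groups of 5,000 sites, 3 x 100
#' generations; neutral deme-size scenarios: the 10x10 grid at half deme
#' sizes, 2 linkage groups of 12,500 sites, 150 generations; per-site
#' mutation and recombination rates are rescaled so the population-scaled
#' products N*mu and N*r match the full-scale values).
#'
#' Migration: m = 0.2 for the multilocus cases, m = 0.05 for the
#' single-locus and neutral scenarios.
#'
#' @param scenario scenario name (see [runScenario()]).
#' @param preset "desk" or "full".
#' @param config,map optional overrides.
#' @return list(map, config, envFields, architecture).
#' @export
scenarioSetup <- function(scenario, preset = c("desk", "full"),
                          config = NULL, map = NULL) {
  preset <- match.arg(preset)
  q1 <- grepl("^q1_", scenario)
  arch <- if (q1) "neutral" else if (scenario == "single_locus")
    "single_locus" else "multilocus"
  m <- if (arch == "multilocus") 0.2 else 0.05

  if (is.null(map)) {
    map <- if (q1) {
      scheme <- sub("^q1_", "", scenario)
      scale <- if (preset == "desk") 0.5 else 1
      sizes <- buildDemeSizes(scheme, 10L, 10L, scale = scale)
      metapopMap(10L, 10L, sizes, m = m)
    } else if (preset == "desk") {
      metapopMap(5L, 5L, 20L, m = m)
    } else {
      metapopMap(10L, 10L, 100L, m = m)
    }
  }

  if (is.null(config)) {
    N <- sum(demeSizes(map))
    sigmaK <- if (scenario == "case4") c(1.25, 4.0) else c(1.25, 1.25)
    config <- if (preset == "full") {
      simConfig(sigmaK = sigmaK)
    } else {
      # rescale rates so N*mu and N*r match the full-scale products; the
      # neutral deme-size scenarios carry a larger genome (2 x 12,500
      # sites) so enough MAF-filtered SNPs remain for the per-replicate
      # drift signal, and run 150 generations (differentiation is
      # stationary well before that at these deme sizes)
      f <- 10000 / N
      simConfig(mu = 1e-7 * f, r = 1e-5 * f, muQTN = 2.5e-6 * f,
                sigmaK = sigmaK, nLG = 2L,
                sitesPerLG = if (q1) 12500L else 5000L,
                phaseGens = c(homogeneous = 100L, transition = 100L,
                              stable = 100L),
                neutralGens = if (q1) 120L else 300L,
                samplePerDeme = if (q1) 5L else 10L)
    }
  }

  envFields <- if (arch == "multilocus") {
    e1 <- switch(scenario,
      case2 = nonmonotonicGradient(-1, 1, "columns", map, "env1"),
      linearGradient(-1, 1, "columns", map, "env1"))
    e2 <- switch(scenario,
      case2 = nonmonotonicGradient(-1, 1, "rows", map, "env2"),
      case3 = linearGradient(-0.25, 0.25, "rows", map, "env2"),
      linearGradient(-1, 1, "rows", map, "env2"))
    list(e1, e2)
  } else {
    list(linearGradient(-1, 1, "columns", map, "env1"))
  }

  list(map = map, config = config, envFields = envFields,
       architecture = arch)
}

#' Run a full scenario pipeline
#'
#' Simulate, sample and MAF-filter, build the decoy environments, fit the
#' turnover engine, compute every offset matrix, build the common-garden
#' fitness matrix, and evaluate offset-fitness correlations. For the
#' neutral deme-size scenarios the pipeline instead fits the engine on the
#' causal gradient and reports the adjacent-shift offset vs. deme-size
#' correlation.
#'
#' Offset variants for selected architectures: GF Offset from all kept
#' loci with all 14 environments and with the causal environments only,
#' GF Offset from causal loci (both environment sets), F_ST genome and
#' causal, and Euclidean/Mahalanobis environmental distance over all or
#' causal environments.
#'
#' @param scenario scenario name.
#' @param preset "desk" or "full".
#' @param seed integer seed for the whole pipeline.
#' @param gf a [gfParams()] list; NULL uses 100 trees for the desk preset
#'   and 500 for the full preset.
#' @param config,map optional overrides forwarded to [runScenario()].
#' @param outDir optional output directory; when given, VCF, TSV and JSON
#'   artifacts are written and listed in a checksum manifest.
#' @return list with elements depending on the scenario: always `run`,
#'   `sample`, `models`; for selected architectures `offsets` (named list
#'   of [OffsetMatrix-class]), `cg`, `localAdaptation`, `evaluation`; for
#'   neutral scenarios `q1` (see [q1OffsetVsDemesize()]).
#' @export
runScenarioPipeline <- function(scenario, preset = c("desk", "full"),
                                seed = 1L, gf = NULL, config = NULL,
                                map = NULL, outDir = NULL) {
  preset <- match.arg(preset)
  if (is.null(gf)) {
    # neutral single-gradient fits are insensitive to ensemble size
    # (50 vs 500 trees moved the offset/deme-size correlation by < 0.03
    # in pilots), so the desk preset uses a smaller forest there
    nt <- if (preset != "desk") 500L else
      if (grepl("^q1_", scenario)) 50L else 100L
    gf <- gfParams(nTrees = nt)
  }
  run <- runScenario(scenario, preset, seed = seed, config = config,
                     map = map)
  sample <- sampleAndFilter(run, seed = seed + 1L)
  out <- list(run = run, sample = sample)

  if (run$state@architecture == "neutral") {
    envs <- envMatrix(run$envFields)
    model <- fitGF(alleleFreqs(sample), envs, params = gf, seed = seed + 2L)
    out$models <- list(causal_env = model)
    out$q1 <- q1OffsetVsDemesize(model, run$envFields[[1]], run$map)
  } else {
    decoys <- makeDecoyEnvs(run$envFields, seed = seed + 2L)
    fields <- c(run$envFields, decoys)
    envsAll <- envMatrix(fields)
    causalFlags <- vapply(fields, isCausal, logical(1))
    envsCausal <- envsAll[, causalFlags, drop = FALSE]

    st <- sample@siteTableAll
    causalLoci <- which(st$type[keptLoci(sample)] %in% c("qtn", "selected"))
    freqAll <- alleleFreqs(sample)

    models <- list(
      genome_all = fitGF(freqAll, envsAll, gf, seed = seed + 3L),
      genome_causal = fitGF(freqAll, envsCausal, gf, seed = seed + 3L))
    if (length(causalLoci)) {
      freqCausal <- freqAll[, causalLoci, drop = FALSE]
      models$causal_all <- fitGF(freqCausal, envsAll, gf, seed = seed + 3L)
      models$causal_causal <- fitGF(freqCausal, envsCausal, gf,
                                    seed = seed + 3L)
    }
    out$models <- models

    offsets <- list(
      gf_genome_all_env = gfOffsetMatrix(models$genome_all, envsAll,
                                         "genome_all_env"),
      gf_genome_causal_env = gfOffsetMatrix(models$genome_causal,
                                            envsCausal,
                                            "genome_causal_env"),
      fst_genome = fstMatrix(sample, "genome"),
      fst_causal = fstMatrix(sample, "causal"),
      ed_all = envDistanceMatrix(fields, "euclidean", "all"),
      ed_causal = envDistanceMatrix(fields, "euclidean", "causal"),
      md_all = envDistanceMatrix(fields, "mahalanobis", "all"),
      md_causal = envDistanceMatrix(fields, "mahalanobis", "causal"))
    if (length(causalLoci)) {
      offsets$gf_causal_all_env <-
        gfOffsetMatrix(models$causal_all, envsAll, "causal_all_env")
      offsets$gf_causal_causal_env <-
        gfOffsetMatrix(models$causal_causal, envsCausal,
                       "causal_causal_env")
    }
    out$offsets <- offsets
    out$cg <- cgFitnessMatrix(run, sample)
    out$localAdaptation <- localAdaptation(out$cg)
    out$evaluation <- evaluateOffsets(offsets, out$cg, run$map)
    out$fields <- fields
  }

  if (!is.null(outDir)) out$manifest <- writeBundle(out, outDir)
  out
}

#' Run replicated scenario pipelines
#'
#' Replicate seeds are derived deterministically from the master seed, so
#' a fixed master seed reproduces the full result set.
#'
#' @param scenario scenario name.
#' @param preset "desk" or "full".
#' @param replicates number of replicates (>= 1).
#' @param masterSeed master integer seed.
#' @param gf optional [gfParams()].
#' @param outDir optional output directory (per-replicate subdirectories).
#' @return list of [runScenarioPipeline()] bundles.
#' @export
runAll <- function(scenario, preset = c("desk", "full"), replicates = 10L,
                   masterSeed = 1L, gf = NULL, outDir = NULL) {
  preset <- match.arg(preset)
  if (replicates < 1L) stop("replicate count must be >= 1")
  lapply(seq_len(replicates), function(rep) {
    sd <- replicateSeed(masterSeed, rep)
    od <- if (is.null(outDir)) NULL else
      file.path(outDir, sprintf("rep%02d", rep))
    runScenarioPipeline(scenario, preset, seed = sd, gf = gf, outDir = od)
  })
}

#' Derive a replicate seed from a master seed
#'
#' @param masterSeed master integer seed.
#' @param rep replicate index (1-based).
#' @return a 32-bit-safe integer seed.
#' @export
replicateSeed <- function(masterSeed, rep) {
  as.integer((as.numeric(masterSeed) + 7919 * rep) %% 2147480009)
}

#' Save / load a run configuration
#'
#' YAML round-trip of the scenario, preset, replicate count, master seed
#' and engine parameters, so a run is fully reproducible from its config
#' file.
#'
#' @param config list with fields scenario, preset, replicates,
#'   masterSeed, gf (a [gfParams()] list).
#' @param path YAML path.
#' @return `path` (save) or the config list (load).
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  path
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$gf)) cfg$gf <- do.call(gfParams, cfg$gf)
  cfg
}
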