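#' Forward-simulation configuration
#'
#' Constructor for [SimConfig-class]; defaults are the full-scale reference
#' parameterization (see the class documentation).
#'
#' @param mu neutral per-site mutation rate.
#' @param r per-adjacent-site recombination rate.
#' @param muQTN QTN per-site mutation rate.
#' @param sigmaQTN sd of bivariate QTN effects.
#' @param sigmaS burn-in stabilizing-selection width.
#' @param sigmaK post-burn-in widths, one per trait.
#' @param d single-locus fitness slope.
#' @param nLG,sitesPerLG genome layout.
#' @param phaseGens lengths of the homogeneous, transition, and stable
#'   phases of multilocus runs.
#' @param neutralGens generations for neutral/single-locus runs.
#' @param mafThreshold MAF cutoff (loci with metapopulation MAF at or
#'   below it are dropped).
#' @param samplePerDeme individuals sampled per deme.
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig()
#' cfg@mu * 10000          # metapopulation-scaled mutation rate 0.001
#' @export
simConfig <- function(mu = 1e-7, r = 1e-5, muQTN = 2.5e-6, sigmaQTN = 0.1,
                      sigmaS = 4.0, sigmaK = c(1.25, 1.25), d = 0.45,
                      nLG = 10L, sitesPerLG = 50000L,
                      phaseGens = c(homogeneous = 1000L, transition = 1000L,
                                    stable = 1000L),
                      neutralGens = 1000L, mafThreshold = 0.01,
                      samplePerDeme = 10L) {
  if (length(sigmaK) == 1L) sigmaK <- rep(sigmaK, 2L)
  pg <- as.integer(phaseGens)
  names(pg) <- c("homogeneous", "transition", "stable")
  new("SimConfig", mu = mu, r = r, muQTN = muQTN, sigmaQTN = sigmaQTN,
      sigmaS = sigmaS, sigmaK = sigmaK, d = d, nLG = as.integer(nLG),
      sitesPerLG = as.integer(sitesPerLG), phaseGens = pg,
      neutralGens = as.integer(neutralGens), mafThreshold = mafThreshold,
      samplePerDeme = as.integer(samplePerDeme))
}

#' Gaussian stabilizing-selection fitness (two traits)
#'
#' Relative fitness of an individual whose phenotypes (P1, P2) deviate
#' from the local bivariate optimum (theta1, theta2):
#' `w = exp(-0.5 * (((P1-theta1)/sigmaK1)^2 + ((P2-theta2)/sigmaK2)^2))`.
#' Because `w = 1` exactly at the optimum, relative fitness is already
#' normalized by its maximum.
#'
#' @param P1,P2 phenotypes (vectorized).
#' @param theta1,theta2 local optima.
#' @param sigmaK1,sigmaK2 stabilizing-selection widths (> 0); smaller
#'   values mean stronger selection.
#' @return relative fitness in (0, 1].
#' @examples
#' fitnessMultilocus(0, 0, 0, 0, 1.25, 1.25)        # 1
#' fitnessMultilocus(1.25, 0, 0, 0, 1.25, 1.25)     # exp(-1/2)
#' @export
fitnessMultilocus <- function(P1, P2, theta1, theta2, sigmaK1,
                              sigmaK2 = sigmaK1) {
  if (sigmaK1 <= 0 || sigmaK2 <= 0) stop("sigmaK must be positive")
  exp(-0.5 * (((P1 - theta1) / sigmaK1)^2 + ((P2 - theta2) / sigmaK2)^2))
}

#' Antagonistically pleiotropic single-locus fitness
#'
#' Linear fitness-by-environment map for the monogenic model: with `g`
#' copies of the derived allele A, `w = 1 + d * E * (g - 1)`, i.e.
#' w(aa) = 1 - dE, w(Aa) = 1, w(AA) = 1 + dE. Each homozygote is favored
#' at one end of the gradient and disfavored at the other. With
#' `normalize = TRUE` fitness is rescaled by the local maximum
#' (`1 + |d * E|`) so the best genotype has relative fitness 1.
#'
#' @param genotype copies of the derived allele (0, 1, or 2; vectorized).
#' @param E environmental value in \[-1, 1\].
#' @param d fitness slope.
#' @param normalize rescale by the within-environment maximum.
#' @return fitness (relative fitness when normalized).
#' @examples
#' fitnessSingleLocus(2, 1, 0.45, normalize = FALSE)  # 1.45
#' fitnessSingleLocus(0, 1, 0.45, normalize = FALSE)  # 0.55
#' @export
fitnessSingleLocus <- function(genotype, E, d, normalize = TRUE) {
  if (any(abs(d * E) >= 1))
    stop("|d * E| >= 1 would give non-positive fitness")
  w <- 1 + d * E * (genotype - 1)
  if (normalize) w <- w / (1 + abs(d * E))
  w
}

# ---- internal state helpers -------------------------------------------

.emptySiteTable <- function() {
  data.frame(site_id = integer(0), lg = integer(0), pos = numeric(0),
             type = character(0), alpha1 = numeric(0), alpha2 = numeric(0),
             origin_generation = integer(0), stringsAsFactors = FALSE)
}

.sortState <- function(H, st) {
  ord <- order(st$lg, st$pos)
  list(H = H[, ord, drop = FALSE], st = st[ord, , drop = FALSE])
}

.balancedSex <- function(sizes) {
  unlist(lapply(sizes, function(n) rep_len(c(1L, 2L), n)), use.names = FALSE)
}

#' Per-individual phenotypes
#'
#' Additive phenotypes: dosage at QTN sites times their bivariate effects,
#' plus the accumulated offset of fixed QTNs. No dominance, no
#' environmental noise.
#'
#' @param state a [PopulationState-class].
#' @return N x 2 phenotype matrix.
#' @export
phenotypes <- function(state) {
  N <- length(state@demeOf)
  st <- state@siteTable
  qtn <- which(st$type == "qtn")
  P <- matrix(rep(state@fixedEffect, each = N), N, 2)
  if (length(qtn)) {
    P <- P + hap_phenotypes_cpp(state@haplotypes, st$alpha1, st$alpha2)
  }
  colnames(P) <- c("P1", "P2")
  P
}

#' Initialize standing variation
#'
#' Seeds the metapopulation with stationary neutral standing variation in
#' place of a coalescent history: the number of segregating sites is drawn
#' at the `theta = 4 N mu L` expectation (times the harmonic number of
#' 2N - 1), each site's metapopulation frequency is drawn from the neutral
#' site-frequency spectrum (probability proportional to 1/i for i copies),
#' and alleles are then assigned binomially across haplotypes. For the
#' single-locus architecture the derived allele A is additionally seeded at
#' low frequency (0.1) in the demes where it is beneficial (E > 0).
#'
#' @param map a [MetapopMap-class].
#' @param config a [SimConfig-class].
#' @param architecture "neutral", "single_locus", or "multilocus".
#' @param seed integer seed.
#' @param env [EnvField-class] used to place the seeded A allele
#'   (single-locus architecture only).
#' @return a [PopulationState-class].
#' @export
initState <- function(map, config,
                      architecture = c("neutral", "single_locus",
                                       "multilocus"),
                      seed = 1L, env = NULL) {
  architecture <- match.arg(architecture)
  set.seed(seed)
  N <- sum(map@demeSizes)
  twoN <- 2L * N
  demeOf <- rep(seq_len(nDemes(map)), times = map@demeSizes)
  sex <- .balancedSex(map@demeSizes)
  L <- config@nLG * config@sitesPerLG

  theta <- 4 * N * config@mu * L
  aH <- sum(1 / seq_len(twoN - 1L))
  S0 <- rpois(1L, theta * aH)
  S0 <- min(S0, L)
  if (S0 > 0L) {
    i <- sample.int(twoN - 1L, S0, replace = TRUE,
                    prob = 1 / seq_len(twoN - 1L))
    p <- i / twoN
    key <- sample.int(L, S0)  # unique genome positions
    H <- matrix(rbinom(twoN * S0, 1L, rep(p, each = twoN)), nrow = twoN)
    st <- data.frame(site_id = seq_len(S0),
                     lg = (key - 1L) %/% config@sitesPerLG + 1L,
                     pos = as.numeric((key - 1L) %% config@sitesPerLG),
                     type = "neutral", alpha1 = 0, alpha2 = 0,
                     origin_generation = 0L, stringsAsFactors = FALSE)
    cs <- colSums(H)
    keep <- cs > 0L & cs < twoN
    H <- H[, keep, drop = FALSE]
    st <- st[keep, , drop = FALSE]
  } else {
    H <- matrix(0L, twoN, 0L)
    st <- .emptySiteTable()
  }

  if (architecture == "single_locus") {
    if (is.null(env)) stop("single-locus initialization needs an env field")
    selPos <- floor(config@sitesPerLG / 2)
    keep2 <- !(st$lg == 1L & st$pos == selPos)
    st <- st[keep2, , drop = FALSE]
    H <- H[, keep2, drop = FALSE]
    benef <- env@values[demeOf] > 0
    col <- integer(twoN)
    hapBenef <- rep(benef, each = 2L)
    col[hapBenef] <- rbinom(sum(hapBenef), 1L, 0.1)
    H <- cbind(H, col)
    st <- rbind(st, data.frame(site_id = max(st$site_id, 0L) + 1L, lg = 1L,
                               pos = as.numeric(selPos), type = "selected",
                               alpha1 = 0, alpha2 = 0,
                               origin_generation = 0L,
                               stringsAsFactors = FALSE))
  }

  srt <- .sortState(H, st)
  new("PopulationState", haplotypes = srt$H, siteTable = srt$st,
      demeOf = demeOf, sex = sex, generation = 0L,
      fixedEffect = c(0, 0), architecture = architecture)
}

# fitness of the current individuals under the given selection regime
.parentFitness <- function(state, selection) {
  N <- length(state@demeOf)
  if (is.null(selection)) return(rep(1, N))
  if (selection$mode == "multilocus") {
    P <- phenotypes(state)
    th <- selection$optima[state@demeOf, , drop = FALSE]
    fitnessMultilocus(P[, 1], P[, 2], th[, 1], th[, 2],
                      selection$sigmaK[1], selection$sigmaK[2])
  } else if (selection$mode == "single_locus") {
    sel <- which(state@siteTable$type == "selected")
    if (length(sel) != 1L) stop("no selected locus in state")
    H <- state@haplotypes
    g <- H[seq(1L, 2L * N, by = 2L), sel] + H[seq(2L, 2L * N, by = 2L), sel]
    fitnessSingleLocus(g, selection$E[state@demeOf], selection$d,
                       normalize = FALSE)
  } else stop("unknown selection mode")
}

#' Advance the metapopulation one Wright-Fisher generation
#'
#' Event order: migration (each offspring draws both parents from one
#' uniformly chosen adjacent deme with probability m, otherwise from its
#' own deme), fitness-weighted bi-parental reproduction within the source
#' deme (one mother, one father, drawn proportionally to relative
#' fitness), recombination (Poisson crossovers within linkage groups,
#' free recombination between them), and mutation (neutral everywhere,
#' QTNs on linkage groups 1..nLG-1 for the multilocus architecture). Deme
#' sizes are restored exactly each generation. Sites fixed or lost are
#' pruned; fixed QTN effects are folded into the phenotype offset.
#'
#' @param state a [PopulationState-class].
#' @param map a [MetapopMap-class].
#' @param config a [SimConfig-class].
#' @param selection NULL for neutral evolution, or a list: for the
#'   multilocus architecture `list(mode = "multilocus", optima =
#'   <demes x 2>, sigmaK = <length 2>)`; for the single-locus architecture
#'   `list(mode = "single_locus", E = <per-deme env>, d = <slope>)`.
#' @return the next-generation [PopulationState-class].
#' @export
stepGeneration <- function(state, map, config, selection = NULL) {
  N <- length(state@demeOf)
  twoN <- 2L * N
  nd <- nDemes(map)
  adj <- map@adjacency
  m <- map@migrationRate

  w <- .parentFitness(state, selection)

  # migration: choice of source deme per offspring
  src <- state@demeOf
  if (m > 0) {
    mig <- which(runif(N) < m)
    if (length(mig)) {
      src[mig] <- vapply(src[mig], function(d) {
        nb <- adj[[d]]
        nb[sample.int(length(nb), 1L)]
      }, integer(1))
    }
  }

  # fitness-weighted bi-parental sampling within source demes
  demeMembers <- split(seq_len(N), state@demeOf)
  fem <- lapply(demeMembers, function(ix) ix[state@sex[ix] == 1L])
  mal <- lapply(demeMembers, function(ix) ix[state@sex[ix] == 2L])
  mother <- integer(N); father <- integer(N)
  for (d in unique(src)) {
    off <- which(src == d)
    f <- fem[[d]]; ma <- mal[[d]]
    if (!length(f) || !length(ma))
      stop(sprintf("deme %d has no members of one sex: reproduction failed", d))
    wf <- w[f]; wm <- w[ma]
    if (sum(wf) <= 0 || sum(wm) <= 0)
      stop(sprintf("deme %d has zero total fitness", d))
    mother[off] <- f[sample.int(length(f), length(off), replace = TRUE,
                                prob = wf)]
    father[off] <- ma[sample.int(length(ma), length(off), replace = TRUE,
                                 prob = wm)]
  }

  # draw this generation's new mutations up front so the offspring matrix
  # (inherited plus new sites, in genome order) is built in one pass
  st <- state@siteTable
  L <- config@nLG * config@sitesPerLG
  gen <- state@generation + 1L
  nNeut <- rpois(1L, twoN * config@mu * L)
  nQ <- if (state@architecture == "multilocus" && config@nLG > 1L) {
    rpois(1L, twoN * config@muQTN * (config@nLG - 1L) * config@sitesPerLG)
  } else 0L
  keyN <- if (nNeut > 0L) sample.int(L, nNeut, replace = TRUE) else integer(0)
  keyQ <- if (nQ > 0L) {
    sample.int((config@nLG - 1L) * config@sitesPerLG, nQ, replace = TRUE)
  } else integer(0)
  key <- c(keyN, keyQ)
  type <- c(rep("neutral", nNeut), rep("qtn", nQ))
  active <- (st$lg - 1L) * config@sitesPerLG + st$pos + 1L
  ok <- !(key %in% active) & !duplicated(key)
  key <- key[ok]; type <- type[ok]
  nNew <- length(key)
  if (nNew) {
    a1 <- a2 <- numeric(nNew)
    isQ <- type == "qtn"
    if (any(isQ)) {
      a1[isQ] <- rnorm(sum(isQ), 0, config@sigmaQTN)
      a2[isQ] <- rnorm(sum(isQ), 0, config@sigmaQTN)
    }
    nextId <- if (nrow(st)) max(st$site_id) else 0L
    st <- rbind(st, data.frame(site_id = nextId + seq_len(nNew),
                               lg = (key - 1L) %/% config@sitesPerLG + 1L,
                               pos = as.numeric((key - 1L) %%
                                                  config@sitesPerLG),
                               type = type, alpha1 = a1, alpha2 = a2,
                               origin_generation = gen,
                               stringsAsFactors = FALSE))
  }
  nOld <- ncol(state@haplotypes)
  parentCol <- c(seq_len(nOld), rep(NA_integer_, nNew))
  mutHap <- c(rep(NA_integer_, nOld),
              if (nNew) sample.int(twoN, nNew, replace = TRUE) else integer(0))
  ord <- order(st$lg, st$pos)
  st <- st[ord, , drop = FALSE]
  parentCol <- parentCol[ord]; mutHap <- mutHap[ord]

  lambda <- rep(config@r * (config@sitesPerLG - 1L), config@nLG)
  lgLen <- rep(as.numeric(config@sitesPerLG - 1L), config@nLG)
  H <- if (nrow(st)) {
    wf_meiosis_cpp(state@haplotypes, mother - 1L, father - 1L,
                   st$lg, st$pos, lambda, lgLen,
                   as.integer(ifelse(is.na(parentCol), -1L, parentCol - 1L)),
                   as.integer(ifelse(is.na(mutHap), -1L, mutHap - 1L)))
  } else {
    matrix(0L, twoN, 0L)
  }

  # prune fixed / lost sites (the selected locus is always retained)
  fixedEffect <- state@fixedEffect
  if (ncol(H)) {
    cs <- colSums(H)
    lost <- cs == 0L & st$type != "selected"
    fixed <- cs == twoN & st$type != "selected"
    if (any(fixed)) {
      fq <- fixed & st$type == "qtn"
      if (any(fq)) {
        fixedEffect <- fixedEffect +
          c(2 * sum(st$alpha1[fq]), 2 * sum(st$alpha2[fq]))
      }
    }
    keep <- !(lost | fixed)
    if (!all(keep)) {
      H <- H[, keep, drop = FALSE]
      st <- st[keep, , drop = FALSE]
    }
  }

  initialize(state, haplotypes = H, siteTable = st,
             generation = gen, fixedEffect = fixedEffect)
}

#' Run a complete scenario
#'
#' Builds the map and environments for one of the named study scenarios
#' and runs it to completion. Neutral (`q1_*`) and single-locus scenarios
#' run `neutralGens` generations to quasi-equilibrium; multilocus cases run
#' three phases: a homogeneous burn-in with every optimum at 0 and width
#' `sigmaS`, a transition burn-in with optima interpolated linearly toward
#' their final clines (still at width `sigmaS`), and a stable phase on the
#' final clines at widths `sigmaK`.
#'
#' Scenario environments: `case1` has two orthogonal linear clines on
#' -1..1; `case2` two orthogonal nonmonotonic ("tent") clines; `case3` is
#' case1 with the second cline narrowed to -0.25..0.25; `case4` is case1
#' with weak stabilizing selection (width 4.0) on trait 2. Neutral and
#' single-locus scenarios use a single -1..1 column cline.
#'
#' @param scenario scenario name.
#' @param preset "desk" (reduced scale) or "full" (reference scale).
#' @param seed integer seed.
#' @param config optional [SimConfig-class] overriding the preset.
#' @param map optional [MetapopMap-class] overriding the preset.
#' @param verbose print phase progress.
#' @return list with elements `state` ([PopulationState-class]), `map`,
#'   `envFields` (causal [EnvField-class]s), `config`, `scenario`,
#'   `preset`, `seed`.
#' @export
runScenario <- function(scenario = c("q1_equal", "q1_increasing",
                                     "q1_decreasing", "single_locus",
                                     "case1", "case2", "case3", "case4"),
                        preset = c("desk", "full"), seed = 1L,
                        config = NULL, map = NULL, verbose = FALSE) {
  scenario <- match.arg(scenario)
  preset <- match.arg(preset)
  setup <- scenarioSetup(scenario, preset, config = config, map = map)
  config <- setup$config; map <- setup$map
  arch <- setup$architecture

  env1 <- if (arch == "single_locus" || arch == "neutral")
    setup$envFields[[1]] else NULL
  state <- initState(map, config, architecture = arch, seed = seed,
                     env = env1)

  if (arch %in% c("neutral", "single_locus")) {
    selection <- if (arch == "single_locus") {
      list(mode = "single_locus", E = env1@values, d = config@d)
    } else NULL
    for (g in seq_len(config@neutralGens)) {
      state <- stepGeneration(state, map, config, selection)
      if (verbose && g %% 100L == 0L)
        message(sprintf("  generation %d / %d", g, config@neutralGens))
    }
  } else {
    final <- cbind(setup$envFields[[1]]@values, setup$envFields[[2]]@values)
    pg <- config@phaseGens
    zero <- matrix(0, nDemes(map), 2L)
    sigS <- rep(config@sigmaS, 2L)
    for (g in seq_len(pg["homogeneous"])) {
      state <- stepGeneration(state, map, config,
                              list(mode = "multilocus", optima = zero,
                                   sigmaK = sigS))
    }
    if (verbose) message("  homogeneous burn-in done")
    for (g in seq_len(pg["transition"])) {
      opt <- final * (g / pg[["transition"]])
      state <- stepGeneration(state, map, config,
                              list(mode = "multilocus", optima = opt,
                                   sigmaK = sigS))
    }
    if (verbose) message("  transition burn-in done")
    for (g in seq_len(pg["stable"])) {
      state <- stepGeneration(state, map, config,
                              list(mode = "multilocus", optima = final,
                                   sigmaK = config@sigmaK))
    }
    if (verbose) message("  stable phase done")
  }

  list(state = state, map = map, envFields = setup$envFields,
       config = config, scenario = scenario, preset = preset, seed = seed)
}

#' Sample individuals and apply the MAF filter
#'
#' Randomly samples `samplePerDeme` diploids from every deme, computes
#' metapopulation allele frequencies on the sampled individuals, drops loci
#' whose minor-allele frequency is at or below `mafThreshold`, and
#' recomputes per-deme frequencies on the kept loci.
#'
#' @param run a list as returned by [runScenario()], or a
#'   [PopulationState-class] (then `map` and `config` are required).
#' @param map,config used when `run` is a bare state.
#' @param seed integer seed.
#' @return a [DemeSample-class].
#' @export
sampleAndFilter <- function(run, map = NULL, config = NULL, seed = 1L) {
  if (is.list(run)) {
    state <- run$state; map <- run$map; config <- run$config
  } else state <- run
  stopifnot(is(state, "PopulationState"), is(map, "MetapopMap"),
            is(config, "SimConfig"))
  set.seed(seed)
  k <- config@samplePerDeme
  if (any(map@demeSizes < k))
    stop("a deme is smaller than the per-deme sample size")
  ids <- unlist(lapply(seq_len(nDemes(map)), function(d) {
    members <- which(state@demeOf == d)
    members[sample.int(length(members), k)]
  }), use.names = FALSE)

  H <- state@haplotypes
  G <- H[2L * ids - 1L, , drop = FALSE] + H[2L * ids, , drop = FALSE]
  st <- state@siteTable
  colnames(G) <- paste0("s", st$site_id)
  pAll <- colMeans(G) / 2
  maf <- pmin(pAll, 1 - pAll)
  kept <- which(maf > config@mafThreshold)

  demeOfS <- state@demeOf[ids]
  Gk <- G[, kept, drop = FALSE]
  freqs <- rowsum(Gk, demeOfS) / (2 * k)

  phen <- selG <- NULL
  if (state@architecture == "multilocus") {
    phen <- phenotypes(state)[ids, , drop = FALSE]
  } else if (state@architecture == "single_locus") {
    sel <- which(st$type == "selected")
    selG <- as.numeric(G[, sel])
  }

  new("DemeSample", genotypes = Gk, demeOf = demeOfS, freqs = freqs,
      keptLoci = as.integer(kept), metapopFreqAll = pAll,
      siteTableAll = st, phenotypes = phen, selGenotype = selG)
}

#' Share of additive genetic variance retained by the MAF filter
#'
#' The additive variance contributed by QTN locus i to trait j is
#' approximated as `alpha_ij^2 * p_i * (1 - p_i)` with p the
#' metapopulation frequency after sampling. The share is the summed
#' contribution of kept QTN loci over that of all QTN loci, per trait.
#'
#' @param x a [DemeSample-class], or a site table data.frame.
#' @param p metapopulation frequencies per locus (when `x` is a table).
#' @param kept indices of kept loci (when `x` is a table).
#' @return named length-2 numeric (trait1, trait2).
#' @export
additiveVarianceShare <- function(x, p = NULL, kept = NULL) {
  if (is(x, "DemeSample")) {
    st <- x@siteTableAll; p <- x@metapopFreqAll; kept <- x@keptLoci
  } else st <- x
  qtn <- st$type == "qtn"
  v1 <- st$alpha1^2 * p * (1 - p)
  v2 <- st$alpha2^2 * p * (1 - p)
  tot1 <- sum(v1[qtn]); tot2 <- sum(v2[qtn])
  if (tot1 <= 0 && tot2 <= 0) stop("zero total additive variance")
  keptQ <- intersect(which(qtn), kept)
  c(trait1 = if (tot1 > 0) sum(v1[keptQ]) / tot1 else NA_real_,
    trait2 = if (tot2 > 0) sum(v2[keptQ]) / tot2 else NA_real_)
}
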