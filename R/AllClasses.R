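#' @useDynLib offsetforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aggregate approx cor cov dist mahalanobis rbinom rnorm
#'   rpois runif setNames var sd plogis quantile lm coef
#' @importFrom utils write.table read.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MetapopMap: a stepping-stone metapopulation lattice
#'
#' Demes are arranged on an `nx` by `ny` grid, indexed row-major from 1
#' (deme 1 at x = 0, y = 0; x increases along columns). Migration is
#' restricted to rook-adjacent demes at per-generation rate `m`.
#'
#' @slot nx,ny grid dimensions (columns, rows).
#' @slot demeSizes integer number of diploid individuals per deme.
#' @slot migrationRate per-generation migration rate m (fraction of each
#'   deme's offspring whose parents are drawn from one random neighbor).
#' @slot adjacency list of integer vectors; `adjacency[[d]]` are the rook
#'   neighbors of deme d.
#' @exportClass MetapopMap
setClass("MetapopMap",
  representation(nx = "integer", ny = "integer", demeSizes = "integer",
                 migrationRate = "numeric", adjacency = "list"),
  validity = function(object) {
    n <- object@nx * object@ny
    if (length(object@demeSizes) != n)
      return("demeSizes must have one entry per deme")
    if (any(object@demeSizes < 1L))
      return("all deme sizes must be >= 1")
    if (object@migrationRate < 0 || object@migrationRate > 1)
      return("migration rate must lie in [0, 1]")
    if (length(object@adjacency) != n)
      return("adjacency must have one entry per deme")
    for (d in seq_len(n)) {
      for (e in object@adjacency[[d]]) {
        if (!(d %in% object@adjacency[[e]]))
          return("adjacency must be symmetric")
      }
    }
    TRUE
  })

#' EnvField: one environmental variable over the demes
#'
#' Holds the per-deme value of a named environmental variable. Causal
#' fields double as phenotypic optima for the matching trait. A trajectory
#' matrix (generations x demes) may describe time variation; when absent
#' the field is constant in time.
#'
#' @slot name variable name.
#' @slot values numeric per-deme values (dimensionless environmental units).
#' @slot causal whether the field drives a phenotypic optimum.
#' @slot trajectory optional generations x demes matrix of values.
#' @exportClass EnvField
setClass("EnvField",
  representation(name = "character", values = "numeric",
                 causal = "logical", trajectory = "matrixOrNULL"),
  prototype(trajectory = NULL),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (length(object@causal) != 1L) return("causal must be a single flag")
    if (!is.null(object@trajectory) &&
        ncol(object@trajectory) != length(object@values))
      return("trajectory must have one column per deme")
    TRUE
  })

#' SimConfig: forward-simulation parameters
#'
#' Defaults are the full-scale reference configuration: neutral mutation
#' rate mu = 1e-7, recombination r = 1e-5 per adjacent site (about 50 cM
#' per linkage group of 50,000 sites), QTN mutation rate 2.5e-6, QTN effect
#' sd 0.1, stabilizing-selection widths sigma_S = 4.0 (burn-in) and
#' sigma_K = 1.25 per trait afterwards, single-locus fitness slope d =
#' 0.45, 10 linkage groups of 50,000 sites, MAF threshold 0.01 and 10
#' sampled individuals per deme.
#'
#' @slot mu neutral per-site per-generation mutation rate.
#' @slot r per-adjacent-site recombination rate.
#' @slot muQTN QTN per-site mutation rate (linkage groups 1..nLG-1).
#' @slot sigmaQTN sd of bivariate QTN effect sizes.
#' @slot sigmaS stabilizing-selection width during burn-in.
#' @slot sigmaK length-2 post-burn-in stabilizing-selection width per trait.
#' @slot d single-locus fitness slope.
#' @slot nLG,sitesPerLG genome layout; the last linkage group carries no
#'   QTNs (neutral genomic reference).
#' @slot phaseGens named integer vector (homogeneous, transition, stable)
#'   of multilocus phase lengths.
#' @slot neutralGens generations for neutral and single-locus runs.
#' @slot mafThreshold metapopulation MAF below-or-equal cutoff.
#' @slot samplePerDeme individuals sampled per deme.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(mu = "numeric", r = "numeric", muQTN = "numeric",
                 sigmaQTN = "numeric", sigmaS = "numeric", sigmaK = "numeric",
                 d = "numeric", nLG = "integer", sitesPerLG = "integer",
                 phaseGens = "integer", neutralGens = "integer",
                 mafThreshold = "numeric", samplePerDeme = "integer"),
  validity = function(object) {
    if (any(c(object@mu, object@r, object@muQTN) < 0))
      return("mutation/recombination rates must be non-negative")
    if (length(object@sigmaK) != 2L || any(object@sigmaK <= 0))
      return("sigmaK must be two positive values (one per trait)")
    if (object@sigmaS <= 0) return("sigmaS must be positive")
    if (object@nLG < 1L || object@sitesPerLG < 2L)
      return("genome layout must have >= 1 linkage group of >= 2 sites")
    if (length(object@phaseGens) != 3L)
      return("phaseGens must give homogeneous, transition, stable lengths")
    if (object@mafThreshold < 0 || object@mafThreshold >= 0.5)
      return("mafThreshold must lie in [0, 0.5)")
    TRUE
  })

#' PopulationState: the evolving metapopulation
#'
#' @slot haplotypes 2N x S integer matrix of 0/1 alleles over segregating
#'   sites; rows 2i-1, 2i belong to individual i.
#' @slot siteTable data.frame with columns site_id, lg, pos, type
#'   ("neutral", "qtn", "selected"), alpha1, alpha2, origin_generation.
#' @slot demeOf deme index per individual.
#' @slot sex 1 = female, 2 = male, balanced within deme.
#' @slot generation generation counter.
#' @slot fixedEffect length-2 phenotype offset from fixed QTNs.
#' @slot architecture one of "neutral", "single_locus", "multilocus".
#' @exportClass PopulationState
setClass("PopulationState",
  representation(haplotypes = "matrix", siteTable = "data.frame",
                 demeOf = "integer", sex = "integer", generation = "integer",
                 fixedEffect = "numeric", architecture = "character"),
  validity = function(object) {
    if (nrow(object@haplotypes) != 2L * length(object@demeOf))
      return("haplotypes must have two rows per individual")
    if (ncol(object@haplotypes) != nrow(object@siteTable))
      return("one siteTable row per haplotype column required")
    if (length(object@sex) != length(object@demeOf))
      return("sex must have one entry per individual")
    if (!object@architecture %in% c("neutral", "single_locus", "multilocus"))
      return("unknown architecture")
    TRUE
  })

#' DemeSample: sampled genotypes after MAF filtering
#'
#' @slot genotypes sampled individuals x kept loci dosage matrix (0/1/2).
#' @slot demeOf deme per sampled individual.
#' @slot freqs demes x kept loci alternate-allele frequencies.
#' @slot keptLoci indices (into the full site table) surviving the MAF
#'   filter.
#' @slot metapopFreqAll metapopulation frequency of every segregating locus
#'   computed on the sampled individuals (pre-filter).
#' @slot siteTableAll full site table at sampling time.
#' @slot phenotypes sampled individuals x 2 phenotype matrix (multilocus),
#'   or NULL.
#' @slot selGenotype dosage at the environmentally selected locus
#'   (single-locus architecture), or NULL.
#' @exportClass DemeSample
setClass("DemeSample",
  representation(genotypes = "matrix", demeOf = "integer", freqs = "matrix",
                 keptLoci = "integer", metapopFreqAll = "numeric",
                 siteTableAll = "data.frame", phenotypes = "matrixOrNULL",
                 selGenotype = "numericOrNULL"),
  prototype(phenotypes = NULL, selGenotype = NULL),
  validity = function(object) {
    if (ncol(object@genotypes) != length(object@keptLoci))
      return("genotypes must have one column per kept locus")
    if (nrow(object@genotypes) != length(object@demeOf))
      return("one deme assignment per sampled individual required")
    if (ncol(object@freqs) != length(object@keptLoci))
      return("freqs must have one column per kept locus")
    TRUE
  })

#' TurnoverFunction: cumulative importance along one gradient
#'
#' Monotone curve of density-standardized split importance accumulated
#' along an environmental predictor. Evaluation between knots is a
#' right-continuous step; outside the fitted range the curve is clamped.
#'
#' @slot predictor predictor name.
#' @slot knots sorted environmental values; the first knot is the fitted
#'   range minimum, where the curve is zero.
#' @slot ci cumulative importance at each knot (importance units).
#' @slot range fitted environmental range (length 2).
#' @exportClass TurnoverFunction
setClass("TurnoverFunction",
  representation(predictor = "character", knots = "numeric",
                 ci = "numeric", range = "numeric"),
  validity = function(object) {
    if (length(object@knots) != length(object@ci))
      return("knots and ci must have equal length")
    if (length(object@knots) && is.unsorted(object@knots))
      return("knots must be sorted")
    if (length(object@ci)) {
      if (any(diff(object@ci) < -1e-12)) return("ci must be non-decreasing")
      if (abs(object@ci[1]) > 1e-12) return("ci must be zero at the first knot")
      if (any(!is.finite(object@ci))) return("ci must be finite")
    }
    TRUE
  })

#' GFModel: a fitted turnover-function model
#'
#' @slot predictors predictor names.
#' @slot snpR2 out-of-bag R^2 per SNP.
#' @slot importance SNP x predictor matrix of weighted importance
#'   (within-SNP importance share times that SNP's R^2).
#' @slot aggregates named list of aggregate [TurnoverFunction-class] objects.
#' @slot totalImportance named total weighted importance per predictor
#'   (the maximum of its aggregate curve).
#' @slot envRange 2 x predictor matrix of fitted ranges.
#' @slot nSNPUsed SNPs with positive R^2 contributing to aggregates.
#' @slot empty TRUE when no SNP had positive R^2.
#' @slot params the [gfParams()] list used.
#' @exportClass GFModel
setClass("GFModel",
  representation(predictors = "character", snpR2 = "numeric",
                 importance = "matrix", aggregates = "list",
                 totalImportance = "numeric", envRange = "matrix",
                 nSNPUsed = "integer", empty = "logical", params = "list"))

#' OffsetMatrix: pairwise offsets under one metric
#'
#' @slot metric metric name (e.g. "gf", "fst", "euclidean", "mahalanobis").
#' @slot subset loci or environment subset label.
#' @slot values demes x demes symmetric non-negative matrix, zero diagonal.
#' @slot metadata list (e.g. count of clamped negative FST estimates).
#' @exportClass OffsetMatrix
setClass("OffsetMatrix",
  representation(metric = "character", subset = "character",
                 values = "matrix", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("offset matrix must be square")
    if (any(abs(diag(v)) > 1e-9, na.rm = TRUE))
      return("offset matrix must have a zero diagonal")
    if (any(v < -1e-9, na.rm = TRUE))
      return("offsets must be non-negative")
    TRUE
  })

#' CGFitnessMatrix: reciprocal-transplant common-garden fitness
#'
#' Entry (m, n) is the mean relative fitness of the sampled individuals
#' from source deme m evaluated in garden deme n's environment, with no
#' post-transplant evolution.
#'
#' @slot values source x garden matrix with entries in (0, 1].
#' @slot architecture genetic architecture the fitness map came from.
#' @exportClass CGFitnessMatrix
setClass("CGFitnessMatrix",
  representation(values = "matrix", architecture = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("CG fitness matrix must be square")
    if (any(v <= 0 | v > 1 + 1e-9, na.rm = TRUE))
      return("CG fitness entries must lie in (0, 1]")
    TRUE
  })

#' ClineFixture: a constructed allele-frequency pattern along a gradient
#'
#' @slot env sorted environmental values.
#' @slot freq allele frequency at each point, in \[0, 1\].
#' @slot shape one of "steep", "shallow", "reversed", "nonmonotonic",
#'   "noisy", "linear".
#' @slot noiseVar variance of additive noise (0 when noiseless).
#' @exportClass ClineFixture
setClass("ClineFixture",
  representation(env = "numeric", freq = "numeric", shape = "character",
                 noiseVar = "numeric"),
  validity = function(object) {
    if (length(object@env) != length(object@freq))
      return("env and freq must have equal length")
    if (is.unsorted(object@env, strictly = TRUE))
      return("env must be strictly increasing")
    if (any(object@freq < 0 | object@freq > 1))
      return("frequencies must lie in [0, 1]")
    TRUE
  })
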