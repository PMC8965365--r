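# Accessors and show methods for the central classes.

#' @rdname MetapopMap-class
setMethod("nDemes", "MetapopMap", function(x) x@nx * x@ny)
#' @rdname MetapopMap-class
setMethod("demeSizes", "MetapopMap", function(x) x@demeSizes)
#' @rdname MetapopMap-class
setMethod("migrationRate", "MetapopMap", function(x) x@migrationRate)
#' @rdname MetapopMap-class
setMethod("adjacency", "MetapopMap", function(x) x@adjacency)

setMethod("show", "MetapopMap", function(object) {
  cat(sprintf("MetapopMap: %d x %d grid, %d demes, N = %d, m = %g\n",
              object@nx, object@ny, nDemes(object),
              sum(object@demeSizes), object@migrationRate))
  sz <- object@demeSizes
  if (length(unique(sz)) == 1L) {
    cat(sprintf("  equal deme sizes (%d per deme)\n", sz[1]))
  } else {
    cat(sprintf("  deme sizes %d..%d\n", min(sz), max(sz)))
  }
})

#' @rdname EnvField-class
setMethod("envValues", "EnvField", function(x) x@values)
#' @rdname EnvField-class
setMethod("isCausal", "EnvField", function(x) x@causal)

setMethod("show", "EnvField", function(object) {
  cat(sprintf("EnvField '%s' (%s): %d demes, range [%.3g, %.3g]%s\n",
              object@name, if (object@causal) "causal" else "decoy",
              length(object@values), min(object@values), max(object@values),
              if (is.null(object@trajectory)) "" else ", time-varying"))
})

#' @rdname PopulationState-class
setMethod("haplotypes", "PopulationState", function(x) x@haplotypes)
#' @rdname PopulationState-class
setMethod("siteTable", "PopulationState", function(x) x@siteTable)
#' @rdname PopulationState-class
setMethod("demeOf", "PopulationState", function(x) x@demeOf)
#' @rdname PopulationState-class
setMethod("generation", "PopulationState", function(x) x@generation)

setMethod("show", "PopulationState", function(object) {
  st <- object@siteTable
  cat(sprintf(paste0("PopulationState (%s): %d individuals, generation %d\n",
                     "  %d segregating sites (%d QTN)\n"),
              object@architecture, length(object@demeOf), object@generation,
              nrow(st), sum(st$type == "qtn")))
})

#' @rdname DemeSample-class
setMethod("genotypes", "DemeSample", function(x) x@genotypes)
#' @rdname DemeSample-class
setMethod("alleleFreqs", "DemeSample", function(x) x@freqs)
#' @rdname DemeSample-class
setMethod("keptLoci", "DemeSample", function(x) x@keptLoci)
#' @rdname DemeSample-class
setMethod("demeOf", "DemeSample", function(x) x@demeOf)

setMethod("show", "DemeSample", function(object) {
  cat(sprintf(paste0("DemeSample: %d individuals from %d demes, ",
                     "%d loci kept of %d segregating\n"),
              nrow(object@genotypes), length(unique(object@demeOf)),
              length(object@keptLoci), length(object@metapopFreqAll)))
})

#' @rdname GFModel-class
setMethod("predictors", "GFModel", function(x) x@predictors)
#' @rdname GFModel-class
setMethod("snpR2", "GFModel", function(x) x@snpR2)
#' @rdname GFModel-class
setMethod("totalImportance", "GFModel", function(x) x@totalImportance)

setMethod("show", "GFModel", function(object) {
  if (object@empty) {
    cat("GFModel: empty (no SNP with positive R^2)\n")
    return(invisible(NULL))
  }
  cat(sprintf("GFModel: %d SNPs (%d with R^2 > 0), %d predictors\n",
              length(object@snpR2), object@nSNPUsed,
              length(object@predictors)))
  imp <- sort(object@totalImportance, decreasing = TRUE)
  cat("  importance:",
      paste(sprintf("%s=%.4g", names(imp), imp), collapse = ", "), "\n")
})

setMethod("show", "TurnoverFunction", function(object) {
  cat(sprintf(paste0("TurnoverFunction '%s': %d knots on [%.3g, %.3g], ",
                     "total CI %.4g\n"),
              object@predictor, length(object@knots), object@range[1],
              object@range[2],
              if (length(object@ci)) max(object@ci) else 0))
})

#' @rdname OffsetMatrix-class
setMethod("offsetValues", "OffsetMatrix", function(x) x@values)

setMethod("show", "OffsetMatrix", function(object) {
  cat(sprintf("OffsetMatrix [%s, %s]: %d x %d, max %.4g\n",
              object@metric, object@subset, nrow(object@values),
              ncol(object@values), max(object@values, na.rm = TRUE)))
})

#' @rdname CGFitnessMatrix-class
setMethod("fitnessValues", "CGFitnessMatrix", function(x) x@values)

setMethod("show", "CGFitnessMatrix", function(object) {
  v <- object@values
  off <- v[row(v) != col(v)]
  cat(sprintf(paste0("CGFitnessMatrix (%s): %d demes, sympatric mean %.3f, ",
                     "allopatric mean %.3f\n"),
              object@architecture, nrow(v), mean(diag(v)), mean(off)))
})

setMethod("show", "ClineFixture", function(object) {
  cat(sprintf("ClineFixture '%s': %d points, freq range [%.3f, %.3f]\n",
              object@shape, length(object@env), min(object@freq),
              max(object@freq)))
})
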