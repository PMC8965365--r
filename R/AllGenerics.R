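#' @rdname MetapopMap-class
#' @param x,object an object.
#' @export
setGeneric("nDemes", function(x) standardGeneric("nDemes"))

#' @rdname MetapopMap-class
#' @export
setGeneric("demeSizes", function(x) standardGeneric("demeSizes"))

#' @rdname MetapopMap-class
#' @export
setGeneric("migrationRate", function(x) standardGeneric("migrationRate"))

#' @rdname MetapopMap-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname EnvField-class
#' @param x an object.
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))

#' @rdname EnvField-class
#' @export
setGeneric("isCausal", function(x) standardGeneric("isCausal"))

#' @rdname PopulationState-class
#' @param x an object.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname PopulationState-class
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname PopulationState-class
#' @export
setGeneric("demeOf", function(x) standardGeneric("demeOf"))

#' @rdname PopulationState-class
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' @rdname DemeSample-class
#' @param x an object.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname DemeSample-class
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname DemeSample-class
#' @export
setGeneric("keptLoci", function(x) standardGeneric("keptLoci"))

#' @rdname GFModel-class
#' @param x an object.
#' @export
setGeneric("predictors", function(x) standardGeneric("predictors"))

#' @rdname GFModel-class
#' @export
setGeneric("snpR2", function(x) standardGeneric("snpR2"))

#' @rdname GFModel-class
#' @export
setGeneric("totalImportance", function(x) standardGeneric("totalImportance"))

#' @rdname OffsetMatrix-class
#' @param x an object.
#' @export
setGeneric("offsetValues", function(x) standardGeneric("offsetValues"))

#' @rdname CGFitnessMatrix-class
#' @param x an object.
#' @export
setGeneric("fitnessValues", function(x) standardGeneric("fitnessValues"))
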