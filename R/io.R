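#' Export a deme sample as VCF v4.2
#'
#' Writes the MAF-filtered sampled genotypes as an uncompressed VCF:
#' contigs are the linkage groups (`lg_1` ...), positions are 1-based
#' within each group, and genotypes are unphased diploid dosages. REF/ALT
#' are placeholder A/T alleles (the simulator is biallelic 0/1).
#'
#' @param sample a [DemeSample-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(sample, path) {
  st <- sample@siteTableAll[sample@keptLoci, , drop = FALSE]
  G <- sample@genotypes
  n <- nrow(G)
  ids <- sprintf("ind_%03d_deme_%03d", seq_len(n), sample@demeOf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=offsetforest",
               sprintf("##contig=<ID=lg_%d>", sort(unique(st$lg))),
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids),
                     collapse = "\t")), con)
  gtStr <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(st))) {
    writeLines(paste(c(sprintf("lg_%d", st$lg[j]),
                       format(st$pos[j] + 1, scientific = FALSE),
                       paste0("s", st$site_id[j]), "A", "T", ".", "PASS",
                       sprintf("TYPE=%s", st$type[j]), "GT",
                       gtStr[G[, j] + 1L]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Export QTN effect sizes
#'
#' Sidecar TSV (site_id, lg, pos, alpha1, alpha2) for all QTN and selected
#' loci in the site table.
#'
#' @param state a [PopulationState-class] or [DemeSample-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEffectsTSV <- function(state, path) {
  st <- if (is(state, "DemeSample")) state@siteTableAll else state@siteTable
  st <- st[st$type %in% c("qtn", "selected"),
           c("site_id", "lg", "pos", "alpha1", "alpha2")]
  write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the sampled individuals' deme assignments
#'
#' @param sample a [DemeSample-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDemeTSV <- function(sample, path) {
  d <- data.frame(individual = seq_len(nrow(sample@genotypes)),
                  deme = sample@demeOf)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an offset matrix as square TSV
#'
#' @param x an [OffsetMatrix-class] or [CGFitnessMatrix-class].
#' @param path output path; a metadata JSON goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
writeOffsetTSV <- function(x, path) {
  v <- if (is(x, "OffsetMatrix")) x@values else x@values
  write.table(v, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  if (is(x, "OffsetMatrix")) {
    jsonlite::write_json(c(list(metric = x@metric, subset = x@subset),
                           x@metadata),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a turnover curve as long-format TSV
#'
#' @param tf a [TurnoverFunction-class] (or a [GFModel-class], then all
#'   aggregate curves are written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTurnoverTSV <- function(tf, path) {
  d <- if (is(tf, "GFModel")) {
    do.call(rbind, lapply(tf@aggregates, function(a) {
      data.frame(predictor = a@predictor, knot = a@knots, ci = a@ci)
    }))
  } else {
    data.frame(predictor = tf@predictor, knot = tf@knots, ci = tf@ci)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# write a full pipeline bundle + checksum manifest; returns manifest path
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(outDir, "sample.vcf"); writeVCF(bundle$sample, p)
  paths <- c(paths, p)
  p <- file.path(outDir, "demes.tsv"); writeDemeTSV(bundle$sample, p)
  paths <- c(paths, p)
  fields <- bundle$fields %||% bundle$run$envFields
  p <- file.path(outDir, "envs.tsv")
  writeEnvTable(fields, bundle$run$map, p)
  paths <- c(paths, p, paste0(p, ".causal.json"))
  if (!is.null(bundle$offsets)) {
    for (nm in names(bundle$offsets)) {
      p <- file.path(outDir, sprintf("offset_%s.tsv", nm))
      writeOffsetTSV(bundle$offsets[[nm]], p)
      paths <- c(paths, p, paste0(p, ".meta.json"))
    }
    p <- file.path(outDir, "cg_fitness.tsv")
    writeOffsetTSV(bundle$cg, p); paths <- c(paths, p)
    p <- file.path(outDir, "evaluation.tsv")
    write.table(bundle$evaluation, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$models)) {
    for (nm in names(bundle$models)) {
      p <- file.path(outDir, sprintf("turnover_%s.tsv", nm))
      writeTurnoverTSV(bundle$models[[nm]], p)
      paths <- c(paths, p)
    }
  }
  if (any(bundle$sample@siteTableAll$type %in% c("qtn", "selected"))) {
    p <- file.path(outDir, "effects.tsv")
    writeEffectsTSV(bundle$sample, p)
    paths <- c(paths, p)
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    lapply(setNames(paths, basename(paths)),
           function(p) list(md5 = unname(tools::md5sum(p)))),
    manifest, auto_unbox = TRUE)
  manifest
}
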