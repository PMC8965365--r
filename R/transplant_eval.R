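#' Common-garden fitness matrix
#'
#' In silico reciprocal transplant: every sampled individual's fitness is
#' evaluated in every deme's (garden's) contemporary environment with no
#' post-transplant evolution, then averaged per source deme, giving a
#' source x garden matrix of mean relative fitness. For the multilocus
#' architecture the garden optima are the causal environment values and
#' fitness is the Gaussian stabilizing-selection map; for the single-locus
#' architecture fitness is the linear map normalized by the garden
#' maximum.
#'
#' @param run a list from [runScenario()] (provides `envFields`, `config`,
#'   and architecture).
#' @param sample the matching [DemeSample-class] (provides sampled
#'   phenotypes/genotypes).
#' @return a [CGFitnessMatrix-class].
#' @export
cgFitnessMatrix <- function(run, sample) {
  arch <- run$state@architecture
  if (arch == "neutral")
    stop("no fitness is defined for the neutral architecture")
  nd <- nDemes(run$map)
  demes <- sort(unique(sample@demeOf))
  v <- matrix(NA_real_, length(demes), nd,
              dimnames = list(demes, seq_len(nd)))
  if (arch == "multilocus") {
    P <- sample@phenotypes
    if (is.null(P)) stop("sample carries no phenotypes")
    th1 <- run$envFields[[1]]@values
    th2 <- run$envFields[[2]]@values
    sK <- run$config@sigmaK
    for (g in seq_len(nd)) {
      w <- fitnessMultilocus(P[, 1], P[, 2], th1[g], th2[g], sK[1], sK[2])
      v[, g] <- rowsum(w, sample@demeOf)[, 1] / tabulate(sample@demeOf,
                                                         nd)[demes]
    }
  } else {
    g0 <- sample@selGenotype
    if (is.null(g0)) stop("sample carries no selected-locus genotypes")
    E <- run$envFields[[1]]@values
    d <- run$config@d
    for (g in seq_len(nd)) {
      w <- fitnessSingleLocus(g0, E[g], d, normalize = TRUE)
      v[, g] <- rowsum(w, sample@demeOf)[, 1] / tabulate(sample@demeOf,
                                                         nd)[demes]
    }
  }
  new("CGFitnessMatrix", values = v, architecture = arch)
}

#' Local adaptation statistic
#'
#' Mean sympatric fitness minus mean allopatric fitness: the average of
#' the diagonal of the common-garden fitness matrix minus the average of
#' all off-diagonal entries.
#'
#' @param M a [CGFitnessMatrix-class] or a square matrix.
#' @return the local-adaptation value.
#' @examples
#' localAdaptation(diag(5))  # 1
#' @export
localAdaptation <- function(M) {
  if (is(M, "CGFitnessMatrix")) M <- M@values
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  mean(diag(M)) - mean(M[row(M) != col(M)])
}

#' Reciprocal-transplant evaluation subset
#'
#' A fixed quasi-uniform subset of demes used as sources when correlating
#' offsets with common-garden fitness, emulating the partial sampling of
#' real studies. On the 10x10 grid the subset starts from the lattice of
#' demes with odd column index and row index not divisible by 3 (0-based;
#' 30 demes) and is completed to `n` by adding the demes nearest the grid
#' center. Smaller grids use all demes.
#'
#' @param map a [MetapopMap-class].
#' @param n subset size on the 10x10 grid.
#' @return sorted integer deme ids.
#' @export
evaluationSubset <- function(map, n = 32L) {
  ndem <- nDemes(map)
  if (map@nx != 10L || map@ny != 10L || ndem <= n) return(seq_len(ndem))
  x <- (seq_len(ndem) - 1L) %% map@nx
  y <- (seq_len(ndem) - 1L) %/% map@nx
  base <- which(x %% 2L == 1L & y %% 3L != 0L)
  need <- n - length(base)
  if (need > 0L) {
    cx <- (map@nx - 1) / 2; cy <- (map@ny - 1) / 2
    d2 <- (x - cx)^2 + (y - cy)^2
    pool <- setdiff(order(d2), base)
    base <- c(base, pool[seq_len(need)])
  } else if (need < 0L) {
    cx <- (map@nx - 1) / 2; cy <- (map@ny - 1) / 2
    d2 <- (x[base] - cx)^2 + (y[base] - cy)^2
    base <- base[order(d2)][seq_len(n)]
  }
  sort(base)
}

#' Core/edge classification of gardens
#'
#' Demes on the outer ring of the grid are "edge"; all others "core".
#'
#' @param map a [MetapopMap-class].
#' @return character vector ("core"/"edge") per deme.
#' @export
coreEdgeClass <- function(map) {
  ndem <- nDemes(map)
  x <- (seq_len(ndem) - 1L) %% map@nx
  y <- (seq_len(ndem) - 1L) %/% map@nx
  ifelse(x == 0L | x == map@nx - 1L | y == 0L | y == map@ny - 1L,
         "edge", "core")
}

#' Offset vs. fitness correlation at one garden
#'
#' Spearman rank correlation, across the evaluation subset's source demes,
#' between the offset from each source to the garden and the common-garden
#' fitness of each source in that garden. The garden itself is excluded
#' from the sources (its offset is identically zero). A constant offset or
#' constant fitness over the subset leaves the correlation undefined (NA).
#'
#' @param offsets an [OffsetMatrix-class].
#' @param cg a [CGFitnessMatrix-class].
#' @param garden garden deme id.
#' @param subset source deme ids (see [evaluationSubset()]).
#' @return Spearman's rho, or NA.
#' @export
gardenCorrelation <- function(offsets, cg, garden, subset) {
  src <- setdiff(subset, garden)
  o <- offsets@values[src, garden]
  f <- cg@values[src, garden]
  ok <- is.finite(o) & is.finite(f)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(o[ok]) == 0 || sd(f[ok]) == 0) return(NA_real_)
  cor(o[ok], f[ok], method = "spearman")
}

#' Evaluate offset metrics against common-garden fitness
#'
#' Runs [gardenCorrelation()] for every garden in the evaluation subset
#' and every supplied offset matrix, attaching the core/edge class of each
#' garden.
#'
#' @param offsetList named list of [OffsetMatrix-class]es.
#' @param cg a [CGFitnessMatrix-class].
#' @param map a [MetapopMap-class].
#' @param subset source/garden deme ids; default [evaluationSubset()].
#' @return data.frame (metric, subset, garden, class, rho).
#' @export
evaluateOffsets <- function(offsetList, cg, map,
                            subset = evaluationSubset(map)) {
  cls <- coreEdgeClass(map)
  out <- do.call(rbind, lapply(names(offsetList), function(nm) {
    om <- offsetList[[nm]]
    data.frame(metric = nm, subset = om@subset, garden = subset,
               class = cls[subset],
               rho = vapply(subset, function(g) {
                 gardenCorrelation(om, cg, g, subset)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Core and edge mean correlations per metric
#'
#' @param results data.frame from [evaluateOffsets()] (possibly several
#'   replicates bound together).
#' @return data.frame (metric, class, meanRho, n).
#' @export
coreEdgeSummary <- function(results) {
  if (!nrow(results)) stop("empty results")
  agg <- aggregate(rho ~ metric + class, data = results,
                   FUN = function(z) mean(z, na.rm = TRUE))
  cnt <- aggregate(rho ~ metric + class, data = results,
                   FUN = function(z) sum(is.finite(z)))
  names(agg)[3] <- "meanRho"; agg$n <- cnt$rho
  agg
}

#' Adjacent-shift GF Offset vs. deme size (drift confounding)
#'
#' For the neutral deme-size scenarios: each deme's GF Offset for a shift
#' to the adjacent environment one column toward the higher-environment
#' side (the last column uses its lower-side neighbor), correlated with
#' deme size by Pearson's method. Under equal deme sizes the correlation
#' is undefined (zero variance in sizes) and NA is returned.
#'
#' @param model a fitted [GFModel-class] (neutral loci, causal gradient).
#' @param envField the causal [EnvField-class].
#' @param map a [MetapopMap-class].
#' @return list with `r` (Pearson correlation or NA), `offsets` (per-deme
#'   adjacent-shift offsets) and `demeSizes`.
#' @export
q1OffsetVsDemesize <- function(model, envField, map) {
  ndem <- nDemes(map)
  x <- (seq_len(ndem) - 1L) %% map@nx
  shift <- ifelse(x < map@nx - 1L, 1L, -1L)
  nbr <- seq_len(ndem) + shift
  vals <- envField@values
  nm <- envField@name
  off <- vapply(seq_len(ndem), function(d) {
    gfOffset(model, setNames(vals[d], nm), setNames(vals[nbr[d]], nm))
  }, numeric(1))
  sizes <- demeSizes(map)
  r <- if (sd(sizes) == 0 || sd(off) == 0) NA_real_ else cor(sizes, off)
  list(r = r, offsets = off, demeSizes = sizes)
}
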