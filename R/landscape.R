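#' Rook adjacency on a lattice
#'
#' Neighbor lists for an `nx` by `ny` stepping-stone grid under the
#' 4-neighbor (rook) convention. Demes are indexed row-major from 1.
#'
#' @param nx,ny grid dimensions (columns, rows).
#' @return list of integer neighbor vectors, one per deme.
#' @export
demeAdjacency <- function(nx, ny) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  idx <- function(x, y) y * nx + x + 1L  # 0-based coords -> 1-based deme
  out <- vector("list", nx * ny)
  for (y in seq_len(ny) - 1L) {
    for (x in seq_len(nx) - 1L) {
      nb <- integer(0)
      if (x > 0L)      nb <- c(nb, idx(x - 1L, y))
      if (x < nx - 1L) nb <- c(nb, idx(x + 1L, y))
      if (y > 0L)      nb <- c(nb, idx(x, y - 1L))
      if (y < ny - 1L) nb <- c(nb, idx(x, y + 1L))
      out[[idx(x, y)]] <- nb
    }
  }
  out
}

#' Construct a metapopulation map
#'
#' @param nx,ny grid dimensions.
#' @param demeSizes per-deme diploid sizes; a scalar is recycled.
#' @param m per-generation migration rate.
#' @return a [MetapopMap-class] object.
#' @examples
#' metapopMap(10, 10, 100, m = 0.2)
#' @export
metapopMap <- function(nx, ny, demeSizes = 100L, m = 0.2) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  demeSizes <- as.integer(rep_len(demeSizes, nx * ny))
  new("MetapopMap", nx = nx, ny = ny, demeSizes = demeSizes,
      migrationRate = m, adjacency = demeAdjacency(nx, ny))
}

#' Deme-size schemes for the drift-confounding scenarios
#'
#' Builds per-deme sizes on a 10x10 grid for the three neutral scenarios:
#' equal sizes (100 per deme), sizes increasing along columns
#' (10, 10, 50, 50, 95, 95, 145, 145, 200, 200 per row), or the reverse.
#' Row sums are 1000 and the metapopulation totals 10,000 at `scale = 1`.
#' `scale` rescales every deme (rounded) for reduced-scale runs.
#'
#' @param scheme one of "equal", "increasing", "decreasing".
#' @param nx,ny grid dimensions (the named schemes require 10 columns).
#' @param scale multiplicative rescaling of all deme sizes.
#' @return integer vector of deme sizes, row-major.
#' @export
buildDemeSizes <- function(scheme = c("equal", "increasing", "decreasing"),
                           nx = 10L, ny = 10L, scale = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "equal") {
    row <- rep(100L, nx)
  } else {
    if (nx != 10L)
      stop("the increasing/decreasing schemes are defined on 10 columns")
    row <- c(10L, 10L, 50L, 50L, 95L, 95L, 145L, 145L, 200L, 200L)
    if (scheme == "decreasing") row <- rev(row)
  }
  sizes <- rep(row, times = ny)
  sizes <- as.integer(round(scale * sizes))
  if (any(sizes < 1L)) stop("scaled deme sizes fell below 1")
  sizes
}

#' Linear environmental gradient
#'
#' Values evenly spaced from `lo` to `hi` along the chosen axis and
#' constant along the other, e.g. column j (0-based) of a 10-column grid
#' gets `lo + (hi - lo) * j / 9`.
#'
#' @param lo,hi gradient endpoints (`lo < hi`).
#' @param axis "columns" (varies with x) or "rows" (varies with y).
#' @param map a [MetapopMap-class].
#' @param name field name.
#' @param causal whether the field drives a phenotypic optimum.
#' @return an [EnvField-class].
#' @export
linearGradient <- function(lo, hi, axis = c("columns", "rows"), map,
                           name = "env", causal = TRUE) {
  axis <- match.arg(axis)
  if (lo >= hi) stop("need lo < hi")
  n <- if (axis == "columns") map@nx else map@ny
  if (n < 2L) stop("grid is degenerate (width 1) on the chosen axis")
  levels <- seq(lo, hi, length.out = n)
  values <- if (axis == "columns") {
    rep(levels, times = map@ny)
  } else {
    rep(levels, each = map@nx)
  }
  new("EnvField", name = name, values = values, causal = causal,
      trajectory = NULL)
}

#' Nonmonotonic ("tent") environmental gradient
#'
#' Rises from `lo` at one edge to `hi` at the grid center and falls back to
#' `lo` at the opposite edge, so both axis endpoints (and hence all four
#' corners when both gradients are tents) share the value `lo`. For an even
#' number of levels the two central demes form a flat plateau at `hi`.
#'
#' @inheritParams linearGradient
#' @return an [EnvField-class].
#' @export
nonmonotonicGradient <- function(lo, hi, axis = c("columns", "rows"), map,
                                 name = "env", causal = TRUE) {
  axis <- match.arg(axis)
  if (lo >= hi) stop("need lo < hi")
  n <- if (axis == "columns") map@nx else map@ny
  if (n < 3L) stop("need at least 3 levels for a tent gradient")
  j <- seq_len(n) - 1L
  half <- floor((n - 1L) / 2L)
  t <- pmin(j, (n - 1L) - j) / half
  levels <- lo + (hi - lo) * pmin(t, 1)
  values <- if (axis == "columns") {
    rep(levels, times = map@ny)
  } else {
    rep(levels, each = map@nx)
  }
  new("EnvField", name = name, values = values, causal = causal,
      trajectory = NULL)
}

#' Decoy (non-causal) environmental gradients
#'
#' Emulates the confounded predictors used alongside the causal gradients:
#' one noisy copy of each causal field (per-deme Gaussian noise, sd
#' `sigmaNoise`; at sd 1.3 over the -1..1 column gradient the expected
#' Pearson correlation with the parent is about 0.44), plus `nRandom`
#' fields drawn from a multivariate normal whose correlation matrix has
#' off-diagonals sampled Uniform(-1, 1) and is then projected to the
#' nearest positive-definite correlation matrix, mimicking the correlation
#' structure of climate variables.
#'
#' @param causal list of causal [EnvField-class]s.
#' @param sigmaNoise sd of the additive noise on the correlated decoys.
#' @param nRandom number of additional randomly correlated fields.
#' @param seed integer seed.
#' @return list of [EnvField-class]s, all flagged non-causal.
#' @export
makeDecoyEnvs <- function(causal, sigmaNoise = 1.3, nRandom = 10L,
                          seed = 1L) {
  if (sigmaNoise < 0) stop("sigmaNoise must be non-negative")
  stopifnot(length(causal) >= 1L)
  set.seed(seed)
  nd <- length(causal[[1]]@values)
  out <- vector("list", 0L)
  for (f in causal) {
    vals <- f@values + rnorm(nd, 0, sigmaNoise)
    out <- c(out, new("EnvField", name = paste0(f@name, "_decoy"),
                      values = vals, causal = FALSE, trajectory = NULL))
  }
  if (nRandom > 0L) {
    k <- as.integer(nRandom)
    C <- diag(k)
    C[upper.tri(C)] <- runif(k * (k - 1) / 2, -1, 1)
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    X <- MASS::mvrnorm(nd, mu = rep(0, k), Sigma = C)
    for (i in seq_len(k)) {
      out <- c(out, new("EnvField", name = sprintf("rand_%d", i),
                        values = X[, i], causal = FALSE, trajectory = NULL))
    }
  }
  out
}

#' Stack environmental fields into a deme x predictor matrix
#'
#' @param fields list of [EnvField-class]s.
#' @return numeric matrix, one column per field, named by field.
#' @export
envMatrix <- function(fields) {
  m <- vapply(fields, function(f) f@values, numeric(length(fields[[1]]@values)))
  colnames(m) <- vapply(fields, function(f) f@name, character(1))
  m
}

#' Write the deme environment table
#'
#' TSV with columns deme_id (0-based, row-major), x, y and one column per
#' environmental field; causal flags go to a sidecar JSON header
#' (`<path>.causal.json`).
#'
#' @param fields list of [EnvField-class]s.
#' @param map a [MetapopMap-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEnvTable <- function(fields, map, path) {
  n <- nDemes(map)
  d <- data.frame(deme_id = seq_len(n) - 1L,
                  x = (seq_len(n) - 1L) %% map@nx,
                  y = (seq_len(n) - 1L) %/% map@nx)
  em <- envMatrix(fields)
  stopifnot(nrow(em) == n)
  d <- cbind(d, as.data.frame(em))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  flags <- as.list(setNames(vapply(fields, function(f) f@causal, logical(1)),
                            colnames(em)))
  jsonlite::write_json(flags, paste0(path, ".causal.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
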