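# Weir & Cockerham (1984) variance components for a pair of population
# samples, vectorized over loci. Returns per-locus components a, b, c.
.wcComponents <- function(nA, nB, pA, pB, hA, hB) {
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST between two deme samples
#'
#' Multi-locus Weir-Cockerham (1984) estimator: per-locus variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals) are combined across loci as a
#' ratio of sums, `sum(a) / sum(a + b + c)`. Loci monomorphic across both
#' samples carry no information and are excluded; if no locus is
#' polymorphic the estimate is undefined (NA).
#'
#' @param genoA,genoB individuals x loci diploid dosage matrices (0/1/2)
#'   for the two demes (shared loci, same column order).
#' @param loci optional column subset.
#' @return the multi-locus F_ST estimate (possibly negative; see
#'   [fstMatrix()] for the clamped offset convention), or NA.
#' @export
wcFstPair <- function(genoA, genoB, loci = NULL) {
  genoA <- as.matrix(genoA); genoB <- as.matrix(genoB)
  if (ncol(genoA) != ncol(genoB)) stop("demes must share loci")
  if (!is.null(loci)) {
    genoA <- genoA[, loci, drop = FALSE]
    genoB <- genoB[, loci, drop = FALSE]
  }
  nA <- nrow(genoA); nB <- nrow(genoB)
  if (nA < 2L || nB < 2L) stop("need at least 2 diploids per deme")
  pA <- colMeans(genoA) / 2; pB <- colMeans(genoB) / 2
  hA <- colMeans(genoA == 1L); hB <- colMeans(genoB == 1L)
  poly <- (pA + pB) > 0 & (pA + pB) < 2
  if (!any(poly)) return(NA_real_)
  comp <- .wcComponents(nA, nB, pA[poly], pB[poly], hA[poly], hB[poly])
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) return(NA_real_)
  sum(comp$a) / denom
}

#' Pairwise F_ST offset matrix
#'
#' Weir-Cockerham F_ST between every pair of demes, using either all kept
#' loci ("genome") or only the causal QTN loci ("causal"). Negative
#' estimates are clamped to zero for use as offsets (the raw count of
#' clamped pairs is recorded in the metadata).
#'
#' @param sample a [DemeSample-class].
#' @param subset "genome" or "causal".
#' @return an [OffsetMatrix-class].
#' @export
fstMatrix <- function(sample, subset = c("genome", "causal")) {
  subset <- match.arg(subset)
  G <- sample@genotypes
  if (subset == "causal") {
    st <- sample@siteTableAll
    causal <- which(st$type[sample@keptLoci] %in% c("qtn", "selected"))
    if (!length(causal))
      stop("no causal loci survive the MAF filter (neutral run?)")
    G <- G[, causal, drop = FALSE]
  }
  demes <- sort(unique(sample@demeOf))
  nd <- length(demes)
  rowsOf <- lapply(demes, function(d) which(sample@demeOf == d))
  v <- matrix(0, nd, nd, dimnames = list(demes, demes))
  clamped <- 0L
  for (i in seq_len(nd - 1L)) {
    gi <- G[rowsOf[[i]], , drop = FALSE]
    for (j in seq.int(i + 1L, nd)) {
      f <- wcFstPair(gi, G[rowsOf[[j]], , drop = FALSE])
      if (is.na(f)) {
        v[i, j] <- v[j, i] <- NA_real_
      } else {
        if (f < 0) { clamped <- clamped + 1L; f <- 0 }
        v[i, j] <- v[j, i] <- f
      }
    }
  }
  new("OffsetMatrix", metric = "fst", subset = subset, values = v,
      metadata = list(clampedNegative = clamped))
}

#' Environmental distance between two demes
#'
#' Euclidean or Mahalanobis distance between environment vectors. The
#' Mahalanobis form standardizes by the covariance of environments across
#' demes (supply `covariance`, typically from the full deme table); with
#' an identity covariance it reduces to the Euclidean distance. A
#' near-singular covariance is ridge-regularized by `1e-8 * trace`.
#'
#' @param envsA,envsB environment vectors (matching predictor order).
#' @param kind "euclidean" or "mahalanobis".
#' @param covariance predictor covariance matrix (mahalanobis only).
#' @return non-negative distance.
#' @export
envDistance <- function(envsA, envsB, kind = c("euclidean", "mahalanobis"),
                        covariance = NULL) {
  kind <- match.arg(kind)
  d <- envsA - envsB
  if (kind == "euclidean") return(sqrt(sum(d^2)))
  if (is.null(covariance)) stop("mahalanobis distance needs a covariance")
  S <- .ridgeIfSingular(covariance)
  sqrt(drop(t(d) %*% solve(S, d)))
}

.ridgeIfSingular <- function(S) {
  S <- as.matrix(S)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || rcond(S) < 1e-12)
    S <- S + diag(1e-8 * sum(diag(S)), nrow(S))
  S
}

#' Pairwise environmental-distance offset matrix
#'
#' Distances between all deme pairs using either the causal environments
#' only or all fields (causal plus decoys). For the Mahalanobis form the
#' covariance is estimated across all demes' environment vectors.
#'
#' @param fields list of [EnvField-class]s, or a demes x predictors
#'   matrix (then `causal` flags select the causal subset).
#' @param kind "euclidean" or "mahalanobis".
#' @param subset "all" or "causal".
#' @param causal logical per-column flags when `fields` is a matrix.
#' @return an [OffsetMatrix-class].
#' @export
envDistanceMatrix <- function(fields, kind = c("euclidean", "mahalanobis"),
                              subset = c("all", "causal"), causal = NULL) {
  kind <- match.arg(kind); subset <- match.arg(subset)
  if (is.list(fields)) {
    causal <- vapply(fields, function(f) f@causal, logical(1))
    X <- envMatrix(fields)
  } else X <- as.matrix(fields)
  if (subset == "causal") {
    if (is.null(causal)) stop("causal flags required for the causal subset")
    if (!any(causal)) stop("no causal fields supplied")
    X <- X[, causal, drop = FALSE]
  }
  if (kind == "euclidean") {
    v <- as.matrix(dist(X))
  } else {
    S <- .ridgeIfSingular(cov(X))
    U <- chol(S)
    Z <- t(backsolve(U, t(X), transpose = TRUE))
    v <- as.matrix(dist(Z))
  }
  dimnames(v) <- list(seq_len(nrow(X)), seq_len(nrow(X)))
  new("OffsetMatrix", metric = kind, subset = subset, values = v,
      metadata = list())
}
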