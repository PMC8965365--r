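#' Construct an allele-frequency cline fixture
#'
#' Constructed allele-frequency-by-environment patterns used to probe the
#' shape of turnover functions: `steep` is a logistic cline of slope 10 on
#' the environmental scale, `shallow` slope 1, `reversed` the mirrored
#' steep cline, `nonmonotonic` a rise-then-fall pattern with equal
#' frequencies at the two environmental extremes (a plateau between two
#' logistic shoulders at +/- 0.7), `linear` a straight 0..1 ramp, and
#' `noisy` the linear ramp plus Gaussian noise of variance 0.1 clipped to
#' \[0, 1\].
#'
#' @param shape one of "steep", "shallow", "reversed", "nonmonotonic",
#'   "linear", "noisy".
#' @param nPoints number of populations along the gradient (>= 5).
#' @param params optional overrides: `slope` (logistic clines),
#'   `shoulder` (nonmonotonic), `noiseVar` (noisy).
#' @param seed integer seed (noisy shape only).
#' @return a [ClineFixture-class].
#' @export
makeCline <- function(shape = c("steep", "shallow", "reversed",
                                "nonmonotonic", "linear", "noisy"),
                      nPoints = 20L, params = list(), seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(nPoints >= 5L)
  env <- seq(-1, 1, length.out = nPoints)
  noiseVar <- 0
  freq <- switch(shape,
    steep = plogis((params$slope %||% 10) * env),
    shallow = plogis((params$slope %||% 1) * env),
    reversed = plogis(-(params$slope %||% 10) * env),
    nonmonotonic = {
      a <- params$slope %||% 10
      s <- params$shoulder %||% 0.7
      plogis(a * (env + s)) * plogis(-a * (env - s))
    },
    linear = (env + 1) / 2,
    noisy = {
      set.seed(seed)
      noiseVar <- params$noiseVar %||% 0.1
      pmin(pmax((env + 1) / 2 + rnorm(nPoints, 0, sqrt(noiseVar)), 0), 1)
    })
  new("ClineFixture", env = env, freq = freq, shape = shape,
      noiseVar = noiseVar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shape metrics of a turnover curve
#'
#' Splits the fitted environmental range into thirds and reports the
#' share of total cumulative importance accrued in the middle third
#' (`centralFraction`), the share in the outer thirds (`edgeFraction`),
#' and a symmetry score `1 - |left half - right half| / total`.
#'
#' @param tf a [TurnoverFunction-class] with positive total importance.
#' @return named numeric (centralFraction, edgeFraction, symmetry).
#' @export
curveShapeMetrics <- function(tf) {
  lo <- tf@range[1]; hi <- tf@range[2]
  total <- evalTurnover(tf, hi)
  if (total <= 0) stop("zero-total turnover curve")
  b <- seq(lo, hi, length.out = 4L)
  ci <- evalTurnover(tf, b)
  central <- (ci[3] - ci[2]) / total
  mid <- evalTurnover(tf, (lo + hi) / 2)
  c(centralFraction = central, edgeFraction = 1 - central,
    symmetry = 1 - abs(2 * mid - total) / total)
}

# fit the turnover engine to one or more cline fixtures sharing an env axis
.fitClines <- function(fixtures, params, seed) {
  env <- fixtures[[1]]@env
  freqs <- vapply(fixtures, function(f) f@freq, numeric(length(env)))
  colnames(freqs) <- vapply(fixtures, function(f) f@shape, character(1))
  colnames(freqs) <- make.unique(colnames(freqs))
  envs <- matrix(env, ncol = 1, dimnames = list(NULL, "env"))
  fitGF(freqs, envs, params = params, seed = seed)
}

#' Run one thought experiment
#'
#' The five constructed-cline experiments: (1) sampling schemes of a steep
#' cline (dense, sparse, one-sided subsampling of the same pattern);
#' (2) different cline slopes (steep, shallow, reversed); (3) different
#' nonmonotonic patterns (wide and narrow plateaus); (4) linear vs.
#' nonmonotonic patterns; (5) a linear pattern with and without Gaussian
#' noise (variance 0.1). Each fixture (or fixture set) is pushed through
#' the turnover engine; the report carries the fitted models, aggregate
#' curves, shape metrics, and the GF Offset between the environmental
#' extremes (-1 and +1).
#'
#' @param id experiment 1..5.
#' @param nPoints populations per fixture.
#' @param params a [gfParams()] list (the engine is fit per fixture).
#' @param seed integer seed.
#' @return list with `fixtures`, `models`, `curves`, `metrics` (matrix),
#'   and `offsetExtremes` (named GF Offsets from env -1 to +1).
#' @export
runThoughtExperiment <- function(id, nPoints = 20L,
                                 params = gfParams(nTrees = 100L),
                                 seed = 1L) {
  stopifnot(id %in% 1:5)
  fixtures <- switch(id,
    `1` = {
      dense <- makeCline("steep", nPoints)
      keepSparse <- seq(1L, nPoints, by = 3L)
      keepHalf <- seq_len(ceiling(nPoints / 2))
      list(dense = dense,
           sparse = new("ClineFixture", env = dense@env[keepSparse],
                        freq = dense@freq[keepSparse], shape = "steep",
                        noiseVar = 0),
           one_sided = new("ClineFixture", env = dense@env[keepHalf],
                           freq = dense@freq[keepHalf], shape = "steep",
                           noiseVar = 0))
    },
    `2` = list(steep = makeCline("steep", nPoints),
               shallow = makeCline("shallow", nPoints),
               reversed = makeCline("reversed", nPoints)),
    `3` = list(wide = makeCline("nonmonotonic", nPoints),
               narrow = makeCline("nonmonotonic", nPoints,
                                  params = list(shoulder = 0.4))),
    `4` = list(linear = makeCline("linear", nPoints),
               nonmonotonic = makeCline("nonmonotonic", nPoints)),
    `5` = list(clean = makeCline("linear", nPoints),
               noisy = makeCline("noisy", nPoints, seed = seed)))

  models <- lapply(seq_along(fixtures), function(i) {
    .fitClines(fixtures[i], params, seed + i)
  })
  names(models) <- names(fixtures)
  curves <- lapply(models, function(m) m@aggregates[["env"]])
  metrics <- t(vapply(curves, function(tf) {
    if (evalTurnover(tf, tf@range[2]) <= 0) {
      c(centralFraction = NA_real_, edgeFraction = NA_real_,
        symmetry = NA_real_)
    } else curveShapeMetrics(tf)
  }, numeric(3)))
  offsets <- vapply(models, function(m) {
    gfOffset(m, c(env = -1), c(env = 1))
  }, numeric(1))
  list(id = id, fixtures = fixtures, models = models, curves = curves,
       metrics = metrics, offsetExtremes = offsets)
}
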