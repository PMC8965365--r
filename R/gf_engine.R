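#' Turnover-engine parameters
#'
#' Ensemble settings for the per-SNP regression forests. Defaults mirror
#' common random-forest practice at these data sizes: 500 trees per SNP,
#' one candidate predictor per split when there are at most two predictors
#' and `ceiling(k/3)` otherwise, minimum leaf size 2, and 50 equal bins for
#' the density standardization of split importances.
#'
#' @param nTrees trees per SNP (>= 1).
#' @param mtry candidate predictors per split; NA = automatic rule above.
#' @param minLeaf minimum observations per leaf.
#' @param nBins bins for split-density standardization (>= 2).
#' @param bootstrap grow each tree on a bootstrap resample of demes (with
#'   out-of-bag R^2); FALSE fits every tree to all demes and scores R^2
#'   in-sample (used by the exact single-split oracle checks).
#' @return a list of class "gfParams".
#' @export
gfParams <- function(nTrees = 500L, mtry = NA_integer_, minLeaf = 2L,
                     nBins = 50L, bootstrap = TRUE) {
  stopifnot(nTrees >= 1L, nBins >= 2L, minLeaf >= 1L)
  structure(list(nTrees = as.integer(nTrees), mtry = mtry,
                 minLeaf = as.integer(minLeaf), nBins = as.integer(nBins),
                 bootstrap = isTRUE(bootstrap)),
            class = "gfParams")
}

# deterministic per-SNP substream seed: depends only on the master seed
# and the SNP's name, so any SNP subset reproduces identically
.snpSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((seed + h) %% 2147480009)
}

# empirical density of predictor values over nBins equal bins; floored at
# the smallest positive bin density so standardization never divides by 0
.binDensity <- function(x, nBins) {
  rg <- range(x)
  if (diff(rg) <= 0) return(list(breaks = rg, dens = 1))
  breaks <- seq(rg[1], rg[2], length.out = nBins + 1L)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = nBins)
  dens <- cnt / (length(x) * diff(breaks)[1])
  floor_ <- min(dens[dens > 0])
  dens[dens <= 0] <- floor_
  list(breaks = breaks, dens = dens)
}

#' Fit a gradient-forest-style turnover model
#'
#' For each SNP an ensemble of regression trees is grown on bootstrap
#' resamples of demes (response: per-deme allele frequency; predictors:
#' the environments). Every split contributes its impurity reduction at
#' its split location; per predictor, split importances are standardized
#' by the empirical density of predictor values in the split's bin and
#' accumulated into a per-SNP cumulative-importance curve scaled so its
#' total equals the SNP's within-ensemble importance share for that
#' predictor times the SNP's out-of-bag R^2. Aggregate curves are means of
#' these R^2-scaled curves over SNPs with positive R^2 (an R^2-weighted
#' combination). SNPs with non-positive R^2 are excluded from aggregation;
#' constant predictors simply receive zero importance.
#'
#' @param freqs demes x SNPs allele-frequency matrix (column names used as
#'   SNP ids).
#' @param envs demes x predictors environment matrix (column names used as
#'   predictor names).
#' @param params a [gfParams()] list.
#' @param seed master seed; per-SNP substream seeds are derived from it.
#' @return a [GFModel-class].
#' @export
fitGF <- function(freqs, envs, params = gfParams(), seed = 1L) {
  freqs <- as.matrix(freqs); envs <- as.matrix(envs)
  if (nrow(freqs) < 3L) stop("need at least 3 demes")
  if (nrow(envs) != nrow(freqs)) stop("freqs/envs deme mismatch")
  if (ncol(envs) < 1L) stop("need at least 1 predictor")
  if (anyNA(freqs) || anyNA(envs)) stop("missing values are not supported")
  if (is.null(colnames(freqs)))
    colnames(freqs) <- paste0("snp", seq_len(ncol(freqs)))
  if (is.null(colnames(envs)))
    colnames(envs) <- paste0("env", seq_len(ncol(envs)))

  k <- ncol(envs)
  preds <- colnames(envs)
  mtry <- params$mtry
  if (is.na(mtry)) mtry <- if (k <= 2L) 1L else ceiling(k / 3)
  nSNP <- ncol(freqs)

  densities <- lapply(seq_len(k), function(j) {
    .binDensity(envs[, j], params$nBins)
  })
  envRange <- apply(envs, 2L, range)
  rownames(envRange) <- c("min", "max")

  r2 <- numeric(nSNP)
  importance <- matrix(0, nSNP, k, dimnames = list(colnames(freqs), preds))
  # per predictor: accumulated (location, scaled increment) pairs
  accLoc <- accInc <- rep(list(vector("list", nSNP)), k)

  for (s in seq_len(nSNP)) {
    set.seed(.snpSeed(seed, colnames(freqs)[s]))
    fit <- gf_fit_snp_cpp(envs, freqs[, s], params$nTrees, as.integer(mtry),
                          params$minLeaf, params$bootstrap)
    r2[s] <- fit$r2
    sp <- fit$splits
    if (r2[s] <= 0 || nrow(sp) == 0L) next
    totImp <- sum(sp[, "improvement"])
    for (j in seq_len(k)) {
      rows <- sp[, "predictor"] == j
      if (!any(rows)) next
      share <- sum(sp[rows, "improvement"]) / totImp
      importance[s, j] <- share * r2[s]
      loc <- sp[rows, "value"]
      imp <- sp[rows, "improvement"]
      d <- densities[[j]]
      if (length(d$dens) > 1L) {
        bin <- findInterval(loc, d$breaks, rightmost.closed = TRUE,
                            all.inside = TRUE)
        imp <- imp / d$dens[bin]
      }
      ord <- order(loc)
      loc <- loc[ord]; imp <- imp[ord]
      # scale standardized importances so the curve total is share * R^2
      imp <- imp * (share * r2[s]) / sum(imp)
      accLoc[[j]][[s]] <- loc
      accInc[[j]][[s]] <- imp
    }
  }

  used <- which(r2 > 0)
  empty <- length(used) == 0L
  aggregates <- vector("list", k); names(aggregates) <- preds
  totalImp <- setNames(numeric(k), preds)
  for (j in seq_len(k)) {
    loc <- unlist(accLoc[[j]], use.names = FALSE)
    inc <- unlist(accInc[[j]], use.names = FALSE)
    if (empty || !length(loc)) {
      aggregates[[j]] <- new("TurnoverFunction", predictor = preds[j],
                             knots = envRange[1, j], ci = 0,
                             range = envRange[, j])
      next
    }
    inc <- inc / length(used)  # mean over contributing (positive-R^2) SNPs
    ord <- order(loc)
    loc <- loc[ord]; inc <- inc[ord]
    knots <- c(envRange[1, j], loc)
    ci <- c(0, cumsum(inc))
    dup <- duplicated(knots, fromLast = TRUE)
    aggregates[[j]] <- new("TurnoverFunction", predictor = preds[j],
                           knots = knots[!dup], ci = ci[!dup],
                           range = envRange[, j])
    totalImp[j] <- ci[length(ci)]
  }

  new("GFModel", predictors = preds, snpR2 = setNames(r2, colnames(freqs)),
      importance = importance, aggregates = aggregates,
      totalImportance = totalImp, envRange = envRange,
      nSNPUsed = length(used), empty = empty,
      params = unclass(params))
}

#' Aggregate turnover function for one predictor
#'
#' @param model a fitted [GFModel-class].
#' @param predictor predictor name.
#' @return the aggregate [TurnoverFunction-class].
#' @export
aggregateTurnover <- function(model, predictor) {
  if (!predictor %in% model@predictors)
    stop(sprintf("unknown predictor '%s'", predictor))
  model@aggregates[[predictor]]
}

#' Evaluate a turnover function
#'
#' Right-continuous step evaluation of cumulative importance; values
#' outside the fitted range are clamped to the curve endpoints.
#'
#' @param tf a [TurnoverFunction-class].
#' @param x environmental values.
#' @return cumulative importance at `x`.
#' @export
evalTurnover <- function(tf, x) {
  if (length(tf@knots) == 1L) return(rep(tf@ci, length(x)))
  approx(tf@knots, tf@ci, xout = pmin(pmax(x, tf@range[1]), tf@range[2]),
         method = "constant", f = 0, rule = 2)$y
}

#' Transform an environment into cumulative-importance units
#'
#' Componentwise evaluation of the aggregate turnover functions: the
#' fitted model rescales each predictor from its original units into
#' common units of cumulative importance.
#'
#' @param model a fitted [GFModel-class].
#' @param env named numeric vector (one value per predictor), or a matrix
#'   with one column per predictor.
#' @return numeric vector (or matrix) of cumulative importance.
#' @export
transformEnv <- function(model, env) {
  if (is.matrix(env)) {
    out <- vapply(model@predictors, function(p) {
      evalTurnover(model@aggregates[[p]], env[, p])
    }, numeric(nrow(env)))
    if (!is.matrix(out)) out <- matrix(out, nrow = nrow(env),
                                       dimnames = list(NULL,
                                                       model@predictors))
    return(out)
  }
  if (is.null(names(env))) {
    if (length(env) != length(model@predictors))
      stop("env must have one value per predictor")
    names(env) <- model@predictors
  }
  missing <- setdiff(model@predictors, names(env))
  if (length(missing))
    stop("missing predictors: ", paste(missing, collapse = ", "))
  vapply(model@predictors, function(p) {
    evalTurnover(model@aggregates[[p]], env[[p]])
  }, numeric(1))
}

#' GF Offset between two environments
#'
#' The Euclidean distance between two multivariate environments after each
#' predictor has been rescaled by its aggregate cumulative-importance
#' curve: `sqrt(sum_i (CI_Ai - CI_Bi)^2)`. The squared form (no radical)
#' is available via `squared = TRUE`.
#'
#' @param model a fitted [GFModel-class].
#' @param envA,envB named numeric environment vectors.
#' @param squared return the squared distance.
#' @return non-negative offset.
#' @export
gfOffset <- function(model, envA, envB, squared = FALSE) {
  d2 <- sum((transformEnv(model, envA) - transformEnv(model, envB))^2)
  if (squared) d2 else sqrt(d2)
}

#' Pairwise GF Offset matrix over demes
#'
#' @param model a fitted [GFModel-class].
#' @param envs demes x predictors environment matrix.
#' @param subset label recorded on the result (e.g. which loci/envs were
#'   used for the fit).
#' @return an [OffsetMatrix-class].
#' @export
gfOffsetMatrix <- function(model, envs, subset = "genome_all_env") {
  ci <- transformEnv(model, as.matrix(envs))
  v <- as.matrix(dist(ci))
  dimnames(v) <- list(rownames(envs), rownames(envs))
  new("OffsetMatrix", metric = "gf", subset = subset, values = v,
      metadata = list(note = paste("Euclidean (rooted) form; square the",
                                   "entries for the unrooted variant")))
}

#' Rank predictors by total weighted importance
#'
#' @param model a fitted [GFModel-class].
#' @return character vector of predictor names, descending importance
#'   (ties broken lexicographically).
#' @export
rankPredictors <- function(model) {
  if (model@empty) stop("model is empty (no SNP with positive R^2)")
  imp <- model@totalImportance
  names(imp)[order(-imp, names(imp))]
}
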