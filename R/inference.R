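## Maximum-likelihood fitting by bounded differential-evolution search,
## constrained refits, parametric-bootstrap confidence intervals, and
## bootstrap likelihood-ratio model selection.

.MODEL_PARAMS <- list(single = c("Na", "Nb", "Tb", "d", "Nc"),
                      two_pop = c("Na", "Nb", "Tb", "d", "Nc", "f", "Ng"))
.SENTINEL <- -1e15   # orders below every finite composite loglik

#' Parameter space constructors
#'
#' \code{defaultParameterSpace()} returns the default search space: diploid
#' sizes \code{Na} in [500, 1e5], \code{Nb} in [50, 1e5], \code{Nc} in
#' [1e4, 1e8] and \code{Ng} in [50, 1e8] searched on a log10 scale;
#' bottleneck onset \code{Tb} in [20, 100] and duration \code{d} in [1, 60]
#' generations; merge fraction \code{f} in [0.01, 0.99].  For the
#' two-population model \code{Ng} (the merged size at the onset of the
#' expansion) is tied to \code{Nb} by default.  Inter-parameter constraints
#' (\code{d <= Tb - 1}, \code{Nb < Na} for the two-population model,
#' \code{Nc >= Nb} / \code{Nc >= Ng}) are enforced during the search through
#' a sentinel objective value.
#'
#' @param type \code{"single"} or \code{"two_pop"}.
#' @param fixed named numeric vector of parameters to hold fixed.
#' @param lower,upper,tied,logScale overrides of the defaults (named as the
#'   model parameters).
#' @return A [ParameterSpace-class].
#' @examples
#' defaultParameterSpace("single", fixed = c(Na = 10000))
#' @export
defaultParameterSpace <- function(type = c("single", "two_pop"),
                                  fixed = numeric(), lower = NULL,
                                  upper = NULL, tied = NULL,
                                  logScale = NULL) {
  type <- match.arg(type)
  pars <- .MODEL_PARAMS[[type]]
  lo <- c(Na = 500, Nb = 50, Tb = 20, d = 1, Nc = 1e4, f = 0.01, Ng = 50)[pars]
  up <- c(Na = 1e5, Nb = 1e5, Tb = 100, d = 60, Nc = 1e8, f = 0.99,
          Ng = 1e8)[pars]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  if (is.null(tied)) tied <- if (type == "two_pop") c(Ng = "Nb") else character()
  if (is.null(logScale)) logScale <- intersect(c("Na", "Nb", "Nc", "Ng"), pars)
  tied <- tied[setdiff(names(tied), names(fixed))]
  new("ParameterSpace", lower = lo, upper = up, fixed = fixed, tied = tied,
      logScale = logScale)
}

## ---- encode/decode ---------------------------------------------------------

## free parameters live in a transformed box (log10 for size parameters)
.transformBounds <- function(space) {
  free <- freeParameters(space)
  lo <- space@lower[free]; up <- space@upper[free]
  isLog <- free %in% space@logScale
  lo[isLog] <- log10(lo[isLog]); up[isLog] <- log10(up[isLog])
  list(free = free, lower = lo, upper = up, isLog = isLog)
}

.decodeParams <- function(x, space, tb) {
  v <- x
  v[tb$isLog] <- 10^v[tb$isLog]
  full <- c(stats::setNames(v, tb$free), space@fixed)
  for (p in names(space@tied)) full[p] <- full[[space@tied[p]]]
  full
}

.encodeParams <- function(params, space, tb) {
  x <- params[tb$free]
  x[tb$isLog] <- log10(x[tb$isLog])
  x
}

## positive violation measure; 0 when the inter-parameter constraints hold
.constraintViolation <- function(p, type) {
  v <- max(0, p[["d"]] - (p[["Tb"]] - 1))
  if (type == "two_pop") {
    v <- v + max(0, p[["Nb"]] - (p[["Na"]] - 1))
    v <- v + max(0, p[["Ng"]] - p[["Nc"]]) / max(p[["Nc"]], 1)
  } else {
    v <- v + max(0, p[["Nb"]] - p[["Na"]]) / max(p[["Na"]], 1)
    v <- v + max(0, p[["Nb"]] - p[["Nc"]]) / max(p[["Nc"]], 1)
  }
  v
}

## ---- objective -------------------------------------------------------------

## Precompute, per dataset, everything the objective needs: the conditional
## expectation matrix E (u = 1..uFit x bins), counts, pair count, sampling.
## uFit is chosen so that (i) the PMF reaches the ancestral epoch for every
## Tb in the space and (ii) segments above the smallest analysed bin edge
## have negligible (< 1e-18 relative) expectation beyond it.
.prepDatasets <- function(datasets, genome, upperTb) {
  if (is(datasets, "SegmentCountTable")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, is, TRUE, "SegmentCountTable")))
  genomeM <- chromLengths(genome) / .CM_PER_MORGAN
  lapply(datasets, function(ds) {
    edgesM <- binEdges(ds) / .CM_PER_MORGAN
    decay <- if (edgesM[1] > 0) ceiling(45 / (2 * edgesM[1])) else 20000L
    if (decay > 20000L) {
      warning("very small bin edges: truncating the TMRCA sum at 20000 ",
              "generations")
      decay <- 20000L
    }
    uFit <- max(decay, ceiling(upperTb - ds@sampling@sampleTime) + 60L)
    list(E = .expectedCountsMatrix(seq_len(uFit), genomeM, edgesM),
         K = binCounts(ds), P = nPairs(ds), sampling = ds@sampling,
         uFit = as.integer(uFit))
  })
}

## per-pair composite loglik of `params` for one prepared dataset
.perPairLoglik <- function(params, type, prep) {
  raw <- .pmfRaw(params, type, prep$sampling, prep$uFit)
  lambda <- prep$P * drop(raw$q %*% prep$E)
  ll <- poissonCompositeLoglik(prep$K, lambda, P = prep$P)
  ll$perPair
}

.makeObjective <- function(preps, type, space, tb) {
  function(x) {
    params <- .decodeParams(x, space, tb)
    viol <- .constraintViolation(params, type)
    if (viol > 0) return(.SENTINEL * (1 + viol))
    val <- tryCatch(
      sum(vapply(preps, function(prep)
        .perPairLoglik(params, type, prep), numeric(1))),
      error = function(e) -Inf)
    if (!is.finite(val)) .SENTINEL * 10 else val
  }
}

## ---- differential evolution ------------------------------------------------

## Differential evolution, maximizing `fn` over a box.  Mutation mixes
## rand/1 (exploration) and current-to-best/1 (ridge tracking) with a
## dithered scale factor; binomial crossover.  init: optional matrix of
## starting points (columns) seeded into the population.  Deterministic
## given `seed`; restores the caller's RNG state.
.deOptim <- function(fn, lower, upper, seed, NP = NULL, itermax = 400L,
                     reltol = 1e-6, window = 60L, CR = 0.9, init = NULL) {
  d <- length(lower)
  if (is.null(NP)) NP <- max(10L * d, 40L)
  .withSeed(seed, {
    X <- matrix(stats::runif(d * NP, lower, upper), nrow = d)
    if (!is.null(init)) {
      init <- as.matrix(init)
      take <- min(ncol(init), NP %/% 2)
      span <- (upper - lower) * 0.05
      for (j in seq_len(take)) {
        base <- pmin(pmax(init[, j], lower), upper)
        X[, j] <- pmin(pmax(base + stats::rnorm(d, 0, span), lower), upper)
      }
      X[, 1] <- pmin(pmax(init[, 1], lower), upper)  # exact warm start
    }
    fit <- apply(X, 2, fn)
    nEval <- NP
    bestHist <- max(fit)
    converged <- FALSE
    iter <- 0L
    while (iter < itermax) {
      iter <- iter + 1L
      Fw <- stats::runif(1, 0.5, 1.0)
      bestIdx <- which.max(fit)
      for (i in seq_len(NP)) {
        r <- sample.int(NP, 3L)
        while (any(r == i)) r <- sample.int(NP, 3L)
        v <- if (stats::runif(1) < 0.5)
          X[, r[1]] + Fw * (X[, r[2]] - X[, r[3]])
        else
          X[, i] + Fw * (X[, bestIdx] - X[, i]) + Fw * (X[, r[1]] - X[, r[2]])
        v <- pmin(pmax(v, lower), upper)
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        u <- ifelse(cross, v, X[, i])
        fu <- fn(u)
        nEval <- nEval + 1L
        if (fu >= fit[i]) { X[, i] <- u; fit[i] <- fu }
      }
      best <- max(fit)
      bestHist <- c(bestHist, best)
      if (iter >= window) {
        gain <- best - bestHist[length(bestHist) - window]
        if (gain < reltol * (abs(best) + reltol)) {
          converged <- TRUE
          break
        }
      }
    }
    i <- which.max(fit)
    list(par = X[, i], value = fit[i], iterations = iter, nEval = nEval,
         converged = converged)
  })
}

## Integer-lattice refinement of the time parameters: for each integer
## (Tb, d) within `radius` of the current optimum, hold the times fixed and
## re-optimize the remaining free parameters (smooth within the cell) by
## L-BFGS-B; keep the best.  No-op when neither time parameter is free.
.latticePolish <- function(fn, de, tb, radius) {
  idxT <- which(tb$free == "Tb")
  idxD <- which(tb$free == "d")
  if (!length(idxT) && !length(idxD)) return(de)
  offsets <- -radius:radius
  gridT <- if (length(idxT))
    unique(pmin(pmax(round(de$par[idxT]) + offsets, tb$lower[idxT]),
                tb$upper[idxT])) else NA_real_
  gridD <- if (length(idxD))
    unique(pmin(pmax(round(de$par[idxD]) + offsets, tb$lower[idxD]),
                tb$upper[idxD])) else NA_real_
  others <- setdiff(seq_along(tb$free), c(idxT, idxD))
  for (Tbv in gridT) for (dv in gridD) {
    x <- de$par
    if (length(idxT)) x[idxT] <- Tbv
    if (length(idxD)) x[idxD] <- dv
    if (length(others)) {
      sub <- tryCatch(
        stats::optim(de$par[others],
                     function(xo) { x[others] <- xo; fn(x) },
                     method = "L-BFGS-B", lower = tb$lower[others],
                     upper = tb$upper[others],
                     control = list(fnscale = -1, maxit = 60L,
                                    factr = 1e3)),
        error = function(e) NULL)
      if (is.null(sub)) next
      x[others] <- sub$par
      val <- sub$value
      de$nEval <- de$nEval + unname(sub$counts[1])
    } else {
      val <- fn(x)
      de$nEval <- de$nEval + 1L
    }
    if (is.finite(val) && val > de$value) {
      de$par <- x
      de$value <- val
    }
  }
  de
}

## evaluate `expr` under set.seed(seed), restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## ---- fitting ---------------------------------------------------------------

#' Maximum-likelihood fit of a demographic model to binned segment counts
#'
#' Maximizes the per-pair Poisson composite log-likelihood, summed over the
#' supplied datasets, by a bounded differential-evolution search over the
#' free parameters of \code{space}.  Inter-parameter constraint violations
#' are handled by a sentinel objective value; the search is deterministic
#' given \code{seed}.  When all parameters are fixed the fixed point is
#' evaluated without a search.
#'
#' @param datasets a [SegmentCountTable-class] or a list of them (each
#'   carries its own bins, pair count and sampling spec).
#' @param type \code{"single"} or \code{"two_pop"}.
#' @param space a [ParameterSpace-class]; default
#'   \code{defaultParameterSpace(type)}.
#' @param genome a [GenomeMap-class].
#' @param seed integer seed for the stochastic search.
#' @param control list of optimizer settings: \code{NP} (population size,
#'   default 10 per free parameter), \code{itermax} (default 300),
#'   \code{reltol} (default 1e-6) and \code{window} (generations over which
#'   the improvement is measured, default 40), plus \code{init} (a named
#'   full parameter vector, or matrix of them, to warm-start from).
#' @return A [FitResult-class].
#' @seealso [refitFixedSubset()], [bootstrapCI()],
#'   [modelSelectionBootstrap()]
#' @export
fitModel <- function(datasets, type = c("single", "two_pop"),
                     space = defaultParameterSpace(type),
                     genome = defaultGenomeMap(), seed = 1,
                     control = list()) {
  type <- match.arg(type)
  preps <- .prepDatasets(datasets, genome, space@upper[["Tb"]])
  tb <- .transformBounds(space)
  obj <- .makeObjective(preps, type, space, tb)

  if (length(tb$free) == 0L) {           # fully fixed: no search
    params <- .decodeParams(numeric(0), space, tb)
    val <- obj(numeric(0))
    return(new("FitResult", modelType = type,
               estimates = params[.MODEL_PARAMS[[type]]], space = space,
               loglik = val,
               diagnostics = list(iterations = 0L, seed = as.integer(seed),
                                  converged = TRUE, nEval = 1L),
               ci = matrix(numeric(0), 0, 2)))
  }

  init <- control$init
  if (!is.null(init)) {
    init <- as.matrix(init)
    init <- apply(init, 2, function(p)
      .encodeParams(p, space, tb), simplify = FALSE)
    init <- do.call(cbind, init)
  }
  nStarts <- control$nStarts %||% 2L
  de <- NULL
  for (s in seq_len(nStarts)) {
    run <- .deOptim(obj, tb$lower, tb$upper,
                    seed = as.integer((seed + (s - 1L) * 1000003) %%
                                        .Machine$integer.max),
                    NP = control$NP, itermax = control$itermax %||% 400L,
                    reltol = control$reltol %||% 1e-6,
                    window = control$window %||% 60L, init = init)
    if (is.null(de) || run$value > de$value) de <- run
  }
  ## Epoch membership of the integer generations changes whenever Tb or
  ## Tb - d crosses an integer, so the likelihood surface is a staircase in
  ## the time parameters: smooth within a unit cell, stepped between cells.
  ## Scan nearby integer (Tb, d) cells, re-optimizing the smooth (size)
  ## parameters within each, then polish.
  lat <- control$latticeRadius %||% 2L
  if (lat > 0L) de <- .latticePolish(obj, de, tb, lat)
  if (control$polish %||% TRUE) {
    ## bounded quasi-Newton polish from the DE optimum: the composite
    ## likelihood surface is smooth but ridged in (Na, Tb, d), which a
    ## population search tracks slowly
    polished <- tryCatch(
      stats::optim(de$par, obj, method = "L-BFGS-B", lower = tb$lower,
                   upper = tb$upper,
                   control = list(fnscale = -1,
                                  maxit = control$polishMaxit %||% 200L,
                                  factr = control$polishFactr %||% 100)),
      error = function(e) NULL)
    if (!is.null(polished) && is.finite(polished$value) &&
        polished$value > de$value) {
      de$par <- polished$par
      de$value <- polished$value
      de$nEval <- de$nEval + unname(polished$counts[1])
    }
  }
  params <- .decodeParams(de$par, space, tb)
  new("FitResult", modelType = type,
      estimates = params[.MODEL_PARAMS[[type]]], space = space,
      loglik = de$value,
      diagnostics = list(iterations = de$iterations,
                         seed = as.integer(seed),
                         converged = de$converged, nEval = de$nEval),
      ci = matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("2.5%", "97.5%"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit with a subset of parameters freed
#'
#' Re-estimates the parameters in \code{free} while holding every other
#' parameter at its value in \code{priorFit}.  This is the building block of
#' the constrained procedures used to reconcile modern and ancient data:
#' e.g. free \code{(Na, Nb)} against ancient ROH (a narrower bottleneck), or
#' free \code{Tb} (a longer bottleneck), then free \code{(d, Nc)} against
#' modern IBD — each step one call, sequenced by the caller.
#'
#' @param priorFit a [FitResult-class].
#' @param free character vector of parameter names to free.
#' @param datasets dataset(s) to fit against.
#' @param genome,seed,control as in [fitModel()].
#' @return A [FitResult-class].
#' @export
refitFixedSubset <- function(priorFit, free, datasets,
                             genome = defaultGenomeMap(), seed = 1,
                             control = list()) {
  stopifnot(is(priorFit, "FitResult"))
  pars <- .MODEL_PARAMS[[priorFit@modelType]]
  if (length(free) == 0L || !all(free %in% pars))
    stop("free must be a non-empty subset of: ", paste(pars, collapse = ", "))
  prior <- priorFit@space
  tied <- prior@tied[setdiff(names(prior@tied), free)]
  fixedNames <- setdiff(pars, c(free, names(tied)))
  space <- new("ParameterSpace", lower = prior@lower, upper = prior@upper,
               fixed = priorFit@estimates[fixedNames], tied = tied,
               logScale = prior@logScale)
  if (is.null(control$init)) control$init <- priorFit@estimates
  fitModel(datasets, type = priorFit@modelType, space = space,
           genome = genome, seed = seed, control = control)
}

#' Parametric-bootstrap confidence intervals
#'
#' For each replicate, every observed bin count \code{K_b} is replaced by a
#' \code{Poisson(K_b)} draw and the model is refit over the same parameter
#' space, warm-started from the point estimate's neighbourhood (with a
#' full-space restart if a replicate fit fails).  Intervals are the
#' [2.5, 97.5] percentiles of the replicate estimates.
#'
#' @param fit a converged [FitResult-class].
#' @param datasets the dataset(s) the fit was computed from.
#' @param nReplicates number of bootstrap replicates (default 100).
#' @param genome,seed,control as in [fitModel()].
#' @return \code{fit} with its \code{ci} slot filled (rows = free
#'   parameters) and replicate estimates in
#'   \code{diagnostics$bootstrapEstimates}.
#' @export
bootstrapCI <- function(fit, datasets, nReplicates = 100,
                        genome = defaultGenomeMap(), seed = 1,
                        control = list()) {
  stopifnot(is(fit, "FitResult"), nReplicates >= 2)
  if (is(datasets, "SegmentCountTable")) datasets <- list(datasets)
  free <- freeParameters(fit@space)
  if (length(free) == 0L) stop("fit has no free parameters")
  reps <- matrix(NA_real_, nReplicates, length(free),
                 dimnames = list(NULL, free))
  failed <- 0L
  for (r in seq_len(nReplicates)) {
    repSeed <- as.integer((seed + 104729 * r) %% .Machine$integer.max)
    bootData <- .withSeed(repSeed, lapply(datasets, function(ds) {
      initialize(ds, counts = as.numeric(stats::rpois(length(ds@counts),
                                                      ds@counts)))
    }))
    ctl <- control
    ctl$init <- fit@estimates
    bootFit <- tryCatch(
      fitModel(bootData, type = fit@modelType, space = fit@space,
               genome = genome, seed = repSeed, control = ctl),
      error = function(e) NULL)
    if (is.null(bootFit)) {             # full-space restart
      ctl$init <- NULL
      bootFit <- tryCatch(
        fitModel(bootData, type = fit@modelType, space = fit@space,
                 genome = genome, seed = repSeed, control = ctl),
        error = function(e) NULL)
    }
    if (is.null(bootFit)) failed <- failed + 1L
    else reps[r, ] <- bootFit@estimates[free]
  }
  if (failed > 0.2 * nReplicates)
    stop(failed, " of ", nReplicates, " bootstrap refits failed")
  if (failed > 0)
    message(failed, " bootstrap replicate(s) failed and were excluded")
  ok <- stats::complete.cases(reps)
  ci <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975)))
  colnames(ci) <- c("2.5%", "97.5%")
  fit@ci <- ci
  fit@diagnostics$bootstrapEstimates <- reps[ok, , drop = FALSE]
  fit@diagnostics$bootstrapSeed <- as.integer(seed)
  fit
}

#' Bootstrap likelihood-ratio model selection
#'
#' Tests whether the two-population split/merge model improves on the
#' single-population model more than expected by chance.  The observed
#' statistic is \code{delta = loglik(two-pop) - loglik(single)} (per-pair
#' scale).  The null distribution is built by parametric bootstrap: counts
#' are redrawn as Poisson variables with means equal to the single-model
#' expectations at its optimum, both models are refit, and the empirical
#' p-value is \code{(1 + #\{delta* >= delta\}) / (nReplicates + 1)}.
#'
#' @param datasets dataset(s) to fit (see [fitModel()]).
#' @param singleSpace,twoPopSpace parameter spaces for the two models.
#' @param nReplicates bootstrap replicates (default 100).
#' @param genome,seed,control as in [fitModel()].
#' @param rohSubpop subgroup assignment given to ROH-mode datasets under the
#'   two-population model (default \code{"bottleneck"}: the ancient sample
#'   represents the bottlenecked subgroup).
#' @return A list with \code{p}, \code{delta}, \code{deltaNull},
#'   \code{singleFit} and \code{twoPopFit}.
#' @export
modelSelectionBootstrap <- function(datasets,
                                    singleSpace = defaultParameterSpace("single"),
                                    twoPopSpace = defaultParameterSpace("two_pop"),
                                    nReplicates = 100,
                                    genome = defaultGenomeMap(), seed = 1,
                                    control = list(),
                                    rohSubpop = "bottleneck") {
  if (is(datasets, "SegmentCountTable")) datasets <- list(datasets)
  datasets2 <- lapply(datasets, .assignSubpop, rohSubpop)

  ## observed and replicate fits go through the identical procedure (same
  ## settings, no asymmetric warm starts), so the optimization-error
  ## component of delta is exchangeable between them
  fitBoth <- function(ds1, ds2, seed) {
    s <- fitModel(ds1, "single", space = singleSpace, genome = genome,
                  seed = seed, control = control)
    ctl <- control
    ctl$init <- .twoPopInit(s@estimates, twoPopSpace)
    t2 <- fitModel(ds2, "two_pop", space = twoPopSpace, genome = genome,
                   seed = seed, control = ctl)
    list(single = s, twoPop = t2, delta = t2@loglik - s@loglik)
  }

  obs <- fitBoth(datasets, datasets2, seed)
  lambdaNull <- .lambdaForDatasets(obs$single@estimates, "single", datasets,
                                   genome, singleSpace@upper[["Tb"]])
  deltaNull <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    repSeed <- as.integer((seed + 15485863 * r) %% .Machine$integer.max)
    simData <- .withSeed(repSeed, mapply(function(ds, lam)
      initialize(ds, counts = as.numeric(stats::rpois(length(lam), lam))),
      datasets, lambdaNull, SIMPLIFY = FALSE))
    simData2 <- lapply(simData, .assignSubpop, rohSubpop)
    deltaNull[r] <- fitBoth(simData, simData2, repSeed)$delta
  }
  list(p = (1 + sum(deltaNull >= obs$delta)) / (nReplicates + 1),
       delta = obs$delta, deltaNull = deltaNull,
       singleFit = obs$single, twoPopFit = obs$twoPop)
}

## expected per-bin counts (P-scaled) for each dataset at `params`
.lambdaForDatasets <- function(params, type, datasets, genome, upperTb) {
  preps <- .prepDatasets(datasets, genome, upperTb)
  lapply(preps, function(prep) {
    raw <- .pmfRaw(params, type, prep$sampling, prep$uFit)
    prep$P * drop(raw$q %*% prep$E)
  })
}

## give ROH-mode datasets a split-epoch subgroup for two-population fits
.assignSubpop <- function(ds, subpop) {
  if (ds@sampling@mode == "ROH" && is.na(ds@sampling@subpop))
    initialize(ds, sampling = initialize(ds@sampling, subpop = subpop))
  else ds
}

## warm start for the two-population model from a single-population optimum
.twoPopInit <- function(singleEst, space) {
  p <- c(singleEst[c("Na", "Nb", "Tb", "d", "Nc")],
         f = 0.9, Ng = unname(singleEst["Nb"]))
  p["Nb"] <- min(p[["Nb"]], p[["Na"]] * 0.98)
  p["Ng"] <- p[["Nb"]]
  pmin(pmax(p, space@lower[names(p)]), space@upper[names(p)])
}
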