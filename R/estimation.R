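#' @include TraceSet.R pathway-model.R nlme.R
NULL

#' Define a least-squares fit problem on trace data
#'
#' Sets up weighted least-squares estimation of a subset of the 18
#' fixed-effect parameters from the cell-aggregated (mean) ratio trace
#' of a \linkS4class{TraceSet}, using a multiple-shooting formulation:
#' the time span is partitioned into \code{nIntervals} shooting
#' intervals whose junction states are free variables tied together by
#' continuity penalties.
#'
#' @param data a \linkS4class{TraceSet} (strain and glucose protocol
#'   are taken from its metadata).
#' @param free non-empty character vector of parameters to estimate.
#' @param fixed template \linkS4class{ModelParameters}; non-free
#'   parameters stay at these values.
#' @param lower,upper optional named bounds for the free parameters
#'   (default: template value / 10 and x 10).
#' @param nIntervals shooting intervals (default 5; 1 = single
#'   shooting).
#' @param weights per-time-point weights (default 1).
#' @param logResiduals fit on the log-ratio scale (default FALSE).
#' @return A \linkS4class{FitProblem}.
#' @export
fitProblem <- function(data, free, fixed = defaultParameters(),
                       lower = NULL, upper = NULL, nIntervals = 5L,
                       weights = NULL, logResiduals = FALSE) {
  stopifnot(is(data, "TraceSet"))
  if (missing(free) || !length(free))
    stop("the free parameter set must be non-empty")
  md <- S4Vectors::metadata(data)
  strain <- md$strainConfig
  profile <- md$profile
  if (is.null(strain) || is.null(profile))
    stop("TraceSet metadata must carry strainConfig and profile")
  th <- parameterVector(fixed)[free]
  if (is.null(lower)) lower <- th / 10
  if (is.null(upper)) upper <- th * 10
  lower <- structure(as.numeric(lower), names = free)
  upper <- structure(as.numeric(upper), names = free)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  new("FitProblem", data = data, fixed = fixed, strain = strain,
      profile = profile, free = free, lower = lower, upper = upper,
      nIntervals = as.integer(nIntervals), weights = as.numeric(weights),
      logResiduals = isTRUE(logResiduals))
}

## Merge free-parameter values into the template.
.mergeTheta <- function(problem, freeValues) {
  th <- parameterVector(problem@fixed)
  th[problem@free] <- freeValues
  modelParameters(th)
}

## Observed aggregate trace: mean over cells at each time point.
.observedAggregate <- function(problem) {
  rowMeans(ratios(problem@data))
}

#' Residuals of a parameter vector against the aggregated trace
#'
#' Simulates the model at \code{theta} (single shooting, from the
#' relaxed pre-shift state) on the data's time grid and returns the
#' weighted differences between simulated and observed mean ratio at
#' every time point.  A solver failure returns a finite large-penalty
#' sentinel (1e3 per point) with a warning rather than an error, so
#' optimizers can retreat from pathological parameter regions.
#'
#' @param theta a \linkS4class{ModelParameters}, or a named vector of
#'   the problem's free parameters.
#' @param problem a \linkS4class{FitProblem}.
#' @return Numeric vector of weighted residuals, one per time point.
#' @export
traceResiduals <- function(theta, problem) {
  stopifnot(is(problem, "FitProblem"))
  params <- if (is(theta, "ModelParameters")) theta
            else .mergeTheta(problem, theta[problem@free])
  obs <- .observedAggregate(problem)
  grid <- traceTimes(problem@data)
  sim <- tryCatch(
    simulateCell(params, problem@strain, problem@profile, grid)@ratio,
    error = function(e) {
      warning("solver failure during residual evaluation: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(sim)) return(rep(1e3, length(obs)))
  if (problem@logResiduals)
    problem@weights * (log(sim) - log(obs))
  else
    problem@weights * (sim - obs)
}

## Shooting-interval bookkeeping: grid indices of the K+1 node points.
.nodeIndex <- function(nt, K) unique(round(seq(1L, nt, length.out = K + 1L)))

## Residual vector of the shooting formulation: data residuals for all
## intervals plus sqrt(mu)-scaled continuity defects at the junctions.
## x = c(log free params, junction states column-wise).
.shootingResiduals <- function(x, problem, nodeIdx, mu) {
  K <- length(nodeIdx) - 1L
  nf <- length(problem@free)
  freeValues <- exp(x[seq_len(nf)])
  params <- .mergeTheta(problem, freeValues)
  nodes <- if (K > 1L)
    matrix(x[-seq_len(nf)], nrow = 8L,
           dimnames = list(.SPECIES_NAMES, NULL))
  else NULL
  grid <- traceTimes(problem@data)
  obs <- .observedAggregate(problem)

  simRatio <- rep(NA_real_, length(grid))
  defects <- numeric(0L)
  ok <- tryCatch({
    y0 <- initialState(params, problem@strain,
                       gex0 = problem@profile@preLevel)
    for (k in seq_len(K)) {
      idx <- nodeIdx[k]:nodeIdx[k + 1L]
      yk <- if (k == 1L) y0 else nodes[, k - 1L]
      tr <- simulateCell(params, problem@strain, problem@profile,
                         grid[idx], y0 = yk)
      simRatio[idx] <- tr@ratio
      if (k < K) {
        yEnd <- tr@states[nrow(tr@states), ]
        defects <- c(defects, yEnd - nodes[, k])
      }
    }
    TRUE
  }, error = function(e) {
    warning("solver failure during shooting evaluation: ",
            conditionMessage(e), call. = FALSE)
    FALSE
  })
  if (!ok)
    return(rep(1e3, length(grid) + 8L * max(K - 1L, 0L)))
  res <- if (problem@logResiduals)
    problem@weights * (log(simRatio) - log(obs))
  else
    problem@weights * (simRatio - obs)
  c(res, sqrt(mu) * defects)
}

#' Fit fixed-effect parameters by multiple shooting
#'
#' Minimizes the weighted residual sum of squares of the aggregated
#' ratio trace over the free parameters (on the log scale, within
#' bounds) jointly with the shooting junction states, using
#' Levenberg-Marquardt least squares.  Continuity is enforced by a
#' quadratic penalty on the junction defects with an increasing weight
#' schedule; the final defects are reported in the result.  Additional
#' randomized starts (multiplicative lognormal jitter of the start
#' point, seeded) can be requested; the best final objective wins.
#'
#' @param problem a \linkS4class{FitProblem}.
#' @param start starting \linkS4class{ModelParameters} (default: the
#'   problem template), or a named vector of free parameters.
#' @param seed integer seed for the randomized extra starts.
#' @param nStarts number of starts (default 1).
#' @param muSchedule increasing continuity penalty weights.
#' @param maxIter Levenberg-Marquardt iteration cap per penalty stage.
#' @return A \linkS4class{FitResult}.
#' @export
fitFixedEffects <- function(problem, start = NULL, seed = 1L,
                            nStarts = 1L,
                            muSchedule = c(1e2, 1e4, 1e6),
                            maxIter = 60L) {
  stopifnot(is(problem, "FitProblem"))
  if (is.null(start)) start <- problem@fixed
  startFree <- if (is(start, "ModelParameters"))
    parameterVector(start)[problem@free]
  else start[problem@free]
  startFree <- pmin(pmax(startFree, problem@lower), problem@upper)

  grid <- traceTimes(problem@data)
  nodeIdx <- .nodeIndex(length(grid), problem@nIntervals)
  K <- length(nodeIdx) - 1L

  runOne <- function(sf) {
    params0 <- .mergeTheta(problem, sf)
    ## junction states initialized from the single-shooting trajectory
    nodes0 <- NULL
    if (K > 1L) {
      tr0 <- simulateCell(params0, problem@strain, problem@profile, grid)
      nodes0 <- t(tr0@states[nodeIdx[2:K], , drop = FALSE])
    }
    x <- c(log(sf), as.vector(nodes0))
    lowerX <- c(log(problem@lower), rep(0, 8L * max(K - 1L, 0L)))
    upperX <- c(log(problem@upper), rep(Inf, 8L * max(K - 1L, 0L)))
    nEv <- 0L
    info <- 0L
    msg <- ""
    for (mu in muSchedule) {
      fit <- minpack.lm::nls.lm(
        par = x, lower = lowerX, upper = upperX,
        fn = .shootingResiduals, problem = problem, nodeIdx = nodeIdx,
        mu = mu,
        ## FD steps must clear the adaptive-solver noise floor (~rtol)
        control = minpack.lm::nls.lm.control(maxiter = maxIter,
                                             ftol = 1e-12, ptol = 1e-10,
                                             epsfcn = 1e-6))
      x <- fit$par
      nEv <- nEv + fit$niter
      info <- fit$info
      msg <- fit$message
      if (K == 1L) break  # no defects to anneal
    }
    final <- .shootingResiduals(x, problem, nodeIdx, mu = 1)
    nRes <- length(grid)
    dataSS <- sum(final[seq_len(nRes)]^2)
    defects <- if (K > 1L) final[-seq_len(nRes)] else numeric(0L)
    list(x = x, dataSS = dataSS, defects = defects, nEv = nEv,
         info = info, msg = msg)
  }

  starts <- list(startFree)
  if (nStarts > 1L) {
    set.seed(as.integer(seed))
    for (k in seq_len(nStarts - 1L))
      starts[[k + 1L]] <- pmin(pmax(
        startFree * exp(stats::rnorm(length(startFree), 0, 0.3)),
        problem@lower), problem@upper)
  }
  runs <- lapply(starts, runOne)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1L), "dataSS"))]]

  thetaHat <- .mergeTheta(problem, exp(best$x[seq_along(problem@free)]))
  scale <- pmax(abs(best$x[-seq_along(problem@free)]), 1e-3)
  relDef <- if (length(best$defects))
    abs(best$defects) / rep_len(scale, length(best$defects))
  else numeric(0L)
  new("FitResult", thetaHat = thetaHat, free = problem@free,
      objective = best$dataSS, defects = abs(best$defects),
      relDefects = relDef, converged = best$info %in% 1:4,
      nEvals = as.integer(best$nEv), message = best$msg)
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective %.4e, %s after %d iterations\n",
              object@objective,
              if (object@converged) "converged" else "NOT converged",
              object@nEvals))
  if (length(object@defects))
    cat(sprintf("  max continuity defect %.2e (relative %.2e)\n",
                max(object@defects), max(object@relDefects)))
  print(signif(parameterVector(object@thetaHat)[object@free], 5))
})

#' @rdname accessors
#' @export
setMethod("parameterVector", "FitResult", function(object)
  parameterVector(object@thetaHat))

#' Diagonal random-effect covariance from per-cell refits
#'
#' Builds the empirical log-scale covariance of the cell-to-cell
#' variation from per-cell fit results: the diagonal entry of each
#' fitted parameter is the sample variance of
#' \eqn{\log(\hat\theta_i / \bar\theta_i)} across cells (scale
#' invariant); all other entries are 0.
#'
#' @param fits list of at least two \linkS4class{FitResult}s, one per
#'   cell, sharing the same free parameter set.
#' @param fixed the reference \linkS4class{ModelParameters}
#'   (\eqn{\bar\theta}).
#' @return 18 x 18 diagonal covariance matrix.
#' @export
estimateCovarianceDiagonal <- function(fits, fixed) {
  if (length(fits) < 2L)
    stop("at least 2 per-cell fits are required")
  free <- fits[[1L]]@free
  thBar <- parameterVector(fixed)
  lr <- vapply(fits, function(f)
    log(parameterVector(f@thetaHat)[free] / thBar[free]),
    numeric(length(free)))
  lr <- matrix(lr, nrow = length(free),
               dimnames = list(free, NULL))
  v <- apply(lr, 1L, stats::var)
  sigma <- diagonalCovariance(0)
  diag(sigma)[match(free, .PARAM_NAMES)] <- v
  sigma
}
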