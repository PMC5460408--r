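#' @include TraceSet.R pathway-model.R
NULL

#' Diagonal random-effect covariance
#'
#' Convenience constructor for the default diagonal log-scale
#' covariance of the cell-to-cell random effects.
#'
#' @param variance scalar or length-18 vector of log-scale variances
#'   (default 0.04, i.e. ~20\% cell-to-cell parameter variation).
#' @return 18 x 18 matrix with dimnames \code{parameterNames()}.
#' @export
diagonalCovariance <- function(variance = 0.04) {
  v <- rep_len(variance, 18L)
  m <- diag(v, 18L)
  dimnames(m) <- list(.PARAM_NAMES, .PARAM_NAMES)
  m
}

#' Validate a random-effect covariance matrix
#'
#' @param sigma 18 x 18 symmetric positive-semidefinite matrix.
#' @return The matrix (with canonical dimnames), invisibly usable.
#' @export
validateCovariance <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!identical(dim(sigma), c(18L, 18L)))
    stop("sigma must be an 18 x 18 matrix")
  if (max(abs(sigma - t(sigma))) > 1e-12)
    stop("sigma must be symmetric (tolerance 1e-12)")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop(sprintf("sigma is not positive-semidefinite: eigenvalue %.3e",
                 min(ev)))
  dimnames(sigma) <- list(.PARAM_NAMES, .PARAM_NAMES)
  sigma
}

## Deterministic per-cell substream: cell j of a population seeded with
## `seed` always sees the same RNG state regardless of how many other
## cells are drawn or in which order.  `stream` separates independent
## uses (0 = design-level, 1 = random effects, 2 = size, 3 = noise).
.cellSeed <- function(seed, j, stream = 1L) {
  as.integer((as.numeric(seed) %% 1e9) * 1009 + j * 101 + stream * 7919) %%
    2147483647L
}

#' Draw individual cells from the lognormal NLME law
#'
#' Individual parameter vectors follow \eqn{\theta = \bar\theta \cdot
#' \exp(\eta)} elementwise with \eqn{\eta \sim N(0, \sigma)} on the log
#' scale, so \eqn{\bar\theta} is the population median.  Each cell uses
#' its own deterministic RNG substream derived from the master seed, so
#' draws are reproducible and independent of population size and order.
#'
#' @param fixed a \linkS4class{ModelParameters} (the fixed effects).
#' @param sigma 18 x 18 covariance of the log-scale random effects.
#' @param n number of cells (>= 1).
#' @param seed integer master seed.
#' @param cellId optional identifiers (default \code{cell_001} ...).
#' @return An \linkS4class{IndividualDraws}.
#' @examples
#' d <- sampleIndividuals(defaultParameters(), diagonalCovariance(), 5, 1)
#' d
#' @export
sampleIndividuals <- function(fixed, sigma, n, seed, cellId = NULL) {
  stopifnot(is(fixed, "ModelParameters"), n >= 1)
  sigma <- validateCovariance(sigma)
  n <- as.integer(n)
  if (is.null(cellId)) cellId <- sprintf("cell_%03d", seq_len(n))
  eta <- matrix(0, 18L, n, dimnames = list(.PARAM_NAMES, cellId))
  for (j in seq_len(n)) {
    set.seed(.cellSeed(seed, j, stream = 1L))
    eta[, j] <- MASS::mvrnorm(1L, mu = rep(0, 18L), Sigma = sigma)
  }
  theta <- fixed@theta * exp(eta)
  new("IndividualDraws", cellId = cellId, eta = eta, theta = theta,
      thetaBar = fixed@theta)
}

#' @rdname trace-accessors
#' @export
setMethod("etaMatrix", "IndividualDraws", function(object) object@eta)

#' @rdname trace-accessors
#' @export
setMethod("thetaMatrix", "IndividualDraws", function(object) object@theta)

#' @rdname trace-accessors
#' @export
setMethod("nCells", "IndividualDraws", function(object)
  length(object@cellId))

setMethod("show", "IndividualDraws", function(object) {
  cat(sprintf("IndividualDraws: %d cells, 18 parameters\n",
              length(object@cellId)))
  cat(sprintf("  |eta| range: [%.3g, %.3g]\n", min(abs(object@eta)),
              max(abs(object@eta))))
})

#' Simulate a population of single cells (noise-free)
#'
#' Draws \code{n} individuals from the NLME law and integrates each
#' cell through the upshift.  The observed ratio equals the model ratio
#' (no measurement noise); use \code{\link{generateExperiment}} for
#' full synthetic experiments.
#'
#' @inheritParams sampleIndividuals
#' @param strain a \linkS4class{StrainConfig}.
#' @param profile a \linkS4class{GlucoseProfile}.
#' @param timeGrid shared time grid, minutes.
#' @param size per-cell size metadata (default 1; the noise-free
#'   population simulation does not model size).
#' @return A synthetic \linkS4class{TraceSet} whose \code{ratio} and
#'   \code{trueRatio} assays coincide.
#' @export
simulatePopulation <- function(fixed, sigma, n, strain, profile,
                               timeGrid = seq(0, 15, by = 0.5), seed = 1L,
                               size = rep(1, n)) {
  draws <- sampleIndividuals(fixed, sigma, n, seed)
  th <- thetaMatrix(draws)
  ratio <- matrix(NA_real_, length(timeGrid), nCells(draws))
  for (j in seq_len(nCells(draws))) {
    tr <- tryCatch(
      simulateCell(modelParameters(th[, j]), strain, profile, timeGrid),
      error = function(e) stop("cell ", draws@cellId[j], ": ",
                               conditionMessage(e), call. = FALSE))
    ratio[, j] <- tr@ratio
  }
  TraceSet(ratio = ratio, time = timeGrid, cellId = draws@cellId,
           size = size, strain = strain, profile = profile,
           trueRatio = ratio, theta = th, eta = etaMatrix(draws),
           thetaBar = fixed, covariance = validateCovariance(sigma),
           design = NULL, seed = as.integer(seed), synthetic = TRUE)
}

#' Random-effect magnitude heat map data
#'
#' Draws \code{nDraws} random-effect vectors \eqn{\eta \sim N(0,
#' \sigma)} and returns the matrix of magnitudes \eqn{|\eta|}
#' (parameters x individuals) used for population heat-map displays.
#' Rows for the uptake parameters of transporters absent from the
#' strain are masked as \code{NA} (they cannot influence the model
#' output); the masked names are attached as the \code{"masked"}
#' attribute.
#'
#' @inheritParams sampleIndividuals
#' @param strain a \linkS4class{StrainConfig}.
#' @param nDraws number of individuals (default 50).
#' @return 18 x \code{nDraws} numeric matrix with \code{NA} in masked
#'   rows and attribute \code{masked}.
#' @export
randomEffectHeatmap <- function(fixed, sigma, strain, nDraws = 50L,
                                seed = 1L) {
  stopifnot(nDraws >= 1)
  draws <- sampleIndividuals(fixed, sigma, nDraws, seed,
                             cellId = sprintf("ind_%02d", seq_len(nDraws)))
  m <- abs(etaMatrix(draws))
  masked <- maskedParameters(strain)
  m[masked, ] <- NA_real_
  attr(m, "masked") <- masked
  m
}
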