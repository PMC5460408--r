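#' @include nlme.R
NULL

#' Construct an ExperimentDesign
#'
#' Describes one synthetic microfluidics-style experiment.  Defaults
#' emulate the imaging protocol: a step from 0 mM to one of the
#' protocol levels at t = 0, a 15-minute post-upshift observation
#' window sampled every 0.5 min with 2 min of pre-shift baseline, a
#' per-experiment cell count drawn uniformly from 22..41
#' (\code{nCells = "paper-range"}), and 5\% multiplicative lognormal
#' measurement noise.
#'
#' @param strain a \linkS4class{StrainConfig} or a strain label.
#' @param postLevel post-shift glucose, mM (default 220).
#' @param nCells count or \code{"paper-range"} (default).
#' @param samplingInterval minutes between samples (default 0.5).
#' @param preTime minutes of pre-shift baseline (default 2).
#' @param duration minutes of post-shift observation (default 15).
#' @param noiseCv measurement noise CV (default 0.05).
#' @param sizeMean,sizeSd cell-size distribution, arbitrary units
#'   (default 30 +/- 6).
#' @param sizeEffect coupling of standardized log size to the nuclear
#'   import capacity kim1 (default 0 = sizes independent of kinetics).
#' @param seed integer master seed.
#' @return An \linkS4class{ExperimentDesign}.
#' @examples
#' experimentDesign("HXT1", postLevel = 55, nCells = 30, seed = 7)
#' @export
experimentDesign <- function(strain = "WT", postLevel = 220,
                             nCells = "paper-range",
                             samplingInterval = 0.5, preTime = 2,
                             duration = 15, noiseCv = 0.05,
                             sizeMean = 30, sizeSd = 6, sizeEffect = 0,
                             seed = 1L) {
  if (is.character(strain)) strain <- strainConfig(strain)
  new("ExperimentDesign", strain = strain,
      profile = glucoseProfile(postLevel),
      nCells = if (is.character(nCells)) nCells else as.integer(nCells),
      samplingInterval = as.numeric(samplingInterval),
      preTime = as.numeric(preTime), duration = as.numeric(duration),
      noiseCv = as.numeric(noiseCv), sizeMean = as.numeric(sizeMean),
      sizeSd = as.numeric(sizeSd), sizeEffect = as.numeric(sizeEffect),
      seed = as.integer(seed))
}

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(paste0("ExperimentDesign: strain %s, 0 -> %g mM, ",
                     "%s cells, grid [-%g, %g] by %g min, noise CV %g\n"),
              strainLabel(object@strain), object@profile@postLevel,
              if (is.character(object@nCells)) "22-41" else object@nCells,
              object@preTime, object@duration, object@samplingInterval,
              object@noiseCv))
})

## Resolve "paper-range" cell counts on the design-level substream.
.resolveCellCount <- function(design) {
  if (is.numeric(design@nCells)) return(as.integer(design@nCells))
  set.seed(.cellSeed(design@seed, 0L, stream = 0L))
  sample(22:41, 1L)
}

#' Sampling grid of a design
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @return Time grid in minutes, from \code{-preTime} to
#'   \code{duration} in steps of \code{samplingInterval} (upshift at 0).
#' @export
designTimeGrid <- function(design) {
  seq(-design@preTime, design@duration, by = design@samplingInterval)
}

#' Generate a synthetic single-cell experiment
#'
#' The end-to-end generator emulating one imaging experiment:
#' individuals are drawn from the lognormal NLME law, each cell is
#' integrated through the upshift, cell sizes are drawn lognormally,
#' and the observed ratio is the model ratio times multiplicative
#' lognormal noise with coefficient of variation \code{noiseCv}.  With
#' \code{sizeEffect} = 0 sizes are independent of the kinetic
#' parameters; a non-zero value adds \code{sizeEffect * z} (z the
#' standardized log size) to the random effect of \code{kim1}, planting
#' a size-response association.  Everything is reproducible from the
#' design seed.
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param fixed a \linkS4class{ModelParameters} (default
#'   \code{defaultParameters()}).
#' @param sigma 18 x 18 random-effect covariance (default
#'   \code{diagonalCovariance()}).
#' @return A synthetic \linkS4class{TraceSet} with \code{ratio}
#'   (observed) and \code{trueRatio} (noise-free) assays and full
#'   provenance in \code{metadata()}.
#' @examples
#' ts <- generateExperiment(experimentDesign("HXT1", nCells = 5, seed = 2))
#' ts
#' @export
generateExperiment <- function(design, fixed = defaultParameters(),
                               sigma = diagonalCovariance()) {
  stopifnot(is(design, "ExperimentDesign"))
  n <- .resolveCellCount(design)
  grid <- designTimeGrid(design)
  seed <- design@seed
  draws <- sampleIndividuals(fixed, sigma, n, seed)
  eta <- etaMatrix(draws)

  ## cell sizes: lognormal with the requested mean/sd on natural scale
  sdlog <- sqrt(log(1 + (design@sizeSd / design@sizeMean)^2))
  meanlog <- log(design@sizeMean) - sdlog^2 / 2
  size <- numeric(n)
  for (j in seq_len(n)) {
    set.seed(.cellSeed(seed, j, stream = 2L))
    size[j] <- stats::rlnorm(1L, meanlog, sdlog)
  }
  if (design@sizeEffect != 0 && sdlog > 0) {
    z <- (log(size) - meanlog) / sdlog
    eta["kim1", ] <- eta["kim1", ] + design@sizeEffect * z
  }
  theta <- parameterVector(fixed) * exp(eta)

  noiseSdlog <- sqrt(log(1 + design@noiseCv^2))
  true <- obs <- matrix(NA_real_, length(grid), n)
  ## cells sharing one parameter vector (e.g. sigma = 0) integrate once
  key <- apply(theta, 2L, paste, collapse = "\r")
  cache <- new.env(parent = emptyenv())
  for (j in seq_len(n)) {
    if (is.null(cache[[key[j]]])) {
      tr <- tryCatch(
        simulateCell(modelParameters(theta[, j]), design@strain,
                     design@profile, grid),
        error = function(e) stop("cell ", draws@cellId[j], ": ",
                                 conditionMessage(e), call. = FALSE))
      cache[[key[j]]] <- tr@ratio
    }
    true[, j] <- cache[[key[j]]]
    if (noiseSdlog > 0) {
      set.seed(.cellSeed(seed, j, stream = 3L))
      obs[, j] <- tr@ratio * stats::rlnorm(length(grid), 0, noiseSdlog)
    } else {
      obs[, j] <- tr@ratio
    }
  }

  TraceSet(ratio = obs, time = grid, cellId = draws@cellId, size = size,
           strain = design@strain, profile = design@profile,
           trueRatio = true, theta = theta, eta = eta, thetaBar = fixed,
           covariance = validateCovariance(sigma), design = design,
           seed = seed, synthetic = TRUE)
}

#' Convert glucose mM to percent weight/volume
#'
#' \code{percent = mM * 180.16 / 10000} (grams of glucose per 100 mL).
#' \code{glucosePercentLabel} applies the one-significant-digit display
#' rounding used for the protocol presets, mapping 0, 2.75, 11, 27.5,
#' 55 and 220 mM to 0, 0.05, 0.2, 0.5, 1 and 4\%.
#'
#' @param mM glucose concentration(s), mM, non-negative.
#' @return \code{mmToPercent}: percent w/v; \code{glucosePercentLabel}:
#'   display-rounded percent.
#' @examples
#' mmToPercent(220)            # 3.9635
#' glucosePercentLabel(220)    # 4
#' @export
mmToPercent <- function(mM) {
  if (any(!is.finite(mM) | mM < 0))
    stop("glucose concentration must be finite and non-negative")
  mM * 180.16 / 10000
}

#' @rdname mmToPercent
#' @export
glucosePercentLabel <- function(mM) signif(mmToPercent(mM), 1)
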