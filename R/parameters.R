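#' @include AllClasses.R AllGenerics.R
NULL

## Default fixed-effect calibration (see the methods vignette).  The
## transporter affinities follow the low/high-affinity physiology
## (km1 = 100 mM for Hxt1, km4 = 10 mM for Hxt4, km7 = 1 mM for Hxt7,
## vm1 > vm4 > vm7); the remaining rates are calibrated once so that the
## three strain backgrounds show the expected qualitative phenotypes: a
## graded HXT1 response over 2.75-220 mM upshifts, a near-constant HXT7
## response, and a population responder-fraction peak ~1 min after the
## upshift (fast Gin turnover and nucleocytoplasmic shuttling).
.DEFAULT_THETA <- c(vm1 = 2.5, km1 = 100, vm4 = 1.0, km4 = 10,
                    vm7 = 0.6, km7 = 1, kmet = 6,
                    vmsi = 8, kg5 = 0.05, ksp = 1,
                    kin7 = 4, kout7 = 4,
                    k8 = 18, kex1 = 5.4, kex2 = 0.1,
                    kim1 = 4.8, kim2 = 0.1, vmd = 18)

#' Construct a ModelParameters object
#'
#' @param theta named numeric vector or list covering all 18 parameters
#'   (any order; names must be exactly \code{parameterNames()}), or a
#'   bare numeric(18) taken to be in canonical order.
#' @return A \linkS4class{ModelParameters}.
#' @examples
#' p <- defaultParameters()
#' p2 <- modelParameters(replace(parameterVector(p), "vmd", 3))
#' @export
modelParameters <- function(theta) {
  theta <- unlist(theta)
  if (is.null(names(theta)) && length(theta) == 18L) {
    names(theta) <- .PARAM_NAMES
  } else {
    miss <- setdiff(.PARAM_NAMES, names(theta))
    extra <- setdiff(names(theta), .PARAM_NAMES)
    if (length(miss) || length(extra))
      stop("theta must name exactly the 18 canonical parameters; ",
           if (length(miss)) paste("missing:", paste(miss, collapse = ", ")),
           if (length(extra)) paste(" unknown:", paste(extra, collapse = ", ")))
    theta <- theta[.PARAM_NAMES]
  }
  new("ModelParameters", theta = theta)
}

#' Default fixed-effect parameter set
#'
#' The shipped calibration of the 18-parameter pathway model (time in
#' minutes, glucose in mM, total Mig1 = total Snf1 = 1).  The same
#' values are versioned as a YAML preset under
#' \code{system.file("extdata", "default_parameters.yaml", package =
#' "MigFlux")}.
#'
#' @return A \linkS4class{ModelParameters}.
#' @export
defaultParameters <- function() modelParameters(.DEFAULT_THETA)

#' @rdname accessors
#' @export
setMethod("parameterVector", "ModelParameters", function(object) object@theta)

#' @rdname accessors
#' @export
setMethod("parameterVector", "IndividualDraws",
          function(object) object@thetaBar)

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (18 fixed effects)\n")
  print(signif(object@theta, 4))
})

#' Construct a StrainConfig
#'
#' @param label one of \code{"WT"}, \code{"HXT1"}, \code{"HXT7"}, or any
#'   label when the indicators are given explicitly.
#' @param hxt1a,hxt4a,hxt7a binary transporter indicators; defaults come
#'   from the label presets (WT = 1,1,1; HXT1 = 1,0,0; HXT7 = 0,0,1).
#' @return A \linkS4class{StrainConfig}.
#' @examples
#' strainConfig("HXT1")
#' @export
strainConfig <- function(label = "WT", hxt1a = NULL, hxt4a = NULL,
                         hxt7a = NULL) {
  presets <- list(WT = c(1L, 1L, 1L), HXT1 = c(1L, 0L, 0L),
                  HXT7 = c(0L, 0L, 1L))
  if (is.null(hxt1a) || is.null(hxt4a) || is.null(hxt7a)) {
    if (!label %in% names(presets))
      stop("unknown strain label '", label,
           "'; give hxt1a/hxt4a/hxt7a explicitly")
    ind <- presets[[label]]
  } else {
    ind <- as.integer(c(hxt1a, hxt4a, hxt7a))
  }
  new("StrainConfig", hxt1a = ind[1L], hxt4a = ind[2L], hxt7a = ind[3L],
      label = label)
}

#' @rdname accessors
#' @export
setMethod("transporterFlags", "StrainConfig", function(object)
  c(hxt1a = object@hxt1a, hxt4a = object@hxt4a, hxt7a = object@hxt7a))

#' @rdname accessors
#' @export
setMethod("strainLabel", "StrainConfig", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("maskedParameters", "StrainConfig", function(object) {
  flags <- transporterFlags(object)
  out <- unlist(.TRANSPORTER_PARAMS[names(flags)[flags == 0L]],
                use.names = FALSE)
  if (is.null(out)) character(0) else out
})

setMethod("show", "StrainConfig", function(object) {
  f <- transporterFlags(object)
  cat(sprintf("StrainConfig '%s' (HXT1a=%d, HXT4a=%d, HXT7a=%d)\n",
              object@label, f[1L], f[2L], f[3L]))
})

#' Construct a GlucoseProfile
#'
#' A step upshift of extracellular glucose, by default from 0 mM.  The
#' imaging experiments used post-shift levels of 0, 2.75, 11, 27.5, 55
#' or 220 mM; arbitrary non-negative levels are accepted.
#'
#' @param postLevel mM after the shift.
#' @param preLevel mM before the shift (default 0).
#' @param shiftTime minutes at which the step occurs (default 0).
#' @return A \linkS4class{GlucoseProfile}.
#' @examples
#' glucoseProfile(220)
#' @export
glucoseProfile <- function(postLevel, preLevel = 0, shiftTime = 0) {
  new("GlucoseProfile", preLevel = as.numeric(preLevel),
      postLevel = as.numeric(postLevel), shiftTime = as.numeric(shiftTime))
}

#' Extracellular glucose at a given time
#'
#' @param profile a \linkS4class{GlucoseProfile}.
#' @param t time(s) in minutes.
#' @return mM, vectorized over \code{t}; the post-shift level applies
#'   from \code{shiftTime} onwards (right-continuous step).
#' @export
glucoseAt <- function(profile, t) {
  ifelse(t < profile@shiftTime, profile@preLevel, profile@postLevel)
}

#' Paper-protocol glucose upshift levels
#'
#' @return The six post-shift glucose levels (mM) used across the
#'   imaging experiments.
#' @export
paperUpshifts <- function() .PAPER_UPSHIFTS

setMethod("show", "GlucoseProfile", function(object) {
  cat(sprintf("GlucoseProfile: %g -> %g mM at t = %g min\n",
              object@preLevel, object@postLevel, object@shiftTime))
})

#' Read and write parameter sets
#'
#' Parameter sets serialize to YAML or JSON (chosen by file extension)
#' as both an ordered 18-vector and a named map; numeric values
#' round-trip at full double precision.
#'
#' @param path file path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @param params a \linkS4class{ModelParameters}.
#' @return \code{readParameters} returns a
#'   \linkS4class{ModelParameters}; \code{writeParameters} invisibly
#'   returns \code{path}.
#' @export
readParameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path),
                stop("unsupported parameter file extension: .", ext))
  named <- unlist(obj$parameters)
  ordered <- as.numeric(unlist(obj$ordered))
  p <- modelParameters(named)
  if (!is.null(ordered) && !identical(unname(p@theta), ordered))
    stop("ordered vector and named map disagree in ", path)
  p
}

#' @rdname readParameters
#' @export
writeParameters <- function(params, path) {
  stopifnot(is(params, "ModelParameters"))
  th <- params@theta
  ext <- tolower(tools::file_ext(path))
  ## full 17-significant-digit decimal strings round-trip doubles exactly
  fmt <- function(x) as.numeric(sprintf("%.17g", x))
  obj <- list(order = as.list(.PARAM_NAMES),
              ordered = lapply(unname(th), fmt),
              parameters = lapply(as.list(th), fmt))
  switch(ext,
         yaml = , yml = yaml::write_yaml(obj, path, precision = 17L),
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                     digits = I(17)),
         stop("unsupported parameter file extension: .", ext))
  invisible(path)
}
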