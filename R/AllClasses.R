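#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Canonical orderings used throughout the package.  Every vector, matrix
## row and serialized parameter set follows these names in this order.
.PARAM_NAMES <- c("vm1", "km1", "vm4", "km4", "vm7", "km7", "kmet",
                  "vmsi", "kg5", "ksp", "kin7", "kout7",
                  "k8", "kex1", "kex2", "kim1", "kim2", "vmd")

.SPECIES_NAMES <- c("gin", "csnf1", "csnf1p", "nsnf1p",
                    "cmig1p", "cmig1", "nmig1", "nmig1p")

.RATE_NAMES <- c("r1i", "r4i", "r7i", "r4", "r5", "r6",
                 "r7a", "r7b", "r1", "r2", "r3", "r8")

## Transporter-linked uptake parameters, masked when the strain lacks
## the transporter.
.TRANSPORTER_PARAMS <- list(hxt1a = c("vm1", "km1"),
                            hxt4a = c("vm4", "km4"),
                            hxt7a = c("vm7", "km7"))

.PAPER_UPSHIFTS <- c(0, 2.75, 11, 27.5, 55, 220)

#' Canonical parameter, species and reaction names
#'
#' The dynamical model has 8 species, 12 reactions and 18 parameters.
#' These helpers expose the canonical orderings (indices 1..18 for
#' parameters) used by every function in the package.
#'
#' @return A character vector of names in canonical order.
#' @examples
#' parameterNames()
#' speciesNames()
#' reactionNames()
#' @export
parameterNames <- function() .PARAM_NAMES

#' @rdname parameterNames
#' @export
speciesNames <- function() .SPECIES_NAMES

#' @rdname parameterNames
#' @export
reactionNames <- function() .RATE_NAMES

#' StrainConfig: transporter presence switches for a strain background
#'
#' Three binary indicators (\code{hxt1a}, \code{hxt4a}, \code{hxt7a})
#' select which hexose-uptake reactions are active.  The three study
#' backgrounds are \code{"WT"} (1,1,1), \code{"HXT1"} (1,0,0) and
#' \code{"HXT7"} (0,0,1).
#'
#' @slot hxt1a,hxt4a,hxt7a integer(1), exactly 0 or 1.
#' @slot label character(1) strain name.
#' @export
setClass("StrainConfig",
         representation(hxt1a = "integer", hxt4a = "integer",
                        hxt7a = "integer", label = "character"))

setValidity("StrainConfig", function(object) {
  ind <- c(object@hxt1a, object@hxt4a, object@hxt7a)
  if (length(ind) != 3L || !all(ind %in% c(0L, 1L)))
    return("transporter indicators must each be exactly 0 or 1")
  presets <- list(WT = c(1L, 1L, 1L), HXT1 = c(1L, 0L, 0L),
                  HXT7 = c(0L, 0L, 1L))
  if (object@label %in% names(presets) &&
      !identical(ind, presets[[object@label]]))
    return(sprintf("label '%s' requires indicators (%s)", object@label,
                   paste(presets[[object@label]], collapse = ",")))
  TRUE
})

#' ModelParameters: the 18 fixed-effect parameters of the pathway model
#'
#' An ordered, strictly positive named vector of the 18 kinetic
#' parameters (see \code{\link{parameterNames}} for the canonical order):
#' transporter uptake Vmax/Km pairs (\code{vm1}/\code{km1},
#' \code{vm4}/\code{km4}, \code{vm7}/\code{km7}), intracellular glucose
#' consumption \code{kmet}, Snf1p dephosphorylation capacity \code{vmsi}
#' with glucose half-saturation \code{kg5}, Snf1 phosphorylation
#' \code{ksp}, nuclear Snf1p shuttling \code{kin7}/\code{kout7}, nuclear
#' Mig1 phosphorylation \code{k8}, Mig1 nuclear export \code{kex1}/
#' \code{kex2} and import \code{kim1}/\code{kim2}, and cytosolic Mig1
#' dephosphorylation \code{vmd}.
#'
#' @slot theta named numeric(18), strictly positive, canonical order.
#' @export
setClass("ModelParameters", representation(theta = "numeric"))

setValidity("ModelParameters", function(object) {
  th <- object@theta
  if (length(th) != 18L)
    return("theta must contain exactly 18 parameters")
  if (!identical(names(th), .PARAM_NAMES))
    return("theta names must equal parameterNames() in canonical order")
  bad <- names(th)[!is.finite(th) | th <= 0]
  if (length(bad))
    return(sprintf("parameters must be finite and strictly positive: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' GlucoseProfile: a step upshift of extracellular glucose
#'
#' Extracellular glucose is \code{preLevel} mM before \code{shiftTime}
#' (minutes) and \code{postLevel} mM from \code{shiftTime} onwards.
#'
#' @slot preLevel,postLevel numeric(1), mM, non-negative.
#' @slot shiftTime numeric(1), minutes.
#' @export
setClass("GlucoseProfile",
         representation(preLevel = "numeric", postLevel = "numeric",
                        shiftTime = "numeric"))

setValidity("GlucoseProfile", function(object) {
  if (length(object@preLevel) != 1L || length(object@postLevel) != 1L ||
      length(object@shiftTime) != 1L)
    return("preLevel, postLevel and shiftTime must be scalars")
  if (!is.finite(object@preLevel) || object@preLevel < 0 ||
      !is.finite(object@postLevel) || object@postLevel < 0)
    return("glucose levels must be finite and non-negative")
  if (!is.finite(object@shiftTime))
    return("shiftTime must be finite")
  TRUE
})

#' Trajectory: a simulated single-cell time course
#'
#' Holds the time grid (minutes), the 8-species state matrix (one row
#' per time point, columns in \code{\link{speciesNames}} order) and the
#' derived nuclear/cytosolic Mig1 ratio.
#'
#' @slot time strictly increasing numeric vector, minutes.
#' @slot states numeric matrix, \code{length(time)} x 8.
#' @slot ratio numeric vector, same length as \code{time}.
#' @export
setClass("Trajectory",
         representation(time = "numeric", states = "matrix",
                        ratio = "numeric"))

setValidity("Trajectory", function(object) {
  n <- length(object@time)
  if (n > 1L && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (!identical(colnames(object@states), .SPECIES_NAMES))
    return("states columns must equal speciesNames()")
  if (nrow(object@states) != n || length(object@ratio) != n)
    return("states and ratio must have one entry per time point")
  TRUE
})

#' IndividualDraws: per-cell parameter draws from the NLME law
#'
#' Random effects \eqn{\eta \sim N(0, \sigma)} on the log scale and the
#' implied individual parameters \eqn{\theta = \bar\theta \exp(\eta)}
#' (elementwise), one column per cell.
#'
#' @slot cellId character vector of cell identifiers.
#' @slot eta 18 x n matrix of random effects.
#' @slot theta 18 x n matrix of individual parameters.
#' @slot thetaBar named numeric(18) fixed effects.
#' @export
setClass("IndividualDraws",
         representation(cellId = "character", eta = "matrix",
                        theta = "matrix", thetaBar = "numeric"))

setValidity("IndividualDraws", function(object) {
  n <- length(object@cellId)
  if (!identical(dim(object@eta), c(18L, as.integer(n))) ||
      !identical(dim(object@theta), c(18L, as.integer(n))))
    return("eta and theta must be 18 x n matrices")
  if (!identical(rownames(object@eta), .PARAM_NAMES) ||
      !identical(rownames(object@theta), .PARAM_NAMES))
    return("eta and theta rows must equal parameterNames()")
  if (!all(object@theta == object@thetaBar * exp(object@eta)))
    return("theta must equal thetaBar * exp(eta) exactly")
  TRUE
})

#' ExperimentDesign: a microfluidics-style synthetic experiment
#'
#' Describes one simulated glucose-upshift experiment: strain, upshift
#' protocol, number of cells (\code{"paper-range"} draws uniformly from
#' 22..41 as in the imaging experiments), sampling grid, multiplicative
#' measurement noise and the cell-size model.
#'
#' @slot strain a \linkS4class{StrainConfig}.
#' @slot profile a \linkS4class{GlucoseProfile}.
#' @slot nCells integer count or the string \code{"paper-range"}.
#' @slot samplingInterval numeric(1), minutes between samples.
#' @slot preTime numeric(1), minutes of pre-shift baseline recorded.
#' @slot duration numeric(1), minutes of post-shift observation.
#' @slot noiseCv numeric(1), coefficient of variation of the
#'   multiplicative lognormal measurement noise.
#' @slot sizeMean,sizeSd numeric(1), mean and sd of the lognormal cell
#'   size distribution (arbitrary units).
#' @slot sizeEffect numeric(1), coupling of standardized log cell size
#'   to the nuclear-import capacity \code{kim1} (0 = independent).
#' @slot seed integer(1) master seed.
#' @export
setClass("ExperimentDesign",
         representation(strain = "StrainConfig", profile = "GlucoseProfile",
                        nCells = "ANY", samplingInterval = "numeric",
                        preTime = "numeric", duration = "numeric",
                        noiseCv = "numeric", sizeMean = "numeric",
                        sizeSd = "numeric", sizeEffect = "numeric",
                        seed = "integer"))

setValidity("ExperimentDesign", function(object) {
  n <- object@nCells
  okN <- (is.character(n) && identical(n, "paper-range")) ||
    (is.numeric(n) && length(n) == 1L && n >= 1 && n == round(n))
  if (!okN) return("nCells must be a positive count or \"paper-range\"")
  if (object@samplingInterval <= 0) return("samplingInterval must be > 0")
  if (object@preTime < 0) return("preTime must be >= 0")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (object@sizeMean <= 0 || object@sizeSd < 0)
    return("sizeMean must be > 0 and sizeSd >= 0")
  TRUE
})

#' TraceSet: a collection of single-cell ratio traces
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"ratio"} assay
#' is a time-points x cells matrix of observed nuclear/cytosolic Mig1
#' ratios; synthetic sets additionally carry a \code{"trueRatio"} assay
#' (noise-free) and full generative provenance (design, seed, fixed
#' effects, covariance, per-cell theta and eta) in \code{metadata()}.
#' \code{rowData()$time_min} is the shared time grid (minutes, upshift
#' at 0); \code{colData()} holds \code{cell_id}, \code{size_au},
#' \code{strain}, \code{gex_pre_mM} and \code{gex_post_mM}.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  if (!"ratio" %in% SummarizedExperiment::assayNames(object))
    return("TraceSet requires a 'ratio' assay")
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_min" %in% colnames(rd))
    return("rowData must contain a time_min column")
  tm <- rd$time_min
  if (length(tm) > 1L && any(diff(tm) <= 0))
    return("time_min must be strictly increasing")
  r <- SummarizedExperiment::assay(object, "ratio")
  if (any(!is.finite(r)) || any(r <= 0))
    return("observed ratios must be finite and strictly positive")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_id", "size_au", "strain", "gex_pre_mM", "gex_post_mM")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData is missing: %s", paste(miss, collapse = ", ")))
  syn <- S4Vectors::metadata(object)$synthetic
  if (!is.logical(syn) || length(syn) != 1L)
    return("metadata()$synthetic must be a logical flag")
  if (syn) {
    need <- c("thetaBar", "covariance", "theta", "eta", "design", "seed")
    miss <- setdiff(need, names(S4Vectors::metadata(object)))
    if (length(miss))
      return(sprintf("synthetic TraceSet metadata is missing: %s",
                     paste(miss, collapse = ", ")))
  }
  TRUE
})

#' FitProblem: a least-squares estimation problem on trace data
#'
#' Defines the data, the free parameter subset, box bounds, the number
#' of multiple-shooting intervals and per-point weights for fitting the
#' fixed-effect parameters to the (cell-aggregated) ratio trace.
#'
#' @slot data a \linkS4class{TraceSet}.
#' @slot fixed template \linkS4class{ModelParameters}; parameters not in
#'   \code{free} stay at these values.
#' @slot strain a \linkS4class{StrainConfig}.
#' @slot profile a \linkS4class{GlucoseProfile}.
#' @slot free character, non-empty subset of \code{parameterNames()}.
#' @slot lower,upper named positive bounds for the free parameters.
#' @slot nIntervals integer(1), number of shooting intervals (1 =
#'   single shooting).
#' @slot weights numeric, one weight per time point.
#' @slot logResiduals logical(1), residuals on log-ratio scale.
#' @export
setClass("FitProblem",
         representation(data = "TraceSet", fixed = "ModelParameters",
                        strain = "StrainConfig", profile = "GlucoseProfile",
                        free = "character", lower = "numeric",
                        upper = "numeric", nIntervals = "integer",
                        weights = "numeric", logResiduals = "logical"))

setValidity("FitProblem", function(object) {
  if (!length(object@free))
    return("the free parameter set must be non-empty")
  bad <- setdiff(object@free, .PARAM_NAMES)
  if (length(bad))
    return(sprintf("unknown free parameters: %s", paste(bad, collapse = ", ")))
  if (!identical(names(object@lower), object@free) ||
      !identical(names(object@upper), object@free))
    return("lower/upper must be named after the free parameters")
  if (any(object@lower <= 0) || any(object@upper <= object@lower))
    return("bounds must satisfy 0 < lower < upper")
  if (object@nIntervals < 1L)
    return("nIntervals must be >= 1")
  nt <- nrow(object@data)
  if (length(object@weights) != nt)
    return("weights must have one entry per time point")
  TRUE
})

#' FitResult: outcome of a fixed-effect fit
#'
#' @slot thetaHat estimated \linkS4class{ModelParameters} (free
#'   parameters at their optimum, others at the template values).
#' @slot free character, the fitted subset.
#' @slot objective numeric(1), weighted residual sum of squares of the
#'   data residuals at the optimum.
#' @slot defects numeric, absolute continuity defects at each shooting
#'   junction (empty for single shooting).
#' @slot relDefects numeric, the same defects relative to state scale.
#' @slot converged logical(1).
#' @slot nEvals integer(1), number of residual evaluations.
#' @slot message character(1), optimizer termination message.
#' @export
setClass("FitResult",
         representation(thetaHat = "ModelParameters", free = "character",
                        objective = "numeric", defects = "numeric",
                        relDefects = "numeric", converged = "logical",
                        nEvals = "integer", message = "character"))

setValidity("FitResult", function(object) {
  if (length(object@objective) != 1L || object@objective < 0)
    return("objective must be a non-negative scalar")
  TRUE
})
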