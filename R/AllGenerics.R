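#' @include AllClasses.R
NULL

#' Accessors for pathway-model objects
#'
#' \code{parameterVector} returns the named 18-vector of a
#' \linkS4class{ModelParameters} or the fixed effects of an
#' \linkS4class{IndividualDraws}; \code{transporterFlags} the named
#' 0/1 indicator vector of a \linkS4class{StrainConfig};
#' \code{strainLabel} the strain name; \code{maskedParameters} the
#' uptake parameters inactivated by the strain background.
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("parameterVector", function(object) standardGeneric("parameterVector"))

#' @rdname accessors
#' @export
setGeneric("transporterFlags", function(object) standardGeneric("transporterFlags"))

#' @rdname accessors
#' @export
setGeneric("strainLabel", function(object) standardGeneric("strainLabel"))

#' @rdname accessors
#' @export
setGeneric("maskedParameters", function(object) standardGeneric("maskedParameters"))

#' Accessors for trace containers
#'
#' \code{traceTimes} returns the shared time grid in minutes;
#' \code{ratios} the observed ratio matrix (time points x cells);
#' \code{trueRatios} the noise-free ratio matrix of a synthetic set (or
#' NULL); \code{cellSizes} the per-cell sizes; \code{nCells} the number
#' of cells; \code{isSynthetic} whether ground truth is attached;
#' \code{thetaMatrix}/\code{etaMatrix} the per-cell true parameters and
#' random effects (18 x n).
#'
#' @param object a \linkS4class{TraceSet}, \linkS4class{Trajectory} or
#'   \linkS4class{IndividualDraws}.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname trace-accessors
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @rdname trace-accessors
#' @export
setGeneric("trueRatios", function(object) standardGeneric("trueRatios"))

#' @rdname trace-accessors
#' @export
setGeneric("cellSizes", function(object) standardGeneric("cellSizes"))

#' @rdname trace-accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname trace-accessors
#' @export
setGeneric("isSynthetic", function(object) standardGeneric("isSynthetic"))

#' @rdname trace-accessors
#' @export
setGeneric("thetaMatrix", function(object) standardGeneric("thetaMatrix"))

#' @rdname trace-accessors
#' @export
setGeneric("etaMatrix", function(object) standardGeneric("etaMatrix"))
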