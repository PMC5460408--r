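#' @include parameters.R
NULL

#' Construct a TraceSet
#'
#' Low-level constructor; most users obtain trace sets from
#' \code{\link{simulatePopulation}}, \code{\link{generateExperiment}} or
#' \code{\link{readTraces}}.
#'
#' @param ratio time-points x cells matrix of observed ratios.
#' @param time shared time grid, minutes (upshift at 0).
#' @param cellId character cell identifiers.
#' @param size per-cell sizes, arbitrary units.
#' @param strain a \linkS4class{StrainConfig} (shared by all cells).
#' @param profile a \linkS4class{GlucoseProfile}.
#' @param trueRatio optional noise-free ratio matrix (synthetic sets).
#' @param theta,eta optional 18 x cells ground-truth matrices.
#' @param thetaBar,covariance optional generative fixed effects
#'   (\linkS4class{ModelParameters}) and 18 x 18 covariance.
#' @param design optional \linkS4class{ExperimentDesign}.
#' @param seed optional master seed.
#' @param synthetic logical; TRUE when ground truth is attached.
#' @return A \linkS4class{TraceSet}.
#' @export
TraceSet <- function(ratio, time, cellId, size, strain, profile,
                     trueRatio = NULL, theta = NULL, eta = NULL,
                     thetaBar = NULL, covariance = NULL, design = NULL,
                     seed = NULL, synthetic = !is.null(theta)) {
  ratio <- as.matrix(ratio)
  dimnames(ratio) <- list(NULL, cellId)
  assays <- list(ratio = ratio)
  if (!is.null(trueRatio)) {
    trueRatio <- as.matrix(trueRatio)
    dimnames(trueRatio) <- list(NULL, cellId)
    assays$trueRatio <- trueRatio
  }
  cd <- S4Vectors::DataFrame(cell_id = cellId, size_au = size,
                             strain = strainLabel(strain),
                             gex_pre_mM = profile@preLevel,
                             gex_post_mM = profile@postLevel,
                             row.names = cellId)
  md <- list(synthetic = isTRUE(synthetic), strainConfig = strain,
             profile = profile)
  if (isTRUE(synthetic))
    md <- c(md, list(thetaBar = thetaBar, covariance = covariance,
                     theta = theta, eta = eta, design = design,
                     seed = seed))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(time_min = as.numeric(time)),
    colData = cd)
  S4Vectors::metadata(se) <- md
  new("TraceSet", se)
}

#' @rdname trace-accessors
#' @export
setMethod("traceTimes", "TraceSet", function(object)
  SummarizedExperiment::rowData(object)$time_min)

#' @rdname trace-accessors
#' @export
setMethod("ratios", "TraceSet", function(object)
  SummarizedExperiment::assay(object, "ratio"))

#' @rdname trace-accessors
#' @export
setMethod("trueRatios", "TraceSet", function(object) {
  if ("trueRatio" %in% SummarizedExperiment::assayNames(object))
    SummarizedExperiment::assay(object, "trueRatio")
  else NULL
})

#' @rdname trace-accessors
#' @export
setMethod("cellSizes", "TraceSet", function(object) {
  s <- SummarizedExperiment::colData(object)$size_au
  names(s) <- colnames(object)
  s
})

#' @rdname trace-accessors
#' @export
setMethod("nCells", "TraceSet", function(object) ncol(object))

#' @rdname trace-accessors
#' @export
setMethod("isSynthetic", "TraceSet", function(object)
  isTRUE(S4Vectors::metadata(object)$synthetic))

#' @rdname trace-accessors
#' @export
setMethod("thetaMatrix", "TraceSet", function(object)
  S4Vectors::metadata(object)$theta)

#' @rdname trace-accessors
#' @export
setMethod("etaMatrix", "TraceSet", function(object)
  S4Vectors::metadata(object)$eta)

#' @rdname accessors
#' @export
setMethod("strainLabel", "TraceSet", function(object)
  unique(SummarizedExperiment::colData(object)$strain))

setMethod("show", "TraceSet", function(object) {
  tm <- traceTimes(object)
  cat(sprintf("TraceSet: %d cells x %d time points [%g, %g] min\n",
              ncol(object), nrow(object), min(tm), max(tm)))
  cat(sprintf("  strain %s, glucose %g -> %g mM, %s\n",
              paste(strainLabel(object), collapse = "/"),
              SummarizedExperiment::colData(object)$gex_pre_mM[1L],
              SummarizedExperiment::colData(object)$gex_post_mM[1L],
              if (isSynthetic(object)) "synthetic (ground truth attached)"
              else "observational"))
})

#' Coerce a TraceSet to a tidy data.frame
#'
#' One row per (cell, time point), the layout used by the CSV
#' interchange format.
#'
#' @param x a \linkS4class{TraceSet}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns \code{cell_id}, \code{time_min},
#'   \code{ratio}, \code{size_au}, \code{strain}, \code{gex_mM}.
#' @export
as.data.frame.TraceSet <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  tidyTraces(x)
}

#' Tidy view of a TraceSet
#'
#' @param x a \linkS4class{TraceSet}.
#' @return data.frame with columns \code{cell_id}, \code{time_min},
#'   \code{ratio}, \code{size_au}, \code{strain}, \code{gex_mM}.
#' @export
tidyTraces <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  tm <- traceTimes(x)
  r <- ratios(x)
  data.frame(cell_id = rep(cd$cell_id, each = length(tm)),
             time_min = rep(tm, times = ncol(x)),
             ratio = as.vector(r),
             size_au = rep(cd$size_au, each = length(tm)),
             strain = rep(cd$strain, each = length(tm)),
             gex_mM = rep(cd$gex_post_mM, each = length(tm)))
}

setMethod("as.data.frame", "TraceSet", function(x, ...) tidyTraces(x))
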