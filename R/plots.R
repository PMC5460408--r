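#' @include trace-analysis.R
NULL

#' Plot single-cell ratio traces
#'
#' One grey line per cell with the population mean overlaid, ratio on
#' a log scale — the standard display for Mig1 localization time
#' courses.  Numbers, not figures, are the package's contract; this is
#' a convenience.
#'
#' @param traces a \linkS4class{TraceSet}.
#' @return A ggplot object.
#' @export
plotTraces <- function(traces) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotTraces requires the ggplot2 package")
  df <- as.data.frame(traces)
  mt <- data.frame(time_min = traceTimes(traces),
                   ratio = rowMeans(ratios(traces)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$ratio)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cell_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = mt, colour = "black", linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after upshift (min)",
                  y = "nuclear/cytosolic Mig1 ratio")
}

#' Plot cell size against final response
#'
#' Scatter of cell size versus the final post-upshift ratio with a
#' least-squares line, the display behind the size-association test.
#'
#' @inheritParams plotTraces
#' @param finalAt minutes after the shift (default 15).
#' @return A ggplot object.
#' @export
plotSizeResponse <- function(traces, finalAt = 15) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSizeResponse requires the ggplot2 package")
  tm <- traceTimes(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  if (is.null(shift)) shift <- 0
  finalIdx <- max(which(tm >= shift & tm <= shift + finalAt))
  df <- data.frame(size_au = cellSizes(traces),
                   final = ratios(traces)[finalIdx, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_au, y = .data$final)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "cell size (a.u.)",
                  y = sprintf("ratio %g min after upshift", finalAt))
}
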