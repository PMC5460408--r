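#' @include TraceSet.R
NULL

## Per-cell baseline: mean observed ratio over the pre-shift samples.
.baselines <- function(traces) {
  tm <- traceTimes(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  if (is.null(shift)) shift <- 0
  pre <- tm < shift
  if (!any(pre))
    stop("traces contain no pre-shift samples; cannot estimate baselines")
  colMeans(ratios(traces)[pre, , drop = FALSE])
}

## First run of >= debounce consecutive above-threshold post-shift
## samples; returns the index (into postIdx) of its first sample, or NA.
.firstSustained <- function(above, debounce) {
  if (debounce <= 1L) return(if (any(above)) which(above)[1L] else NA_integer_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= debounce)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Summarize single-cell ratio traces
#'
#' Per cell: baseline (mean ratio over pre-shift samples), peak and
#' final post-shift ratio, responder flag and response time.  A cell
#' responds when its ratio exceeds \code{baseline x thresholdFactor}
#' for at least \code{debounce} consecutive post-shift samples (the
#' debounce guards against isolated noise spikes); the response time is
#' the time of the first sample of the first such run.  The final
#' ratio is read at the last grid point at or before 15 min after the
#' shift.  Per experiment: the responder fraction, mean trace and
#' coefficient of variation over time.
#'
#' @param traces a \linkS4class{TraceSet} with at least one pre-shift
#'   sample.
#' @param thresholdFactor baseline multiplier defining "nuclear
#'   localized" (default 1.5).
#' @param debounce consecutive samples required (default 2).
#' @param finalAt minutes after the shift at which the final ratio is
#'   read (default 15).
#' @return A list of class \code{TraceSummary}: \code{perCell}
#'   (data.frame with \code{cell_id}, \code{baseline}, \code{peak},
#'   \code{final}, \code{responder}, \code{response_time_min},
#'   \code{size_au}), \code{responderFraction}, \code{fractionCurve}
#'   (from \code{\link{responderFractionCurve}}), \code{meanTrace},
#'   \code{cv} (when >= 2 cells) and \code{nCells}.
#' @export
summarizeTraces <- function(traces, thresholdFactor = 1.5, debounce = 2L,
                            finalAt = 15) {
  stopifnot(is(traces, "TraceSet"))
  tm <- traceTimes(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  if (is.null(shift)) shift <- 0
  base <- .baselines(traces)
  r <- ratios(traces)
  postIdx <- which(tm >= shift)
  finalIdx <- postIdx[which(tm[postIdx] <= shift + finalAt)]
  finalIdx <- finalIdx[length(finalIdx)]

  n <- ncol(r)
  responder <- logical(n)
  rtime <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    above <- r[postIdx, j] > base[j] * thresholdFactor
    k <- .firstSustained(above, debounce)
    responder[j] <- !is.na(k)
    if (responder[j]) rtime[j] <- tm[postIdx[k]]
  }
  perCell <- data.frame(
    cell_id = colnames(r),
    baseline = unname(base),
    peak = apply(r[postIdx, , drop = FALSE], 2L, max),
    final = r[finalIdx, ],
    responder = responder,
    response_time_min = rtime,
    size_au = unname(cellSizes(traces)),
    row.names = NULL)

  out <- list(perCell = perCell,
              responderFraction = mean(responder),
              fractionCurve = responderFractionCurve(traces,
                                                     thresholdFactor),
              meanTrace = data.frame(time_min = tm,
                                     mean_ratio = rowMeans(r)),
              cv = if (n >= 2L) cvOverTime(traces) else NULL,
              nCells = n,
              thresholdFactor = thresholdFactor,
              debounce = as.integer(debounce))
  class(out) <- "TraceSummary"
  out
}

#' @export
print.TraceSummary <- function(x, ...) {
  cat(sprintf(paste0("TraceSummary: %d cells, responder fraction %.2f ",
                     "(threshold %gx baseline, debounce %d)\n"),
              x$nCells, x$responderFraction, x$thresholdFactor,
              x$debounce))
  rt <- x$perCell$response_time_min
  if (any(!is.na(rt)))
    cat(sprintf("  median response time %.2g min; median final ratio %.3g\n",
                stats::median(rt, na.rm = TRUE),
                stats::median(x$perCell$final)))
  invisible(x)
}

#' Responder fraction over time
#'
#' The fraction of cells whose ratio exceeds their own baseline times
#' \code{thresholdFactor} at each time point, and the first time at
#' which this fraction reaches its maximum.
#'
#' @inheritParams summarizeTraces
#' @return data.frame with \code{time_min} and \code{fraction}
#'   (in [0, 1]); the attribute \code{timeToMax} holds the first time
#'   (minutes after the shift) at which the maximum is attained.
#' @export
responderFractionCurve <- function(traces, thresholdFactor = 1.5) {
  stopifnot(is(traces, "TraceSet"))
  tm <- traceTimes(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  if (is.null(shift)) shift <- 0
  base <- .baselines(traces)
  above <- sweep(ratios(traces), 2L, base * thresholdFactor, ">")
  frac <- rowMeans(above)
  out <- data.frame(time_min = tm, fraction = frac)
  post <- tm >= shift
  iMax <- which(post)[which.max(frac[post])]
  attr(out, "timeToMax") <- tm[iMax] - shift
  out
}

#' Coefficient of variation of the ratio over time
#'
#' Sample (n-1) standard deviation divided by the mean of the observed
#' ratio across cells, at each time point.
#'
#' @param traces a \linkS4class{TraceSet} with at least 2 cells.
#' @return data.frame with \code{time_min}, \code{cv}, \code{mean} and
#'   \code{n}.
#' @export
cvOverTime <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  r <- ratios(traces)
  if (ncol(r) < 2L)
    stop("cvOverTime requires at least 2 cells")
  m <- rowMeans(r)
  s <- apply(r, 1L, stats::sd)
  data.frame(time_min = traceTimes(traces), cv = s / m, mean = m,
             n = ncol(r))
}

#' Association between cell size and final response
#'
#' Pearson correlation (with 95\% confidence interval) between cell
#' size and the final post-upshift ratio, the test used to ask whether
#' pathway activity scales with cell size.
#'
#' @inheritParams summarizeTraces
#' @return list with \code{estimate}, \code{conf.int}, \code{p.value},
#'   \code{n} and \code{nullConsistent} (TRUE when the interval
#'   contains 0).
#' @export
sizeResponseAssociation <- function(traces, finalAt = 15) {
  stopifnot(is(traces, "TraceSet"))
  if (ncol(traces) < 3L)
    stop("sizeResponseAssociation requires at least 3 cells")
  size <- cellSizes(traces)
  if (stats::sd(size) == 0)
    stop("cell sizes are constant; correlation is undefined")
  tm <- traceTimes(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  if (is.null(shift)) shift <- 0
  finalIdx <- max(which(tm >= shift & tm <= shift + finalAt))
  final <- ratios(traces)[finalIdx, ]
  ct <- stats::cor.test(size, final, method = "pearson")
  list(estimate = unname(ct$estimate),
       conf.int = as.numeric(ct$conf.int),
       p.value = ct$p.value,
       n = ncol(traces),
       nullConsistent = ct$conf.int[1L] <= 0 && ct$conf.int[2L] >= 0)
}
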