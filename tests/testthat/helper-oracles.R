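# Independent oracles used across the suite.

# Fixed-step classical RK4 integration of the pathway model, piecewise
# around the glucose step.  Independent of the adaptive solver path.
rk4Simulate <- function(params, strain, profile,
                        timeGrid = seq(0, 15, by = 0.5), h = 1e-3,
                        y0 = NULL) {
  th <- parameterVector(params)
  hxt <- unname(transporterFlags(strain))
  f <- function(y, gex) MigFlux:::.deriv(y, gex, th, hxt)
  if (is.null(y0))
    y0 <- initialState(params, strain, gex0 = profile@preLevel)
  stepTo <- function(y, t1, t2, gex) {
    if (t2 <= t1) return(y)
    nsub <- max(1L, ceiling((t2 - t1) / h))
    hh <- (t2 - t1) / nsub
    for (i in seq_len(nsub)) {
      k1 <- f(y, gex)
      k2 <- f(y + hh / 2 * k1, gex)
      k3 <- f(y + hh / 2 * k2, gex)
      k4 <- f(y + hh * k3, gex)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  ts <- profile@shiftTime
  out <- matrix(NA_real_, length(timeGrid), 8L,
                dimnames = list(NULL, speciesNames()))
  y <- y0
  tPrev <- timeGrid[1L]
  out[1L, ] <- y
  for (i in seq_along(timeGrid)[-1L]) {
    t2 <- timeGrid[i]
    if (t2 <= ts) {                      # fully before the step
      y <- stepTo(y, tPrev, t2, profile@preLevel)
    } else if (tPrev >= ts) {            # fully after the step
      y <- stepTo(y, tPrev, t2, profile@postLevel)
    } else {                             # straddles the step
      y <- stepTo(y, tPrev, ts, profile@preLevel)
      y <- stepTo(y, ts, t2, profile@postLevel)
    }
    out[i, ] <- y
    tPrev <- t2
  }
  out
}

maxRelDiff <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# Plain-loop re-implementation of the trace statistics, kept naive on
# purpose (operates on the tidy data.frame, not the assay matrix).
flatSummary <- function(traces, factor = 1.5, debounce = 2L) {
  df <- as.data.frame(traces)
  shift <- S4Vectors::metadata(traces)$profile@shiftTime
  cells <- unique(df$cell_id)
  res <- data.frame(cell_id = cells, baseline = NA_real_,
                    responder = NA, response_time_min = NA_real_,
                    final = NA_real_)
  for (ci in seq_along(cells)) {
    d <- df[df$cell_id == cells[ci], ]
    d <- d[order(d$time_min), ]
    base <- mean(d$ratio[d$time_min < shift])
    post <- d[d$time_min >= shift, ]
    above <- post$ratio > base * factor
    resp <- FALSE; rt <- NA_real_
    run <- 0L
    for (k in seq_along(above)) {
      run <- if (above[k]) run + 1L else 0L
      if (run >= debounce) {
        resp <- TRUE
        rt <- post$time_min[k - debounce + 1L]
        break
      }
    }
    fin <- post$ratio[max(which(post$time_min <= shift + 15))]
    res[ci, c("baseline", "final")] <- c(base, fin)
    res$responder[ci] <- resp
    res$response_time_min[ci] <- rt
  }
  res
}

# Small helper: deterministic single-cell TraceSet wrapping one
# simulated trajectory (with pre-shift baseline samples).
deterministicTraceSet <- function(params = defaultParameters(),
                                  strain = strainConfig("WT"),
                                  postLevel = 220,
                                  grid = seq(-2, 15, by = 0.5),
                                  nCells = 1L) {
  profile <- glucoseProfile(postLevel)
  tr <- simulateCell(params, strain, profile, grid)
  ratio <- matrix(rep(tr@ratio, nCells), ncol = nCells)
  TraceSet(ratio = ratio, time = grid,
           cellId = sprintf("cell_%03d", seq_len(nCells)),
           size = rep(30, nCells), strain = strain, profile = profile,
           trueRatio = ratio,
           theta = matrix(rep(parameterVector(params), nCells), 18L,
                          dimnames = list(parameterNames(), NULL)),
           eta = matrix(0, 18L, nCells,
                        dimnames = list(parameterNames(), NULL)),
           thetaBar = params, covariance = diagonalCovariance(0),
           seed = 0L, synthetic = TRUE)
}
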