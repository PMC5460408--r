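#' @include parameters.R
NULL

## Internal validation shared by the rate/derivative entry points.
.checkStateArgs <- function(state, gex, params) {
  th <- if (is(params, "ModelParameters")) params@theta else params
  if (length(state) != 8L)
    stop("state must contain exactly 8 species")
  if (is.null(names(state))) names(state) <- .SPECIES_NAMES
  bad <- names(state)[!is.finite(state) | state < 0]
  if (length(bad))
    stop("state components must be finite and non-negative: ",
         paste(bad, collapse = ", "))
  if (!is.finite(gex) || gex < 0)
    stop("gex must be finite and non-negative")
  bad <- names(th)[!is.finite(th) | th <= 0]
  if (length(bad))
    stop("parameters must be finite and strictly positive: ",
         paste(bad, collapse = ", "))
  state[.SPECIES_NAMES]
}

## Unchecked kinetics ledger: the single place the 12 rate laws are
## defined.  state and th are numeric vectors in canonical order, hxt
## the three 0/1 indicators.  Swapping alternative kinetics means
## replacing this function only; the balance equations never change.
.rates <- function(state, gex, th, hxt) {
  state <- unname(state); th <- unname(th); hxt <- unname(hxt)
  gin <- state[1L]; csnf1 <- state[2L]; csnf1p <- state[3L]
  nsnf1p <- state[4L]; cmig1p <- state[5L]; cmig1 <- state[6L]
  nmig1 <- state[7L]; nmig1p <- state[8L]
  c(r1i = hxt[1L] * th[1L] * gex / (th[2L] + gex),
    r4i = hxt[2L] * th[3L] * gex / (th[4L] + gex),
    r7i = hxt[3L] * th[5L] * gex / (th[6L] + gex),
    r4  = th[7L] * gin,
    r5  = th[8L] * (gin / (th[9L] + gin)) * csnf1p,
    r6  = th[10L] * csnf1,
    r7a = th[11L] * csnf1p,
    r7b = th[12L] * nsnf1p,
    r1  = th[14L] * nmig1p / (th[15L] + nmig1p),
    r2  = th[18L] * cmig1p,
    r3  = th[16L] * cmig1 / (th[17L] + cmig1),
    r8  = th[13L] * nsnf1p * nmig1)
}

## Balance equations: assembles the 8 species derivatives from the 12
## rates.  The Mig1 cycle (r1, r2, r3, r8) and the Snf1 block (r5, r6,
## r7a, r7b) telescope, so both totals are conserved exactly.
.deriv <- function(state, gex, th, hxt) {
  r <- unname(.rates(state, gex, th, hxt))
  c(gin    = (r[1L] + r[2L] + r[3L]) - r[4L],
    csnf1  = r[5L] - r[6L],
    csnf1p = r[6L] - r[5L] - (r[7L] - r[8L]),
    nsnf1p = r[7L] - r[8L],
    cmig1p = r[9L] - r[10L],
    cmig1  = r[10L] - r[11L],
    nmig1  = r[11L] - r[12L],
    nmig1p = r[12L] - r[9L])
}

#' Reaction rates of the pathway model
#'
#' Evaluates the 12 reaction rates at a state: the three
#' Michaelis-Menten uptake fluxes (\code{r1i}, \code{r4i}, \code{r7i},
#' each switched by its strain indicator), intracellular glucose
#' consumption (\code{r4}), glucose-driven Snf1p dephosphorylation
#' (\code{r5}), Snf1 phosphorylation (\code{r6}), nuclear Snf1p
#' shuttling (\code{r7a}, \code{r7b}), and the irreversible Mig1 cycle:
#' nuclear export of phosphorylated Mig1 (\code{r1}), cytosolic
#' dephosphorylation (\code{r2}), nuclear import (\code{r3}) and
#' Snf1p-dependent nuclear phosphorylation (\code{r8}).
#'
#' @param state named numeric(8) of species (see \code{speciesNames()}),
#'   non-negative.
#' @param gex extracellular glucose, mM.
#' @param params a \linkS4class{ModelParameters}.
#' @param strain a \linkS4class{StrainConfig}.
#' @return Named numeric(12) of non-negative rates, in
#'   \code{reactionNames()} order.
#' @examples
#' st <- initialState(defaultParameters(), strainConfig("WT"))
#' reactionRates(st, 220, defaultParameters(), strainConfig("WT"))
#' @export
reactionRates <- function(state, gex, params, strain) {
  state <- .checkStateArgs(state, gex, params)
  .rates(state, gex, params@theta, transporterFlags(strain))
}

#' Time derivative of the pathway state
#'
#' Assembles the 8 species derivatives from the reaction rates:
#' \code{dGin/dt = hxt1a*r1i + hxt4a*r4i + hxt7a*r7i - r4}, the Snf1
#' block \code{dcSnf1/dt = r5 - r6}, \code{dcSnf1p/dt = r6 - r5 - (r7a
#' - r7b)}, \code{dnSnf1p/dt = r7a - r7b}, and the Mig1 cycle
#' \code{dcMig1p/dt = r1 - r2}, \code{dcMig1/dt = r2 - r3},
#' \code{dnMig1/dt = r3 - r8}, \code{dnMig1p/dt = r8 - r1}.
#' Evaluation is side-effect free; extracellular glucose is read from
#' the profile at time \code{t}.
#'
#' @param state named numeric(8), non-negative.
#' @param t time in minutes.
#' @param params a \linkS4class{ModelParameters}.
#' @param strain a \linkS4class{StrainConfig}.
#' @param profile a \linkS4class{GlucoseProfile}.
#' @return Named numeric(8) of derivatives in \code{speciesNames()}
#'   order.
#' @export
pathwayDerivatives <- function(state, t, params, strain, profile) {
  gex <- glucoseAt(profile, t)
  state <- .checkStateArgs(state, gex, params)
  .deriv(state, gex, params@theta, transporterFlags(strain))
}

#' Nuclear/cytosolic Mig1 ratio
#'
#' The single-cell observable: total nuclear Mig1 divided by total
#' cytosolic Mig1, \code{(nmig1 + nmig1p + eps) / (cmig1 + cmig1p +
#' eps)}.  The floor \code{eps} keeps the ratio finite when a pool is
#' empty.
#'
#' @param state named numeric(8) or a states matrix with one row per
#'   time point (columns in \code{speciesNames()} order).
#' @param eps non-negative floor (default 1e-9).
#' @return The dimensionless ratio (scalar or vector).
#' @examples
#' mig1Ratio(c(gin = 0, csnf1 = 0, csnf1p = 0.5, nsnf1p = 0.5,
#'             cmig1p = 0.2, cmig1 = 0.2, nmig1 = 0.3, nmig1p = 0.3))
#' @export
mig1Ratio <- function(state, eps = 1e-9) {
  if (is.matrix(state)) {
    (state[, "nmig1"] + state[, "nmig1p"] + eps) /
      (state[, "cmig1"] + state[, "cmig1p"] + eps)
  } else {
    state <- state[.SPECIES_NAMES]
    unname((state[7L] + state[8L] + eps) / (state[6L] + state[5L] + eps))
  }
}

## deSolve-facing RHS; parms carries th/hxt/gex for one constant-input
## segment so the step never passes through the adaptive integrator.
.odeFunc <- function(t, y, parms) {
  list(.deriv(y, parms$gex, parms$th, parms$hxt))
}

## Integrate one constant-glucose segment, returning states at `times`.
.integrateSegment <- function(y0, times, th, hxt, gex, rtol, atol) {
  if (length(times) == 1L)
    return(matrix(y0, nrow = 1L, dimnames = list(NULL, .SPECIES_NAMES)))
  out <- deSolve::lsoda(y = y0, times = times, func = .odeFunc,
                        parms = list(th = th, hxt = hxt, gex = gex),
                        rtol = rtol, atol = atol)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1L] < 0)
    stop("stiff-solver failure (lsoda istate = ", diag[1L],
         ") integrating over [", min(times), ", ", max(times), "] min")
  m <- unname(out[, -1L, drop = FALSE])
  colnames(m) <- .SPECIES_NAMES
  m
}

#' Pre-shift initial state by relaxation
#'
#' Returns the relaxed state of a cell grown without glucose (the
#' pre-upshift condition): the system is integrated at \code{gex} =
#' \code{gex0} for \code{relaxTime} minutes from a canonical start (all
#' Mig1 cytosolic and unphosphorylated, all Snf1 cytosolic and
#' unphosphorylated, no intracellular glucose) and the residual
#' derivative norm at the end point is required to fall below
#' \code{tol}.
#'
#' @param params a \linkS4class{ModelParameters}.
#' @param strain a \linkS4class{StrainConfig}.
#' @param gex0 pre-shift extracellular glucose, mM (default 0).
#' @param relaxTime relaxation horizon in minutes (default 100).
#' @param tol tolerance on the Euclidean norm of the derivative at the
#'   returned state (default 1e-8).
#' @param totalMig1,totalSnf1 conserved totals (default 1, the
#'   normalized units of the model).
#' @return Named numeric(8) steady pre-shift state.
#' @export
initialState <- function(params, strain, gex0 = 0, relaxTime = 100,
                         tol = 1e-8, totalMig1 = 1, totalSnf1 = 1) {
  stopifnot(is(params, "ModelParameters"), is(strain, "StrainConfig"))
  y0 <- c(gin = 0, csnf1 = totalSnf1, csnf1p = 0, nsnf1p = 0,
          cmig1p = 0, cmig1 = totalMig1, nmig1 = 0, nmig1p = 0)
  hxt <- transporterFlags(strain)
  m <- .integrateSegment(y0, c(0, relaxTime), params@theta, hxt, gex0,
                         rtol = 1e-10, atol = 1e-12)
  y <- m[nrow(m), ]
  y[y < 0] <- 0
  res <- sqrt(sum(.deriv(y, gex0, params@theta, hxt)^2))
  if (res > tol)
    stop(sprintf(paste0("initial state failed to relax: residual RHS ",
                        "norm %.3e exceeds tol %.3e after %g min"),
                 res, tol, relaxTime))
  y
}

#' Simulate a single cell through a glucose upshift
#'
#' Integrates the pathway model over \code{timeGrid} with a
#' stiff-capable adaptive solver (lsoda, rtol 1e-8, atol 1e-10),
#' stopping and restarting at the glucose step so the discontinuous
#' input is handled exactly.  The initial state is the relaxed
#' pre-shift state at the profile's pre-level (see
#' \code{\link{initialState}}), unless \code{y0} is supplied.  Both
#' conservation invariants (total Mig1 and total Snf1) are checked to
#' \code{conservationTol} relative.
#'
#' @param params a \linkS4class{ModelParameters}.
#' @param strain a \linkS4class{StrainConfig}.
#' @param profile a \linkS4class{GlucoseProfile}.
#' @param timeGrid strictly increasing times in minutes (default 0 to
#'   15 by 0.5); the shift must lie within the grid span for an upshift
#'   to be observed.
#' @param y0 optional starting state at \code{timeGrid[1]}.
#' @param rtol,atol solver tolerances.
#' @param conservationTol relative tolerance for the conservation check
#'   (default 1e-6).
#' @param eps observable floor passed to \code{\link{mig1Ratio}}.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' tr <- simulateCell(defaultParameters(), strainConfig("HXT1"),
#'                    glucoseProfile(220))
#' tr
#' @export
simulateCell <- function(params, strain, profile,
                         timeGrid = seq(0, 15, by = 0.5), y0 = NULL,
                         rtol = 1e-8, atol = 1e-10,
                         conservationTol = 1e-6, eps = 1e-9) {
  stopifnot(is(params, "ModelParameters"), is(strain, "StrainConfig"),
            is(profile, "GlucoseProfile"))
  if (any(diff(timeGrid) <= 0))
    stop("timeGrid must be strictly increasing")
  th <- params@theta
  hxt <- transporterFlags(strain)
  if (is.null(y0))
    y0 <- initialState(params, strain, gex0 = profile@preLevel)
  y0 <- .checkStateArgs(y0, profile@preLevel, params)

  ts <- profile@shiftTime
  pre <- timeGrid[timeGrid < ts]
  post <- timeGrid[timeGrid >= ts]
  states <- matrix(numeric(0), ncol = 8L,
                   dimnames = list(NULL, .SPECIES_NAMES))
  y <- y0
  if (length(pre)) {
    m <- .integrateSegment(y, pre, th, hxt, profile@preLevel, rtol, atol)
    states <- rbind(states, m)
    y <- m[nrow(m), ]
    if (length(post) && pre[length(pre)] < ts) {
      ## carry the state up to the discontinuity before restarting
      m2 <- .integrateSegment(y, c(pre[length(pre)], ts), th, hxt,
                              profile@preLevel, rtol, atol)
      y <- m2[nrow(m2), ]
    }
  }
  if (length(post)) {
    tsEff <- max(ts, timeGrid[1L])  # state is only defined from grid start
    m <- .integrateSegment(y, unique(c(tsEff, post)), th, hxt,
                           profile@postLevel, rtol, atol)
    if (post[1L] > tsEff) m <- m[-1L, , drop = FALSE]
    states <- rbind(states, m)
  }

  ## integrator round-off can leave tiny negative excursions
  states[states < 0 & states > -1e-9] <- 0

  migTot <- rowSums(states[, c("cmig1", "cmig1p", "nmig1", "nmig1p"),
                           drop = FALSE])
  snfTot <- rowSums(states[, c("csnf1", "csnf1p", "nsnf1p"), drop = FALSE])
  relErr <- function(x) diff(range(x)) / max(mean(x), .Machine$double.eps)
  if (relErr(migTot) > conservationTol || relErr(snfTot) > conservationTol)
    stop(sprintf(paste0("conservation violated: Mig1 rel. drift %.2e, ",
                        "Snf1 rel. drift %.2e (tol %.0e)"),
                 relErr(migTot), relErr(snfTot), conservationTol))

  new("Trajectory", time = as.numeric(timeGrid), states = states,
      ratio = unname(mig1Ratio(states, eps = eps)))
}

#' @rdname trace-accessors
#' @export
setMethod("traceTimes", "Trajectory", function(object) object@time)

#' @rdname trace-accessors
#' @export
setMethod("ratios", "Trajectory", function(object) object@ratio)

#' Species matrix of a trajectory
#'
#' @param object a \linkS4class{Trajectory}.
#' @return Numeric matrix, time points x 8 species.
#' @export
trajectoryStates <- function(object) {
  stopifnot(is(object, "Trajectory"))
  object@states
}

setMethod("show", "Trajectory", function(object) {
  n <- length(object@time)
  cat(sprintf("Trajectory: %d time points over [%g, %g] min\n", n,
              object@time[1L], object@time[n]))
  cat(sprintf("  ratio: start %.3f, end %.3f\n", object@ratio[1L],
              object@ratio[n]))
})

#' Coerce a Trajectory to a tidy data.frame
#'
#' @param x a \linkS4class{Trajectory}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with \code{time_min}, the 8 species columns and
#'   \code{ratio}.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  data.frame(time_min = x@time, as.data.frame(x@states), ratio = x@ratio)
}

setMethod("as.data.frame", "Trajectory",
          function(x, ...) as.data.frame.Trajectory(x))
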