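freeSet <- c("vmsi", "vmd", "kex1", "kim1")
truth <- defaultParameters()

test_that("residuals are zero iff the simulation reproduces the data", {
  ts <- deterministicTraceSet()
  prob <- fitProblem(ts, free = freeSet)
  r <- traceResiduals(truth, prob)
  expect_lt(sqrt(sum(r^2)), 1e-6)

  # constant offset: norm is offset * sqrt(number of points)
  off <- ts
  SummarizedExperiment::assay(off, "ratio") <- ratios(ts) + 0.1
  probOff <- fitProblem(off, free = freeSet)
  rOff <- traceResiduals(truth, probOff)
  expect_equal(sqrt(sum(rOff^2)), 0.1 * sqrt(nrow(ts)), tolerance = 1e-9)

  # the free set may not be empty
  expect_error(fitProblem(ts, free = character(0)), "non-empty")
})

test_that("the true parameters are the global optimum on noise-free data", {
  ts <- deterministicTraceSet()
  prob <- fitProblem(ts, free = freeSet)
  objTruth <- sum(traceResiduals(truth, prob)^2)
  expect_lt(objTruth, 1e-16)
  start <- parameterVector(truth)
  start[freeSet] <- start[freeSet] * 1.5
  objStart <- sum(traceResiduals(modelParameters(start), prob)^2)
  expect_lt(objTruth, objStart)
})

test_that("multiple shooting agrees with single shooting on a continuous trajectory", {
  ts <- deterministicTraceSet()
  prob <- fitProblem(ts, free = freeSet, nIntervals = 5L)
  grid <- traceTimes(ts)
  nodeIdx <- MigFlux:::.nodeIndex(length(grid), 5L)
  tr <- simulateCell(truth, strainConfig("WT"), glucoseProfile(220), grid)
  nodes <- t(tr@states[nodeIdx[2:5], , drop = FALSE])
  x <- c(log(parameterVector(truth)[freeSet]), as.vector(nodes))
  res <- MigFlux:::.shootingResiduals(x, prob, nodeIdx, mu = 1)
  nGrid <- length(grid)
  single <- traceResiduals(truth, prob)
  # agreement is limited only by the integrator tolerance
  expect_lt(max(abs(res[seq_len(nGrid)] - single)), 1e-6)
  expect_lt(max(abs(res[-seq_len(nGrid)])), 1e-7)  # defects vanish
})

test_that("noise-free recovery from a 1.5x-perturbed start is within 5%", {
  ts <- deterministicTraceSet()
  prob <- fitProblem(ts, free = freeSet, nIntervals = 5L)
  start <- parameterVector(truth)
  start[freeSet] <- start[freeSet] * 1.5
  fit <- fitFixedEffects(prob, start = modelParameters(start))
  expect_true(fit@converged)
  rel <- abs(parameterVector(fit)[freeSet] /
               parameterVector(truth)[freeSet] - 1)
  expect_true(all(rel < 0.05))
  expect_lt(fit@objective, 1e-8)
  if (length(fit@relDefects)) expect_lt(max(fit@relDefects), 1e-6)
})

test_that("vmsi is recovered from noisy aggregates across replicates", {
  rel <- vapply(1:10, function(s) {
    des <- experimentDesign("WT", nCells = 15, noiseCv = 0.05, seed = s)
    ts <- generateExperiment(des, sigma = diagonalCovariance(0))
    prob <- fitProblem(ts, free = "vmsi", nIntervals = 1L)
    start <- parameterVector(truth)
    start["vmsi"] <- start["vmsi"] * 1.5
    fit <- fitFixedEffects(prob, start = modelParameters(start))
    abs(parameterVector(fit)[["vmsi"]] /
          parameterVector(truth)[["vmsi"]] - 1)
  }, numeric(1))
  expect_lt(median(rel), 0.15)
})

test_that("per-cell refits recover the generating dispersion of vmd", {
  sigma <- diagonalCovariance(0)
  sigma["vmd", "vmd"] <- 0.04
  des <- experimentDesign("WT", nCells = 30, noiseCv = 0, seed = 27)
  ts <- generateExperiment(des, sigma = sigma)
  fits <- lapply(seq_len(ncol(ts)), function(j) {
    prob <- fitProblem(ts[, j], free = "vmd", nIntervals = 1L)
    fitFixedEffects(prob, start = truth)
  })
  est <- estimateCovarianceDiagonal(fits, truth)
  expect_lt(abs(est["vmd", "vmd"] - 0.04), 0.5 * 0.04)
  expect_true(all(est[-which(parameterNames() == "vmd"),
                      -which(parameterNames() == "vmd")] == 0))
})

test_that("empirical covariance is scale invariant and needs 2 cells", {
  mk <- function(th) new("FitResult", thetaHat = modelParameters(th),
                         free = "vmd", objective = 0,
                         defects = numeric(0), relDefects = numeric(0),
                         converged = TRUE, nEvals = 1L, message = "")
  th <- parameterVector(truth)
  fits <- lapply(c(0.8, 1.0, 1.3), function(f)
    mk(replace(th, "vmd", th[["vmd"]] * f)))
  s1 <- estimateCovarianceDiagonal(fits, truth)
  # doubling every estimate and the reference leaves log-ratios alone
  fits2 <- lapply(c(0.8, 1.0, 1.3), function(f)
    mk(replace(th * 2, "vmd", th[["vmd"]] * 2 * f)))
  s2 <- estimateCovarianceDiagonal(fits2, modelParameters(th * 2))
  expect_equal(s2, s1, tolerance = 1e-12)
  # identical estimates give a zero matrix
  s0 <- estimateCovarianceDiagonal(list(mk(th), mk(th), mk(th)), truth)
  expect_true(all(s0 == 0))
  expect_error(estimateCovarianceDiagonal(list(mk(th)), truth),
               "at least 2")
})
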