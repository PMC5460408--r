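test_that("degenerate generator reproduces the deterministic trajectory", {
  des <- experimentDesign("HXT1", postLevel = 55, nCells = 3,
                          noiseCv = 0, seed = 1)
  ts <- generateExperiment(des, sigma = diagonalCovariance(0))
  det <- simulateCell(defaultParameters(), strainConfig("HXT1"),
                      glucoseProfile(55), designTimeGrid(des))@ratio
  expect_true(all(ratios(ts) == det))
  expect_identical(ratios(ts), trueRatios(ts))
})

test_that("the generator is byte-identical under a fixed seed", {
  des <- experimentDesign("WT", nCells = 4, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeTraces(generateExperiment(des), f1)
  writeTraces(generateExperiment(des), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(MigFlux:::.sidecarPath(f1)),
                   readLines(MigFlux:::.sidecarPath(f2)))
})

test_that("paper-range cell counts stay within 22..41", {
  counts <- vapply(1:100, function(s)
    MigFlux:::.resolveCellCount(experimentDesign(seed = s)), integer(1))
  expect_true(all(counts >= 22 & counts <= 41))
  expect_gt(length(unique(counts)), 5)  # actually varies
})

test_that("measurement noise has the designed multiplicative CV", {
  # 300 cells x 35 points > 1e4 cell-points; sigma = 0 isolates noise
  des <- experimentDesign("HXT1", postLevel = 55, nCells = 300,
                          noiseCv = 0.05, seed = 8)
  ts <- generateExperiment(des, sigma = diagonalCovariance(0))
  q <- as.vector(ratios(ts) / trueRatios(ts))
  n <- length(q)
  expect_gte(n, 1e4)
  cvHat <- sd(q) / mean(q)
  se <- 0.05 * sqrt(1 / (2 * (n - 1)))  # delta-method SE of a CV
  expect_lt(abs(cvHat - 0.05), 3 * se + 1e-4)
  # and the mean multiplicative distortion is ~1
  expect_equal(mean(q), 1, tolerance = 0.005)
})

test_that("sizes are independent of parameters unless an effect is planted", {
  des <- experimentDesign("HXT1", postLevel = 55, nCells = 200,
                          noiseCv = 0, duration = 3,
                          samplingInterval = 1, seed = 12)
  ts <- generateExperiment(des)
  size <- cellSizes(ts)
  th <- thetaMatrix(ts)
  for (p in c("vmsi", "vmd", "kim1", "kex1")) {
    ct <- cor.test(size, th[p, ])
    expect_gt(ct$p.value, 0.01)
  }
  # planted effect: larger cells import Mig1 faster
  des2 <- experimentDesign("HXT1", postLevel = 55, nCells = 200,
                           noiseCv = 0, duration = 3,
                           samplingInterval = 1, sizeEffect = 0.5,
                           seed = 12)
  ts2 <- generateExperiment(des2)
  ct <- cor.test(cellSizes(ts2), thetaMatrix(ts2)["kim1", ])
  expect_gt(ct$estimate, 0.3)
  expect_lt(ct$p.value, 1e-6)
})

test_that("trace CSV + sidecar round-trip is the identity", {
  des <- experimentDesign("HXT7", postLevel = 2.75, nCells = 3, seed = 31)
  ts <- generateExperiment(des)
  f <- tempfile(fileext = ".csv")
  writeTraces(ts, f)
  ts2 <- readTraces(f)
  expect_identical(ratios(ts2), ratios(ts))
  expect_identical(trueRatios(ts2), trueRatios(ts))
  expect_identical(traceTimes(ts2), traceTimes(ts))
  expect_identical(thetaMatrix(ts2), thetaMatrix(ts))
  expect_identical(etaMatrix(ts2), etaMatrix(ts))
  expect_identical(unname(cellSizes(ts2)), unname(cellSizes(ts)))
  expect_identical(S4Vectors::metadata(ts2)$seed,
                   S4Vectors::metadata(ts)$seed)
  expect_identical(parameterVector(S4Vectors::metadata(ts2)$thetaBar),
                   parameterVector(S4Vectors::metadata(ts)$thetaBar))
  expect_true(isSynthetic(ts2))
})

test_that("invalid and observational trace files are handled", {
  des <- experimentDesign("WT", nCells = 2, seed = 3)
  ts <- generateExperiment(des)
  f <- tempfile(fileext = ".csv")
  writeTraces(ts, f)

  # corrupt one ratio: validation points at the row and column
  lines <- readLines(f)
  lines[3] <- sub("^(cell_001,[^,]*,)[^,]*", "\\1-0.5", lines[3])
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(readTraces(bad), "row 2.*ratio")

  # without the sidecar the set is observational (no ground truth)
  obs <- tempfile(fileext = ".csv")
  file.copy(f, obs)
  ts2 <- readTraces(obs)
  expect_false(isSynthetic(ts2))
  expect_null(thetaMatrix(ts2))
  expect_equal(ratios(ts2), ratios(ts), ignore_attr = TRUE)
})

test_that("glucose unit conversion matches the protocol labels", {
  expect_identical(mmToPercent(0), 0)
  expect_equal(mmToPercent(220), 3.9635, tolerance = 1e-4)
  expect_equal(mmToPercent(2.75), 0.049544, tolerance = 1e-4)
  expect_equal(glucosePercentLabel(paperUpshifts()),
               c(0, 0.05, 0.2, 0.5, 1, 4))
  expect_error(mmToPercent(-1), "non-negative")
})
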