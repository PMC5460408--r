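# Hand-built toy TraceSet: full control over crossings.
toyTraces <- function(ratioMatrix, time = NULL, size = NULL) {
  n <- ncol(ratioMatrix)
  if (is.null(time)) time <- seq(-2, 15, length.out = nrow(ratioMatrix))
  if (is.null(size)) size <- seq(20, 40, length.out = n)
  TraceSet(ratio = ratioMatrix, time = time,
           cellId = sprintf("cell_%03d", seq_len(n)), size = size,
           strain = strainConfig("WT"), profile = glucoseProfile(220),
           synthetic = FALSE)
}

test_that("responder calls and response times match manual enumeration", {
  tm <- seq(-2, 15, by = 1)  # two pre-shift samples (-2, -1)
  flat <- rep(1, length(tm))
  resp1 <- flat; resp1[tm >= 3] <- 2     # crosses 1.5x at t = 3
  resp2 <- flat; resp2[tm >= 8] <- 1.8   # crosses at t = 8
  spike <- flat; spike[tm == 5] <- 3     # single-sample spike, debounced
  ts <- toyTraces(cbind(resp1, resp2, spike), time = tm)
  s <- summarizeTraces(ts, thresholdFactor = 1.5, debounce = 2)
  expect_equal(s$responderFraction, 2 / 3)
  expect_equal(s$perCell$responder, c(TRUE, TRUE, FALSE))
  expect_equal(s$perCell$response_time_min, c(3, 8, NA))
  expect_equal(s$perCell$baseline, c(1, 1, 1))
  expect_equal(s$perCell$final, c(2, 1.8, 1))
  # the single spike does count without the debounce
  s1 <- summarizeTraces(ts, thresholdFactor = 1.5, debounce = 1)
  expect_equal(s1$perCell$responder, c(TRUE, TRUE, TRUE))
  expect_equal(s1$perCell$response_time_min[3], 5)
})

test_that("flat populations never respond", {
  tm <- seq(-2, 15, by = 1)
  ts <- toyTraces(matrix(1.2, length(tm), 4), time = tm)
  s <- summarizeTraces(ts)
  expect_equal(s$responderFraction, 0)
  expect_true(all(is.na(s$perCell$response_time_min)))
})

test_that("responder calls are invariant to a common scale factor", {
  des <- experimentDesign("WT", nCells = 6, seed = 21)
  ts <- generateExperiment(des)
  s1 <- summarizeTraces(ts)
  scaled <- ts
  SummarizedExperiment::assay(scaled, "ratio") <- ratios(ts) * 7.5
  s2 <- summarizeTraces(scaled)
  expect_identical(s2$perCell$responder, s1$perCell$responder)
  expect_identical(s2$perCell$response_time_min,
                   s1$perCell$response_time_min)
})

test_that("responder fraction is monotone in the threshold factor", {
  des <- experimentDesign("WT", nCells = 8, seed = 33)
  ts <- generateExperiment(des)
  fr <- vapply(c(1.1, 1.3, 1.5, 2, 3), function(f)
    summarizeTraces(ts, thresholdFactor = f)$responderFraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("summaries are invariant to cell order and match a naive loop", {
  des <- experimentDesign("HXT1", postLevel = 55, nCells = 10, seed = 14)
  ts <- generateExperiment(des)
  s <- summarizeTraces(ts)
  naive <- flatSummary(ts)
  expect_equal(s$perCell$baseline, naive$baseline, tolerance = 1e-12)
  expect_equal(s$perCell$final, naive$final, tolerance = 1e-12)
  expect_identical(s$perCell$responder, naive$responder)
  expect_equal(s$perCell$response_time_min, naive$response_time_min)

  perm <- c(7, 2, 9, 1, 10, 3, 5, 8, 6, 4)
  sp <- summarizeTraces(ts[, perm])
  expect_equal(sp$perCell$baseline, s$perCell$baseline[perm])
  expect_identical(sp$perCell$responder, s$perCell$responder[perm])
  expect_identical(sp$fractionCurve$fraction, s$fractionCurve$fraction)
  expect_equal(sp$responderFraction, s$responderFraction)
})

test_that("a lone responder yields a step fraction curve", {
  tm <- seq(-2, 15, by = 1)
  r <- rep(1, length(tm)); r[tm >= 4] <- 2
  ts <- toyTraces(matrix(r, ncol = 1), time = tm)
  fc <- responderFractionCurve(ts, 1.5)
  expect_identical(unique(fc$fraction[fc$time_min < 4]), 0)
  expect_identical(unique(fc$fraction[fc$time_min >= 4]), 1)
  expect_equal(attr(fc, "timeToMax"), 4)
})

test_that("CV over time follows the sample-sd convention", {
  tm <- seq(-2, 15, by = 1)
  ts <- toyTraces(cbind(rep(1, length(tm)), rep(3, length(tm))), time = tm)
  cv <- cvOverTime(ts)
  expect_equal(unique(cv$cv), sqrt(2) / 2)
  ident <- toyTraces(matrix(2, length(tm), 3), time = tm)
  expect_true(all(cvOverTime(ident)$cv == 0))
  expect_error(cvOverTime(toyTraces(matrix(1, length(tm), 1), time = tm)),
               "at least 2")
})

test_that("population CV grows with the cell-to-cell dispersion", {
  grid <- seq(0, 6, by = 1)
  cvAt <- vapply(c(0.01, 0.04, 0.16), function(v) {
    pop <- simulatePopulation(defaultParameters(), diagonalCovariance(v),
                              15, strainConfig("HXT1"), glucoseProfile(55),
                              grid, seed = 6)
    mean(cvOverTime(pop)$cv[-1])
  }, numeric(1))
  expect_true(all(diff(cvAt) > 0))
})

test_that("size-response association finds the truth", {
  # default generator: sizes carry no information about the response
  des <- experimentDesign("HXT1", postLevel = 220, nCells = 200, seed = 19)
  ts <- generateExperiment(des)
  a <- sizeResponseAssociation(ts)
  expect_true(a$nullConsistent)
  expect_true(a$conf.int[1] <= 0 && a$conf.int[2] >= 0)

  # a planted positive coupling is detected
  des2 <- experimentDesign("HXT1", postLevel = 220, nCells = 100,
                           sizeEffect = 0.6, seed = 19)
  ts2 <- generateExperiment(des2)
  a2 <- sizeResponseAssociation(ts2)
  expect_gt(a2$estimate, 0)
  expect_gt(a2$conf.int[1], 0)
  expect_false(a2$nullConsistent)

  # degenerate: the final ratio duplicated as size correlates exactly
  tm <- seq(-2, 15, by = 1)
  r <- outer(rep(1, length(tm)), c(1, 2, 3, 4))
  ts3 <- toyTraces(r, time = tm, size = c(1, 2, 3, 4))
  expect_equal(sizeResponseAssociation(ts3)$estimate, 1)
  expect_error(sizeResponseAssociation(toyTraces(r, time = tm,
                                                 size = rep(2, 4))),
               "constant")
})
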