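params <- defaultParameters()
theta <- parameterVector(params)
wt <- strainConfig("WT")
hxt1 <- strainConfig("HXT1")
hxt7 <- strainConfig("HXT7")

test_that("reaction rates follow the kinetics ledger", {
  zero <- setNames(rep(0, 8), speciesNames())
  expect_equal(unname(reactionRates(zero, 0, params, wt)), rep(0, 12))

  # strain masking: HXT1 background switches off Hxt4 and Hxt7 uptake
  st <- initialState(params, hxt1)
  r <- reactionRates(st, 55, params, hxt1)
  expect_identical(unname(r[c("r4i", "r7i")]), c(0, 0))

  # Michaelis-Menten quotient against hand arithmetic: km1 = 100 mM,
  # gex = 220 mM gives r1i = vm1 * 220 / 320
  r <- reactionRates(st, 220, params, wt)
  expect_equal(unname(r["r1i"]), theta[["vm1"]] * 220 / 320)
  expect_true(all(r >= 0))
})

test_that("high-affinity Hxt7 uptake is near-saturated across upshifts", {
  st <- initialState(params, hxt7)
  r220 <- reactionRates(st, 220, params, hxt7)[["r7i"]]
  r2.75 <- reactionRates(st, 2.75, params, hxt7)[["r7i"]]
  expect_lt(r220 / r2.75, 1.4)
})

test_that("rate and state validation names the offending field", {
  st <- initialState(params, wt)
  bad <- st; bad["cmig1"] <- -1
  expect_error(reactionRates(bad, 0, params, wt), "cmig1")
  expect_error(reactionRates(st, -5, params, wt), "gex")
  badP <- theta; badP["vmd"] <- -2
  expect_error(reactionRates(st, 0, modelParameters(badP), wt), "positive")
})

test_that("derivatives telescope: Mig1 and Snf1 totals have zero flux", {
  set.seed(42)
  profile <- glucoseProfile(55)
  for (i in 1:25) {
    st <- setNames(runif(8, 0, 2), speciesNames())
    d <- pathwayDerivatives(st, runif(1, 0, 15), params,
                            sample(list(wt, hxt1, hxt7), 1)[[1]], profile)
    expect_lt(abs(sum(d[c("cmig1p", "cmig1", "nmig1", "nmig1p")])), 1e-12)
    expect_lt(abs(sum(d[c("csnf1", "csnf1p", "nsnf1p")])), 1e-12)
  }
})

test_that("derivatives match a centered finite difference of the flow", {
  st <- initialState(params, wt)
  profile <- glucoseProfile(220)
  h <- 1e-4
  # state at t = 2 min post-shift, then central difference around it
  grid <- c(0, 2 - h, 2, 2 + h)
  tr <- simulateCell(params, wt, profile, grid)
  fd <- (tr@states[4L, ] - tr@states[2L, ]) / (2 * h)
  an <- pathwayDerivatives(tr@states[3L, ], 2, params, wt, profile)
  expect_lt(max(abs(fd - an) / pmax(abs(an), 1e-3)), 1e-4)
})

test_that("relaxed initial state is a glucose-free steady state", {
  for (s in list(wt, hxt1, hxt7)) {
    st <- initialState(params, s)
    expect_equal(st[["gin"]], 0, tolerance = 1e-10)
    # conservation of the configured totals is exact
    expect_equal(sum(st[c("cmig1", "cmig1p", "nmig1", "nmig1p")]), 1,
                 tolerance = 1e-9)
    expect_equal(sum(st[c("csnf1", "csnf1p", "nsnf1p")]), 1,
                 tolerance = 1e-9)
  }
  # holding gex = 0 from the relaxed state the observable stays put
  tr <- simulateCell(params, wt, glucoseProfile(0))
  expect_lt(max(abs(tr@ratio - tr@ratio[1L])), 1e-3)
})

test_that("relaxation failure is reported with the residual norm", {
  expect_error(initialState(params, wt, relaxTime = 1e-4), "residual RHS")
})

test_that("no-upshift control trace is constant at baseline", {
  tr <- simulateCell(params, hxt1, glucoseProfile(0),
                     timeGrid = seq(-2, 15, by = 0.5))
  expect_lt(diff(range(tr@ratio)), 1e-3)
})

test_that("adaptive solution matches the fixed-step RK4 oracle", {
  grid <- seq(0, 15, by = 1)
  for (case in list(list(wt, 220), list(hxt1, 11), list(hxt7, 2.75))) {
    profile <- glucoseProfile(case[[2]])
    tr <- simulateCell(params, case[[1]], profile, grid)
    oracle <- rk4Simulate(params, case[[1]], profile, grid, h = 1e-3)
    expect_lt(maxRelDiff(tr@states, oracle), 1e-5)
  }
})

test_that("simulated trajectories conserve Mig1 and Snf1 totals", {
  tr <- simulateCell(params, wt, glucoseProfile(220),
                     timeGrid = seq(-2, 15, by = 0.25))
  mig <- rowSums(tr@states[, c("cmig1", "cmig1p", "nmig1", "nmig1p")])
  snf <- rowSums(tr@states[, c("csnf1", "csnf1p", "nsnf1p")])
  expect_lt(diff(range(mig)) / mean(mig), 1e-6)
  expect_lt(diff(range(snf)) / mean(snf), 1e-6)
  expect_true(all(tr@states >= 0))
})

test_that("inactive transporter parameters cannot affect the output", {
  profile <- glucoseProfile(55)
  tr1 <- simulateCell(params, hxt1, profile)
  altered <- parameterVector(params)
  altered[c("vm4", "km4", "vm7", "km7")] <-
    altered[c("vm4", "km4", "vm7", "km7")] * 7.3
  tr2 <- simulateCell(modelParameters(altered), hxt1, profile)
  expect_identical(tr1@states, tr2@states)
})

test_that("HXT1 final ratio increases with the upshift level", {
  finals <- vapply(c(2.75, 11, 27.5, 55, 220), function(g)
    tail(simulateCell(params, hxt1, glucoseProfile(g))@ratio, 1),
    numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("the observable ratio handles limit cases", {
  st <- setNames(rep(0, 8), speciesNames())
  st[c("nmig1", "nmig1p", "cmig1", "cmig1p")] <- c(0.3, 0.1, 0.2, 0.2)
  expect_equal(mig1Ratio(st), 1.0)
  allCyto <- setNames(rep(0, 8), speciesNames())
  allCyto["cmig1"] <- 1
  expect_lt(mig1Ratio(allCyto), 1e-8)
  symm <- setNames(rep(0.5, 8), speciesNames())
  expect_equal(mig1Ratio(symm), 1.0)
})

test_that("parameter presets round-trip bit-exactly through YAML and JSON", {
  preset <- system.file("extdata", "default_parameters.yaml",
                        package = "MigFlux")
  expect_identical(parameterVector(readParameters(preset)),
                   parameterVector(params))
  set.seed(7)
  p <- modelParameters(theta * exp(rnorm(18, 0, 0.3)))
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeParameters(p, f)
    expect_identical(parameterVector(readParameters(f)),
                     parameterVector(p))
  }
})
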