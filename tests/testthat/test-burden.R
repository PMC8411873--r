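test_that("GEMM relative risk honours its closed form and boundary identities", {
  expect_equal(gemmRelativeRisk(2.4, theta = 0.14, alpha = 1.6, mu = 15.5,
                                nu = 36.8, cf = 2.4), 1)
  expect_equal(gemmRelativeRisk(c(0, 1, 2.3), 0.14, 1.6, 15.5, 36.8, 2.4),
               rep(1, 3))
  expect_equal(gemmRelativeRisk(50, theta = 0, alpha = 1.6, mu = 15.5,
                                nu = 36.8), 1)
  # independent single-expression evaluation at z = 20
  expect_equal(gemmRelativeRisk(22.4, 0.1, 2, 10, 30, 2.4),
               gemmOracle(22.4, 0.1, 2, 10, 30, 2.4), tolerance = 1e-14)
  expect_error(gemmRelativeRisk(-1, 0.1, 2, 10, 30), "nonnegative")
})

test_that("GEMM RR is monotone nondecreasing on a dense grid", {
  p <- paramTable(defaultGEMMParameters("ncd_lri"))
  grid <- seq(0, 300, length.out = 1e4)
  rr <- gemmRelativeRisk(grid, p$theta, p$alpha, p$mu, p$nu, p$cf)
  expect_true(all(diff(rr) >= -1e-13))
  expect_true(all(rr >= 1))
})

test_that("ozone relative risk is multiplicative in 10-ppb increments", {
  erf <- OzoneERFParameters(rr = 1.12, rrLow = 1.08, rrHigh = 1.16,
                            tmrel = 30)
  expect_equal(ozoneRelativeRisk(30, erf), 1)
  expect_equal(ozoneRelativeRisk(10, erf), 1)
  expect_equal(ozoneRelativeRisk(40, erf), 1.12)
  expect_equal(ozoneRelativeRisk(50, erf), 1.12^2)
})

test_that("attributable fraction follows (RR - 1)/RR", {
  expect_equal(attributableFraction(1), 0)
  expect_equal(attributableFraction(2), 0.5)
  expect_equal(attributableFraction(1.25), 0.2)
  expect_error(attributableFraction(0), "positive")
  expect_warning(af <- attributableFraction(0.8), "below 1")
  expect_lt(af, 0)
  # AF o RR bounded in [0, 1) on any nonnegative field
  p <- paramTable(defaultGEMMParameters("ncd_lri"))
  af <- attributableFraction(
    gemmRelativeRisk(runif(1e3, 0, 500), p$theta, p$alpha, p$mu, p$nu,
                     p$cf))
  expect_true(all(af >= 0 & af < 1))
})

test_that("scenario burden reproduces hand-computable cases", {
  gemm <- unitBasisGEMM(theta = log(2))
  # counterfactual everywhere: zero burden
  p0 <- paramTable(gemm); p0$cf <- 10
  zero <- scenarioBurden(constantField(10), uniformPop(1e4),
                         flatBaseline(), GEMMParameters(p0),
                         list(wholeMask()))
  expect_equal(burdenStrata(zero)$mortality, 0)

  # single cell at RR = 2 with rate x fraction x pop = 1000: burden 500
  f1 <- ConcentrationField(matrix(exp(1) - 1, 1, 1), 1, 1, "PM2.5",
                           "annual", "all")
  p1 <- PopulationGrid(matrix(1e5, 1, 1), 1, 1)
  m1 <- RegionMask("ALL", matrix(TRUE, 1, 1), 1, 1)
  b <- scenarioBurden(f1, p1, flatBaseline(mort = 0.01, frac = 1), gemm,
                      list(m1))
  expect_equal(burdenStrata(b)$mortality, 500, tolerance = 1e-9)

  # doubling population doubles the burden
  p2 <- PopulationGrid(matrix(2e5, 1, 1), 1, 1)
  b2 <- scenarioBurden(f1, p2, flatBaseline(mort = 0.01, frac = 1), gemm,
                       list(m1))
  expect_equal(burdenStrata(b2)$mortality,
               2 * burdenStrata(b)$mortality)

  # missing baseline names the region
  expect_error(
    scenarioBurden(f1, p1, flatBaseline(region = "ELSEWHERE"), gemm,
                   list(m1)),
    "missing baseline.*ALL")
})

test_that("fire-attributable burden is the per-stratum scenario difference", {
  mk <- function(m, scen) BurdenResult(
    data.frame(region = c("A", "B"), cause = "ncd_lri",
               age_group = "25plus", mortality = m, dalys = 10 * m),
    scenario = scen)
  same <- fireAttributableBurden(mk(c(5, 7), "all"), mk(c(5, 7), "nofire"))
  expect_equal(burdenStrata(same)$mortality, c(0, 0))

  fire <- fireAttributableBurden(mk(c(120, 80), "all"),
                                 mk(c(100, 60), "nofire"))
  st <- burdenStrata(fire)
  expect_equal(st$mortality, c(20, 20))
  expect_equal(st$mortality_reduction_pct, c(100 * 20 / 120, 25))
  # subtraction commutes with summing strata
  expect_equal(sum(st$mortality), (120 + 80) - (100 + 60))

  bad <- mk(c(1, 2), "nofire"); bad@strata$region <- c("A", "C")
  expect_error(fireAttributableBurden(mk(c(1, 2), "all"), bad),
               "alignment")
})

test_that("burden over a disjoint partition sums to the whole-domain burden", {
  cfg <- smallConfig()
  pair <- generateScenarioPair(cfg)
  pop <- generatePopulation(cfg)
  masks <- quadrantMasks(gridLat(pair), gridLon(pair))
  gemm <- defaultGEMMParameters("ncd_lri")
  baseQ <- BaselineHealthData(defaultBaseline(multipliers = 1))
  baseW <- flatBaseline(region = "ALL", mort = 0.0060, daly = 0.230,
                        frac = 0.65)
  f <- scenarioField(pair, "pm25_annual", "all")
  parts <- scenarioBurden(f, pop, baseQ, gemm, masks)
  whole <- scenarioBurden(
    f, pop, baseW, gemm,
    list(RegionMask("ALL", matrix(TRUE, length(gridLat(pair)),
                                  length(gridLon(pair))),
                    gridLat(pair), gridLon(pair))))
  expect_equal(sum(burdenStrata(parts)$mortality[
    burdenStrata(parts)$cause == "ncd_lri"]),
    burdenStrata(whole)$mortality, tolerance = 1e-12)
})

test_that("a linearized response makes fire burden proportional to exposure difference", {
  # near-linear GEMM basis: logistic weight ~ 1 and large alpha give
  # log RR ~ theta z / alpha, so M_FIRE ~ theta/alpha x rate x frac x
  # sum(pop x (C_all - C_nofire)) for small theta
  cfg <- smallConfig(noise = quietNoise())
  pair <- generateScenarioPair(cfg)
  pop <- generatePopulation(cfg)
  gemm <- GEMMParameters(data.frame(
    cause = "ncd_lri", age_group = "25plus", theta = 1e-5, theta_se = 0,
    alpha = 1e4, mu = -1e3, nu = 1, cf = 0))
  base <- flatBaseline(mort = 0.01, frac = 1)
  msk <- list(RegionMask("ALL",
                         matrix(TRUE, length(gridLat(pair)),
                                length(gridLon(pair))),
                         gridLat(pair), gridLon(pair)))
  bAll <- scenarioBurden(scenarioField(pair, "pm25_annual", "all"), pop,
                         base, gemm, msk)
  bNof <- scenarioBurden(scenarioField(pair, "pm25_annual", "nofire"),
                         pop, base, gemm, msk)
  mFire <- sum(burdenStrata(fireAttributableBurden(bAll, bNof))$mortality)
  diffExp <- sum(fieldValues(pop) *
                 (fieldValues(scenarioField(pair, "pm25_annual", "all")) -
                  fieldValues(scenarioField(pair, "pm25_annual",
                                            "nofire"))))
  predicted <- (1e-5 / 1e4) * 0.01 * diffExp
  expect_equal(mFire, predicted, tolerance = 5e-3)
})

test_that("Monte-Carlo intervals collapse, reproduce and bracket correctly", {
  cfg <- smallConfig()
  pair <- generateScenarioPair(cfg)
  pop <- generatePopulation(cfg)
  masks <- quadrantMasks(gridLat(pair), gridLon(pair))
  fAll <- scenarioField(pair, "pm25_annual", "all")
  fNof <- scenarioField(pair, "pm25_annual", "nofire")

  # all input uncertainties zero: the 95UI collapses to the central value
  gemm0 <- GEMMParameters(transform(
    paramTable(defaultGEMMParameters("ncd_lri")), theta_se = 0))
  base0 <- BaselineHealthData(local({
    tb <- defaultBaseline(multipliers = 1)
    tb$mort_low <- tb$mort_high <- tb$mort_rate
    tb$daly_low <- tb$daly_high <- tb$daly_rate
    tb$frac_low <- tb$frac_high <- tb$age_fraction
    tb
  }))
  ui0 <- uncertaintyInterval(fAll, fNof, pop, base0, gemm0, masks,
                             nDraws = 200, seed = 3L)
  st0 <- burdenStrata(ui0$fire)
  expect_equal(st0$mortality_low, st0$mortality, tolerance = 1e-12)
  expect_equal(st0$mortality_high, st0$mortality, tolerance = 1e-12)

  gemm <- defaultGEMMParameters("ncd_lri")
  base <- BaselineHealthData(defaultBaseline(multipliers = 1))
  ui1 <- uncertaintyInterval(fAll, fNof, pop, base, gemm, masks,
                             nDraws = 300, seed = 5L)
  ui2 <- uncertaintyInterval(fAll, fNof, pop, base, gemm, masks,
                             nDraws = 300, seed = 5L)
  expect_identical(burdenDraws(ui1$fire), burdenDraws(ui2$fire))
  st <- burdenStrata(ui1$fire)
  expect_true(all(st$mortality_low <= st$mortality + 1e-9))
  expect_true(all(st$mortality_high >= st$mortality - 1e-9))
  # per-draw coherence of the subtraction
  expect_equal(burdenDraws(ui1$fire)$mortality,
               burdenDraws(ui1$all)$mortality -
                 burdenDraws(ui1$nofire)$mortality)
  expect_error(uncertaintyInterval(fAll, fNof, pop, base, gemm, masks,
                                   nDraws = 10), "nDraws")
})

test_that("per-capita rates scale as deaths per 100,000", {
  expect_equal(perCapitaRate(25, 1e5), 25)
  expect_equal(perCapitaRate(0, 1e5), 0)
  expect_equal(perCapitaRate(50, 2e5), 0.5 * perCapitaRate(50, 1e5))
  expect_error(perCapitaRate(10, 0), "population")
})
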