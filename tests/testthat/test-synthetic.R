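test_that("zero fire amplitude collapses the scenario pair", {
  cfg <- smallConfig(plumes = data.frame(lat = numeric(), lon = numeric(),
                                         amplitude = numeric(),
                                         decayKm = numeric()),
                     ozone = list(background = 38, seasonalAmplitude = 6,
                                  fireEnhancement = 0),
                     noise = quietNoise())
  pair <- generateScenarioPair(cfg)
  for (prod in c("pm25_monthly", "pm25_annual", "pm10_monthly", "o3_dm8h"))
    expect_equal(fieldValues(scenarioField(pair, prod, "all")),
                 fieldValues(scenarioField(pair, prod, "nofire")))
})

test_that("a single plume injects its amplitude at its centre in the peak month", {
  # plume centred exactly on a cell centre
  cfg <- smallConfig(plumes = data.frame(lat = 12.25, lon = 102.25,
                                         amplitude = 30, decayKm = 200),
                     noise = quietNoise())
  pair <- generateScenarioPair(cfg)
  fire <- fieldValues(fireContribution(pair, "pm25_monthly"))
  iLat <- match(12.25, gridLat(pair)); iLon <- match(102.25, gridLon(pair))
  expect_equal(fire[iLat, iLon, 3L], 30, tolerance = 1e-12)
  # fire contribution vanishes outside the fire season, everywhere
  expect_true(all(fire[, , setdiff(1:12, 1:5)] == 0))
  # and decays away from the centre
  expect_lt(fire[iLat, iLon + 4L, 3L], 30)
})

test_that("the pair satisfies ordering, nonnegativity and annual-mean identities", {
  pair <- generateScenarioPair(smallConfig())
  for (prod in c("pm25_monthly", "pm10_monthly")) {
    a <- fieldValues(scenarioField(pair, prod, "all"))
    n <- fieldValues(scenarioField(pair, prod, "nofire"))
    expect_true(all(a >= n - 1e-12))
    expect_true(all(n >= 0))
  }
  for (scen in c("all", "nofire")) {
    monthly <- fieldValues(scenarioField(pair, "pm25_monthly", scen))
    annual <- fieldValues(scenarioField(pair, "pm25_annual", scen))
    expect_equal(annual, apply(monthly, c(1, 2), mean), tolerance = 1e-9)
  }
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  p1 <- generateScenarioPair(smallConfig())
  p2 <- generateScenarioPair(smallConfig())
  expect_identical(fieldValues(scenarioField(p1, "pm25_monthly", "all")),
                   fieldValues(scenarioField(p2, "pm25_monthly", "all")))
  p3 <- generateScenarioPair(smallConfig(seed = 8L))
  expect_false(identical(
    fieldValues(scenarioField(p1, "pm25_monthly", "all")),
    fieldValues(scenarioField(p3, "pm25_monthly", "all"))))
})

test_that("population conserves the configured total and is reproducible", {
  cfg <- smallConfig()
  pop <- generatePopulation(cfg)
  expect_true(all(fieldValues(pop) >= 0))
  expect_lt(abs(sum(fieldValues(pop)) - cfg@population$total),
            1e-3 * cfg@population$total)
  expect_identical(fieldValues(generatePopulation(cfg)), fieldValues(pop))
  zero <- smallConfig(population = list(total = 0, nClusters = 3L,
                                        clusterDecayKm = 150,
                                        uniformFloor = 0.2))
  expect_true(all(fieldValues(generatePopulation(zero)) == 0))
})

test_that("IMR surface honours coupling, clipping and alignment", {
  cfg0 <- smallConfig(imr = list(base = 40, coupling = 0, noiseSD = 0))
  pair <- generateScenarioPair(cfg0)
  fire <- fireContribution(pair, "pm25_annual")
  imr0 <- generateIMRGrid(cfg0, fire)
  expect_true(all(fieldValues(imr0) == 40))

  cfgC <- smallConfig(imr = list(base = 30, coupling = 3, noiseSD = 5))
  imrC <- generateIMRGrid(cfgC, fire)
  rho <- cor(as.vector(fieldValues(imrC)), as.vector(fieldValues(fire)),
             method = "spearman")
  expect_gt(rho, 0)
  expect_true(all(fieldValues(imrC) >= 0 & fieldValues(imrC) <= 100))

  other <- ConcentrationField(matrix(1, 3, 3), 1:3, 1:3, "PM2.5", "annual")
  expect_error(generateIMRGrid(cfgC, other), "alignment")
})

test_that("station series reproduce the configured bias structure", {
  cfgId <- smallConfig(noise = quietNoise(bias = 1.0))
  pair <- generateScenarioPair(cfgId)
  st <- generateStationSeries(cfgId, pair, 12L)
  expect_length(st, 12L)
  d <- stationData(st[[1L]])
  expect_equal(d$observed, d$model_all)

  # observed = 2 x model: the model underestimates by a factor 2
  cfg2 <- smallConfig(noise = quietNoise(bias = 2.0))
  pair2 <- generateScenarioPair(cfg2)
  st2 <- generateStationSeries(cfg2, pair2, 3L)
  d2 <- stationData(st2[[1L]])
  expect_equal(nmbf(d2$model_all, d2$observed), -1, tolerance = 1e-12)
  expect_error(generateStationSeries(cfg2, pair2, 0L), "nStations")
})

test_that("hourly ozone generator agrees with the ADM8h operation", {
  out <- generateHourlyO3(smallConfig(), nDays = 3L)
  fromHourly <- adm8h(out$hourly)
  fromDaily <- adm8h(out$dm8h)
  expect_equal(fieldValues(fromHourly), fieldValues(fromDaily),
               tolerance = 1e-9)
})
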