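test_that("regional aggregation sums members and validates groupings", {
  br <- BurdenResult(
    data.frame(region = c("A", "B", "C"), cause = "ncd_lri",
               age_group = "25plus", mortality = c(100, 250, 30),
               dalys = c(1000, 2500, 300)),
    scenario = "fire")
  agg <- aggregateRegions(br, list(AB = c("A", "B"), C = "C"))
  expect_equal(agg$mortality, c(350, 30))
  expect_equal(agg$dalys, c(3500, 300))
  expect_error(aggregateRegions(br, list()), "empty")
  expect_error(aggregateRegions(br, list(G = character())), "empty")
  expect_error(aggregateRegions(br, list(G = c("A", "Z"))), "Z")
})

test_that("group 95UIs from per-draw sums are no wider than endpoint sums", {
  cfg <- smallConfig()
  pair <- generateScenarioPair(cfg)
  pop <- generatePopulation(cfg)
  masks <- quadrantMasks(gridLat(pair), gridLon(pair))
  ui <- uncertaintyInterval(scenarioField(pair, "pm25_annual", "all"),
                            scenarioField(pair, "pm25_annual", "nofire"),
                            pop, BaselineHealthData(defaultBaseline()),
                            defaultGEMMParameters("ncd_lri"), masks,
                            nDraws = 400, seed = 9L)
  st <- burdenStrata(ui$fire)
  agg <- aggregateRegions(ui$fire, list(TOTAL = unique(st$region)))
  drawWidth <- agg$mortality_high - agg$mortality_low
  endpointWidth <- sum(st$mortality_high) - sum(st$mortality_low)
  expect_lte(drawWidth, endpointWidth * (1 + 1e-9))
  # group central value equals the member sum exactly, before rounding
  expect_equal(agg$mortality, sum(st$mortality))
})

test_that("presentation rounding follows the table conventions", {
  expect_equal(applyRounding(27451, "pm25_mortality"), 27500)
  expect_equal(applyRounding(27449, "pm25_mortality"), 27400)
  expect_equal(applyRounding(2254, "o3_mortality"), 2250)
  expect_equal(applyRounding(2255, "o3_mortality"), 2260)
  expect_equal(applyRounding(0, "pm25_dalys"), 0)
  expect_equal(applyRounding(-150, "pm25_mortality"), -200) # half away
})

test_that("the pipeline runs end-to-end, reruns identically and names failing stages", {
  cfg <- smallConfig()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  # the 10 x 10 domain leaves an extreme IMR group with < 2 cells, which
  # the equity stage reports as a warning by design
  res <- suppressWarnings(runPipeline(cfg, out1, nStations = 6L,
                                      nDraws = 150))
  for (f in c("burden_summary.csv", "exposure_summary.csv",
              "evaluation_metrics.csv", "equity_imr_bins.csv",
              "stations.csv", "config.yaml", "provenance.json",
              "manifest.json"))
    expect_true(file.exists(file.path(out1, f)))
  suppressWarnings(runPipeline(cfg, out2, nStations = 6L, nDraws = 150))
  expect_identical(readLines(file.path(out1, "burden_summary.csv")),
                   readLines(file.path(out2, "burden_summary.csv")))

  s <- res$summary
  expect_true(all(s$pm25_mortality >= 0))
  expect_true(all(s$pm25_burden_reduction_pct <=
                    s$pm25_exposure_reduction_pct + 1e-9))

  # a baseline missing one region aborts in the burden stage, by name
  cfgBad <- smallConfig(baseline = defaultBaseline(
    regions = c("NW", "NE", "SW")))
  expect_error(runPipeline(cfgBad, withr::local_tempdir(), nStations = 4L,
                           nDraws = 150),
               "stage 'burden'.*SE")
})

test_that("gridded fields, stations and configs round-trip through disk", {
  cfg <- smallConfig()
  pair <- generateScenarioPair(cfg)
  f <- scenarioField(pair, "pm25_monthly", "all")
  path <- file.path(withr::local_tempdir(), "pm25.csv")
  writeField(f, path)
  g <- readField(path)
  expect_equal(fieldValues(g), fieldValues(f), tolerance = 1e-9)
  expect_equal(speciesTag(g), "PM2.5")
  expect_equal(temporalTag(g), "monthly")

  sts <- generateStationSeries(cfg, pair, 3L)
  sPath <- file.path(withr::local_tempdir(), "stations.csv")
  writeStationCSV(sts, sPath)
  back <- readStationCSV(sPath)
  expect_length(back, 3L)
  expect_equal(stationData(back[["ST02"]])$observed,
               stationData(sts[[2L]])$observed, tolerance = 1e-9)

  cPath <- file.path(withr::local_tempdir(), "config.yaml")
  writeConfig(cfg, cPath)
  cfg2 <- readConfig(cPath)
  expect_equal(cfg2@domain, cfg@domain)
  expect_equal(cfg2@plumes$amplitude, cfg@plumes$amplitude)
  expect_identical(
    fieldValues(scenarioField(generateScenarioPair(cfg2), "pm25_annual",
                              "all")),
    fieldValues(scenarioField(pair, "pm25_annual", "all")))
})
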