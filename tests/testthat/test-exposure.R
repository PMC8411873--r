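test_that("bilinear regridding preserves constant and linear fields", {
  src <- ConcentrationField(matrix(10, 6, 6), lat = seq(0, 5),
                            lon = seq(0, 5), species = "PM2.5",
                            temporal = "annual")
  tgt <- regridLinear(src, targetLat = seq(0.5, 4.5, 0.5),
                      targetLon = seq(0.5, 4.5, 0.5))
  expect_true(all(abs(fieldValues(tgt) - 10) < 1e-12))

  lonField <- ConcentrationField(
    outer(rep(1, 6), 2 * seq(0, 5) + 3), lat = seq(0, 5), lon = seq(0, 5),
    species = "PM2.5", temporal = "annual")
  tg <- regridLinear(lonField, seq(0.25, 4.75, 0.5), seq(0.25, 4.75, 0.5))
  expect_equal(fieldValues(tg),
               outer(rep(1, 10), 2 * seq(0.25, 4.75, 0.5) + 3),
               tolerance = 1e-12)

  expect_error(regridLinear(src, seq(-1, 4), seq(0, 4)), "extrapolation")
})

test_that("refine-then-block-average recovers a linear field on the interior", {
  # brute-force check on a 6 x 6 grid: a bilinear (planar) field survives
  # 0.5 -> 0.25 degree refinement followed by 2 x 2 block averaging
  lat <- seq(10.25, 12.75, 0.5); lon <- seq(100.25, 102.75, 0.5)
  plane <- outer(3 * lat, 2 * lon, `+`)
  src <- ConcentrationField(plane, lat, lon, "PM2.5", "annual")
  fineLat <- seq(10.625, 12.375, 0.25); fineLon <- seq(100.625, 102.375, 0.25)
  fine <- regridLinear(src, fineLat, fineLon)
  back <- aggregateMeanToGrid(fieldValues(fine), fineLat, fineLon,
                              targetLat = lat[2:5], targetLon = lon[2:5])
  expect_equal(back, plane[2:5, 2:5], tolerance = 1e-10)
})

test_that("block averaging handles means, missing blocks and checkerboards", {
  fineLat <- c(1, 2); fineLon <- c(1, 2)
  expect_equal(as.numeric(aggregateMeanToGrid(
    matrix(c(10, 30, 20, 40), 2), fineLat, fineLon,
    targetLat = 1.5, targetLon = 1.5)), 25)
  expect_true(is.na(as.numeric(aggregateMeanToGrid(
    matrix(NA_real_, 2, 2), fineLat, fineLon,
    targetLat = 1.5, targetLon = 1.5))))
  expect_equal(as.numeric(aggregateMeanToGrid(
    matrix(c(0, 100, 100, 0), 2), fineLat, fineLon,
    targetLat = 1.5, targetLon = 1.5)), 50)
})

test_that("population weighting behaves as a weighted mean", {
  expect_equal(populationWeightedMean(constantField(12), uniformPop(7)), 12)

  f <- ConcentrationField(matrix(c(10, 30), 1, 2), lat = 1, lon = 1:2,
                          species = "PM2.5", temporal = "annual")
  p <- PopulationGrid(matrix(c(3, 1), 1, 2), lat = 1, lon = 1:2)
  expect_equal(populationWeightedMean(f, p), 15)

  rnd <- constantField(0, n = 4L)
  rnd@values[] <- seq_len(16)
  expect_equal(populationWeightedMean(rnd, uniformPop(5)),
               mean(seq_len(16)))
  # invariant to uniform population rescaling
  expect_equal(populationWeightedMean(rnd, uniformPop(5)),
               populationWeightedMean(rnd, uniformPop(500)))
  expect_error(populationWeightedMean(rnd, uniformPop(0)), "population")
})

test_that("ADM8h matches hand-built and brute-force window results", {
  mk <- function(hours) ConcentrationField(
    array(rep(hours, each = 1), c(1, 1, length(hours))), lat = 1, lon = 1,
    species = "O3", temporal = "hourly")
  expect_equal(as.numeric(fieldValues(adm8h(mk(rep(50, 24))))), 50)

  plateau <- rep(20, 24); plateau[11:18] <- 60 # hours 10..17 (0-based)
  expect_equal(as.numeric(fieldValues(adm8h(mk(plateau)))), 60)

  # triangular diurnal profile vs an exhaustive scan of the 17 windows
  tri <- c(seq(10, 70, length.out = 12), seq(65, 10, length.out = 12))
  brute <- max(vapply(1:17, function(s) mean(tri[s:(s + 7)]), numeric(1)))
  expect_equal(as.numeric(fieldValues(adm8h(mk(tri)))), brute,
               tolerance = 1e-12)

  # a day with missing hours is dropped; all-missing cell is missing
  twoDays <- c(rep(50, 24), rep(NA_real_, 24))
  expect_equal(as.numeric(fieldValues(adm8h(mk(twoDays)))), 50)
  expect_true(is.na(as.numeric(fieldValues(adm8h(mk(rep(NA_real_, 24)))))))
})

test_that("percent change reports the reduction when the source is removed", {
  expect_equal(percentChange(20, 10), 50)
  expect_equal(percentChange(15, 15), 0)
  expect_equal(percentChange(5, 0), 100)
  expect_true(is.na(percentChange(0, 0)))
})

test_that("threshold exceedance population counts strictly-above cells", {
  f <- ConcentrationField(matrix(c(9, 26), 1, 2), lat = 1, lon = 1:2,
                          species = "PM2.5", temporal = "annual")
  p <- PopulationGrid(matrix(c(100, 50), 1, 2), lat = 1, lon = 1:2)
  expect_equal(populationAboveThreshold(f, p, 25), 50)
  expect_equal(populationAboveThreshold(f, p, 100), 0)
  expect_equal(populationAboveThreshold(f, p, 0), 150)
  # exceedance-population reduction bounded by [0, 100] for nonneg fire
  pair <- generateScenarioPair(smallConfig())
  pop <- generatePopulation(smallConfig())
  ea <- populationAboveThreshold(scenarioField(pair, "pm25_annual", "all"),
                                 pop, 25)
  en <- populationAboveThreshold(
    scenarioField(pair, "pm25_annual", "nofire"), pop, 25)
  expect_gte(ea, en)
})
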