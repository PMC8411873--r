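## Regional aggregation, presentation rounding and pipeline orchestration.

#' Aggregate burden strata into regional groups
#'
#' Group central estimates are sums of the member strata; when the burden
#' carries Monte-Carlo draws, group 95UIs come from summing the members'
#' per-draw samples and taking percentiles of the summed draws -- never
#' from summing interval endpoints, which overstates group uncertainty.
#'
#' @param burden a \code{\link{BurdenResult}}.
#' @param groupings named list: group name -> character vector of member
#'   region names (every member must exist in the burden's strata).
#' @return data.frame with one row per group: mortality, dalys and, when
#'   draws are present, 95UI bounds.
#' @export
aggregateRegions <- function(burden, groupings) {
  if (!length(groupings)) stop("empty grouping")
  st <- burdenStrata(burden)
  dr <- burdenDraws(burden)
  rows <- lapply(names(groupings), function(g) {
    members <- groupings[[g]]
    if (!length(members)) stop(sprintf("empty grouping '%s'", g))
    unknown <- setdiff(members, st$region)
    if (length(unknown))
      stop(sprintf("grouping '%s' references unknown region(s): %s", g,
                   paste(unknown, collapse = ", ")))
    sel <- st$region %in% members
    out <- data.frame(region = g,
                      mortality = sum(st$mortality[sel]),
                      dalys = sum(st$dalys[sel]))
    if (length(dr)) {
      mSum <- colSums(dr$mortality[sel, , drop = FALSE])
      dSum <- colSums(dr$dalys[sel, , drop = FALSE])
      qm <- stats::quantile(mSum, c(0.025, 0.975), names = FALSE)
      qd <- stats::quantile(dSum, c(0.025, 0.975), names = FALSE)
      out$mortality_low <- qm[1]; out$mortality_high <- qm[2]
      out$dalys_low <- qd[1]; out$dalys_high <- qd[2]
    }
    out
  })
  do.call(rbind, rows)
}

#' Presentation rounding for burden tables
#'
#' PM2.5 mortality and DALY figures are rounded to the nearest 100, ozone
#' mortality to the nearest 10, halves away from zero. Rounding is
#' presentation-only: machine-readable outputs keep unrounded values.
#'
#' @param value numeric values to round.
#' @param kind \code{"pm25_mortality"}, \code{"pm25_dalys"} or
#'   \code{"o3_mortality"}.
#' @return Rounded values.
#' @export
applyRounding <- function(value,
                          kind = c("pm25_mortality", "pm25_dalys",
                                   "o3_mortality")) {
  kind <- match.arg(kind)
  m <- if (kind == "o3_mortality") 10 else 100
  sign(value) * floor(abs(value) / m + 0.5) * m
}

.stage <- function(name, outdir, manifest, expr) {
  tryCatch(expr, error = function(e) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic configuration
#'
#' Executes generate -> exposure -> burden -> evaluation -> equity ->
#' report, writing tidy CSV tables, equity summaries, a JSON test result
#' and a provenance record to \code{outdir}. Idempotent under a fixed
#' seed (reruns produce byte-identical summary tables). Any stage failure
#' aborts with a stage-named error after writing a manifest of the
#' outputs completed so far.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param outdir output directory (created if needed).
#' @param nStations synthetic stations to generate (default 12).
#' @param nDraws Monte-Carlo draws for the 95UIs (default 1000).
#' @param gemm a \code{\link{GEMMParameters}} set (default the packaged
#'   NCD+LRI aggregate).
#' @param ozoneERF an \code{\link{OzoneERFParameters}} set (default the
#'   packaged example file).
#' @return Invisibly, a list with the main in-memory artifacts (pair,
#'   population, imr, stations, masks, exposure table, burden results,
#'   evaluation metrics, equity summaries, summary table).
#' @export
runPipeline <- function(config, outdir, nStations = 12L, nDraws = 1000L,
                        gemm = defaultGEMMParameters("ncd_lri"),
                        ozoneERF = defaultOzoneERF()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  note <- function(f) manifest <<- c(manifest, f)

  sim <- .stage("simulate", outdir, manifest, {
    pair <- generateScenarioPair(config)
    pop <- generatePopulation(config)
    firePM <- fireContribution(pair, "pm25_annual")
    imr <- generateIMRGrid(config, firePM)
    stations <- generateStationSeries(config, pair, nStations)
    writeStationCSV(stations, file.path(outdir, "stations.csv"))
    note("stations.csv")
    writeConfig(config, file.path(outdir, "config.yaml"))
    note("config.yaml")
    list(pair = pair, pop = pop, imr = imr, firePM = firePM,
         stations = stations)
  })
  masks <- quadrantMasks(gridLat(sim$pair), gridLon(sim$pair))

  expo <- .stage("exposure", outdir, manifest, {
    pmAll <- scenarioField(sim$pair, "pm25_annual", "all")
    pmNof <- scenarioField(sim$pair, "pm25_annual", "nofire")
    o3All <- adm8h(scenarioField(sim$pair, "o3_dm8h", "all"))
    o3Nof <- adm8h(scenarioField(sim$pair, "o3_dm8h", "nofire"))
    regionRow <- function(name, mask) {
      pwA <- populationWeightedMean(pmAll, sim$pop, mask)
      pwN <- populationWeightedMean(pmNof, sim$pop, mask)
      o3A <- populationWeightedMean(o3All, sim$pop, mask)
      o3N <- populationWeightedMean(o3Nof, sim$pop, mask)
      data.frame(
        region = name,
        pm25_pw_all = pwA, pm25_pw_nofire = pwN,
        pm25_exposure_reduction_pct = percentChange(pwA, pwN),
        o3_pw_all = o3A, o3_pw_nofire = o3N,
        o3_exposure_reduction_pct = percentChange(o3A, o3N),
        pop_above_it2_all = populationAboveThreshold(pmAll, sim$pop, 25,
                                                     mask),
        pop_above_it2_nofire = populationAboveThreshold(pmNof, sim$pop, 25,
                                                        mask),
        pop_above_who_all = populationAboveThreshold(pmAll, sim$pop, 10,
                                                     mask),
        pop_above_who_nofire = populationAboveThreshold(pmNof, sim$pop, 10,
                                                        mask))
    }
    tab <- rbind(
      do.call(rbind, Map(regionRow, names(masks), masks)),
      regionRow("TOTAL", NULL))
    utils::write.csv(tab, file.path(outdir, "exposure_summary.csv"),
                     row.names = FALSE)
    note("exposure_summary.csv")
    list(table = tab, pmAll = pmAll, pmNof = pmNof, o3All = o3All,
         o3Nof = o3Nof)
  })

  burden <- .stage("burden", outdir, manifest, {
    baseline <- BaselineHealthData(config@baseline)
    pm <- uncertaintyInterval(expo$pmAll, expo$pmNof, sim$pop, baseline,
                              gemm, masks, nDraws = nDraws,
                              seed = config@seed + 11L)
    o3 <- uncertaintyInterval(expo$o3All, expo$o3Nof, sim$pop, baseline,
                              ozoneERF, masks, nDraws = nDraws,
                              seed = config@seed + 12L)
    list(pm = pm, o3 = o3)
  })

  evalres <- .stage("evaluate", outdir, manifest, {
    pm10All <- scenarioField(sim$pair, "pm10_monthly", "all")
    ann <- function(f) ConcentrationField(.annualValues(f), gridLat(f),
                                          gridLon(f), speciesTag(f),
                                          "annual", scenarioTag(f))
    sel <- selectFireInfluenced(
      ann(pm10All),
      ann(scenarioField(sim$pair, "pm10_monthly", "nofire")),
      sim$stations, 0.20)
    useStations <- if (length(sel) >= 2L) sel else sim$stations
    fd <- lapply(useStations, fireDerivedStation)
    metrics <- rbind(evaluateStations(fd, mode = "per_station"),
                     evaluateStations(fd, mode = "composite"))
    metrics$n_fire_influenced <- length(sel)
    utils::write.csv(metrics, file.path(outdir, "evaluation_metrics.csv"),
                     row.names = FALSE)
    note("evaluation_metrics.csv")
    metrics
  })

  equity <- .stage("equity", outdir, manifest, {
    nonfirePM <- scenarioField(sim$pair, "pm25_annual", "nofire")
    bins <- binExposureByIMR(sim$firePM, sim$imr)
    cmp <- compareExtremeGroups(sim$firePM, sim$imr)
    frac <- exposureSourceFractionByClass(sim$firePM, nonfirePM, sim$imr)
    biv <- bivariateClassification(sim$firePM, sim$imr, pop = sim$pop)
    utils::write.csv(bins, file.path(outdir, "equity_imr_bins.csv"),
                     row.names = FALSE)
    note("equity_imr_bins.csv")
    utils::write.csv(frac, file.path(outdir, "equity_source_fractions.csv"),
                     row.names = FALSE)
    note("equity_source_fractions.csv")
    jsonlite::write_json(cmp, file.path(outdir, "equity_extreme_test.json"),
                         auto_unbox = TRUE, digits = NA)
    note("equity_extreme_test.json")
    list(bins = bins, extreme = cmp, fractions = frac, bivariate = biv)
  })

  summaryTab <- .stage("report", outdir, manifest, {
    tab <- buildSummaryTable(expo$table, burden$pm, burden$o3, sim$pop,
                             masks)
    utils::write.csv(tab, file.path(outdir, "burden_summary.csv"),
                     row.names = FALSE)
    note("burden_summary.csv")
    cfgPath <- file.path(outdir, "config.yaml")
    prov <- list(config_md5 = unname(tools::md5sum(cfgPath)),
                 seed = config@seed,
                 package_version = as.character(
                   utils::packageVersion("fireburden")),
                 r_version = R.version.string)
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE)
    note("provenance.json")
    jsonlite::write_json(as.list(manifest),
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    tab
  })

  invisible(list(pair = sim$pair, population = sim$pop, imr = sim$imr,
                 stations = sim$stations, masks = masks,
                 exposure = expo$table, burdenPM = burden$pm,
                 burdenO3 = burden$o3, evaluation = evalres,
                 equity = equity, summary = summaryTab))
}

#' Assemble the headline per-region summary table
#'
#' One row per region plus a TOTAL row: percentage reductions in
#' population-weighted PM2.5 and ADM8h ozone exposure, percentage burden
#' reductions, averted (fire-attributable) mortality and DALYs with 95UI,
#' ozone mortality with 95UI, and the averted-mortality rate per 100,000
#' persons. Unrounded values are kept; rounded presentation columns
#' (\code{*_rounded}, nearest 100 for PM2.5 figures and nearest 10 for
#' ozone mortality) sit alongside. Group exposure reductions are
#' recomputed from group-level population-weighted means, not averaged
#' across members; group 95UIs come from per-draw aggregation.
#'
#' @param exposureTable per-region exposure summary (from the pipeline's
#'   exposure stage).
#' @param pmBurden,o3Burden results of \code{\link{uncertaintyInterval}}.
#' @param pop a \code{\link{PopulationGrid}}.
#' @param masks named list of \code{\link{RegionMask}}.
#' @return data.frame, one row per region plus \code{"TOTAL"}.
#' @export
buildSummaryTable <- function(exposureTable, pmBurden, o3Burden, pop,
                              masks) {
  groupings <- c(stats::setNames(as.list(names(masks)), names(masks)),
                 list(TOTAL = names(masks)))
  aggPM <- aggregateRegions(pmBurden$fire, groupings)
  aggPMall <- aggregateRegions(pmBurden$all, groupings)
  aggO3 <- aggregateRegions(o3Burden$fire, groupings)
  aggO3all <- aggregateRegions(o3Burden$all, groupings)
  popTotals <- vapply(names(groupings), function(g) {
    if (g == "TOTAL") sum(fieldValues(pop))
    else sum(fieldValues(pop)[maskValues(masks[[g]])])
  }, numeric(1))
  ex <- exposureTable[match(names(groupings), exposureTable$region), ]
  out <- data.frame(
    region = names(groupings),
    pm25_exposure_reduction_pct = ex$pm25_exposure_reduction_pct,
    pm25_burden_reduction_pct = 100 * aggPM$mortality / aggPMall$mortality,
    pm25_mortality = aggPM$mortality,
    pm25_mortality_low = aggPM$mortality_low,
    pm25_mortality_high = aggPM$mortality_high,
    pm25_dalys = aggPM$dalys,
    pm25_dalys_low = aggPM$dalys_low,
    pm25_dalys_high = aggPM$dalys_high,
    o3_exposure_reduction_pct = ex$o3_exposure_reduction_pct,
    o3_burden_reduction_pct = 100 * aggO3$mortality / aggO3all$mortality,
    o3_mortality = aggO3$mortality,
    o3_mortality_low = aggO3$mortality_low,
    o3_mortality_high = aggO3$mortality_high,
    mortality_per_100k = 1e5 * aggPM$mortality / popTotals)
  out$pm25_mortality_rounded <- applyRounding(out$pm25_mortality,
                                              "pm25_mortality")
  out$pm25_dalys_rounded <- applyRounding(out$pm25_dalys, "pm25_dalys")
  out$o3_mortality_rounded <- applyRounding(out$o3_mortality,
                                            "o3_mortality")
  rownames(out) <- NULL
  out
}
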