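## Generics and accessors. Slots are never reached into from user code.

#' @name accessors
#' @title Accessors for fireburden classes
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot content named by the accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x, ...) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("gridLat", function(x) standardGeneric("gridLat"))
#' @rdname accessors
#' @export
setGeneric("gridLon", function(x) standardGeneric("gridLon"))
#' @rdname accessors
#' @export
setGeneric("speciesTag", function(x) standardGeneric("speciesTag"))
#' @rdname accessors
#' @export
setGeneric("temporalTag", function(x) standardGeneric("temporalTag"))
#' @rdname accessors
#' @export
setGeneric("scenarioTag", function(x) standardGeneric("scenarioTag"))
#' @rdname accessors
#' @export
setGeneric("paramTable", function(x) standardGeneric("paramTable"))
#' @rdname accessors
#' @export
setGeneric("burdenStrata", function(x) standardGeneric("burdenStrata"))
#' @rdname accessors
#' @export
setGeneric("burdenDraws", function(x) standardGeneric("burdenDraws"))
#' @rdname accessors
#' @export
setGeneric("stationData", function(x) standardGeneric("stationData"))
#' @rdname accessors
#' @export
setGeneric("stationId", function(x) standardGeneric("stationId"))
#' @rdname accessors
#' @export
setGeneric("fireFraction", function(x) standardGeneric("fireFraction"))
#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname accessors
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' Extract one scenario's field from a ScenarioPair
#'
#' @param x a \code{\link{ScenarioPair}}.
#' @param product product name, e.g. \code{"pm25_annual"}.
#' @param scenario \code{"all"} or \code{"nofire"}.
#' @return A \code{\link{ConcentrationField}}.
#' @export
setGeneric("scenarioField",
           function(x, product, scenario = c("all", "nofire"))
             standardGeneric("scenarioField"))

#' Fire contribution of a product (all-sources minus fires-off)
#'
#' @param x a \code{\link{ScenarioPair}}.
#' @param product product name.
#' @return A \code{\link{ConcentrationField}} with scenario tag
#'   \code{"fire"}.
#' @export
setGeneric("fireContribution",
           function(x, product) standardGeneric("fireContribution"))

setMethod("fieldValues", "ConcentrationField", function(x, ...) x@values)
setMethod("fieldValues", "IMRGrid", function(x, ...) x@values)
setMethod("fieldValues", "PopulationGrid", function(x, ...) x@counts)
setMethod("gridLat", "ConcentrationField", function(x) x@lat)
setMethod("gridLat", "PopulationGrid", function(x) x@lat)
setMethod("gridLat", "IMRGrid", function(x) x@lat)
setMethod("gridLat", "RegionMask", function(x) x@lat)
setMethod("gridLat", "ScenarioPair", function(x) x@lat)
setMethod("gridLon", "ConcentrationField", function(x) x@lon)
setMethod("gridLon", "PopulationGrid", function(x) x@lon)
setMethod("gridLon", "IMRGrid", function(x) x@lon)
setMethod("gridLon", "RegionMask", function(x) x@lon)
setMethod("gridLon", "ScenarioPair", function(x) x@lon)
setMethod("speciesTag", "ConcentrationField", function(x) x@species)
setMethod("temporalTag", "ConcentrationField", function(x) x@temporal)
setMethod("scenarioTag", "ConcentrationField", function(x) x@scenario)
setMethod("paramTable", "GEMMParameters", function(x) x@table)
setMethod("paramTable", "BaselineHealthData", function(x) x@table)
setMethod("burdenStrata", "BurdenResult", function(x) x@strata)
setMethod("burdenDraws", "BurdenResult", function(x) x@draws)
setMethod("stationData", "StationSeries", function(x) x@data)
setMethod("stationId", "StationSeries", function(x) x@id)
setMethod("fireFraction", "StationSeries", function(x) x@fireFraction)
setMethod("maskValues", "RegionMask", function(x) x@mask)
setMethod("regionName", "RegionMask", function(x) x@name)

setMethod("scenarioField", "ScenarioPair",
  function(x, product, scenario = c("all", "nofire")) {
    scenario <- match.arg(scenario)
    prods <- slot(x, scenario)
    if (!product %in% names(prods))
      stop(sprintf("no product '%s' in scenario pair (have: %s)", product,
                   paste(names(prods), collapse = ", ")))
    prods[[product]]
  })

setMethod("fireContribution", "ScenarioPair", function(x, product) {
  fa <- scenarioField(x, product, "all")
  fn <- scenarioField(x, product, "nofire")
  v <- fa@values - fn@values
  if (fa@species %in% c("PM2.5", "PM10")) v <- pmax(v, 0)
  ConcentrationField(v, fa@lat, fa@lon, fa@species, fa@temporal, "fire")
})

setMethod("show", "ConcentrationField", function(object) {
  d <- dim(object@values)
  cat(sprintf("ConcentrationField: %s [%s, %s]\n", object@species,
              object@temporal, object@scenario))
  cat(sprintf("  grid: %d x %d (lat %.2f..%.2f, lon %.2f..%.2f)%s\n",
              d[1], d[2], min(object@lat), max(object@lat),
              min(object@lon), max(object@lon),
              if (length(d) == 3L) sprintf(", %d time slices", d[3]) else ""))
  cat(sprintf("  range: %.3g .. %.3g (%d missing)\n",
              suppressWarnings(min(object@values, na.rm = TRUE)),
              suppressWarnings(max(object@values, na.rm = TRUE)),
              sum(is.na(object@values))))
})

setMethod("show", "ScenarioPair", function(object) {
  cat(sprintf("ScenarioPair on %d x %d grid\n", length(object@lat),
              length(object@lon)))
  cat("  products:", paste(names(object@all), collapse = ", "), "\n")
})

setMethod("show", "PopulationGrid", function(object) {
  cat(sprintf("PopulationGrid: %d x %d cells, %.4g persons total\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

setMethod("show", "IMRGrid", function(object) {
  cat(sprintf("IMRGrid (%s): %d x %d cells, IMR %.1f..%.1f\n",
              object@provenance, nrow(object@values), ncol(object@values),
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d member cells of %d\n", object@name,
              sum(object@mask), length(object@mask)))
})

setMethod("show", "StationSeries", function(object) {
  cat(sprintf("StationSeries %s (%s) at (%.2f, %.2f): %d records, fire fraction %.2f\n",
              object@id, object@species, object@lat, object@lon,
              nrow(object@data), object@fireFraction))
})

setMethod("show", "BurdenResult", function(object) {
  cat(sprintf("BurdenResult [%s]: %d strata, total mortality %.1f yr-1%s\n",
              object@scenario, nrow(object@strata),
              sum(object@strata$mortality),
              if (length(object@draws)) sprintf(" (%d MC draws)",
                  ncol(object@draws$mortality)) else ""))
})

setMethod("show", "EvaluationMetrics", function(object) {
  cat(sprintf(
    "EvaluationMetrics: NMBF %.3f | r %.3f | r2 %.3f | NSD %.3f | n %d\n",
    object@nmbf, object@r, object@rSquared, object@nsd, object@nPairs))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %.2f..%.2f N, %.2f..%.2f E at %.2f deg (seed %d)\n",
              object@domain[1], object@domain[2], object@domain[3],
              object@domain[4], object@resolution, object@seed))
  cat(sprintf("  fire season months %s, peak %d; %d plumes\n",
              paste(range(object@fireSeason), collapse = "-"),
              object@peakMonth, nrow(object@plumes)))
})
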