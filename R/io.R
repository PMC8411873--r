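## Plain-text I/O: gridded products as long-format CSV with a JSON
## metadata sidecar, station series as CSV, configurations as YAML.

.units <- function(species)
  if (species == "O3") "ppbv" else "ug m-3"

#' Write a gridded field as long-format CSV with a metadata sidecar
#'
#' Columns lat, lon (and time for 3-D fields), value; a
#' \code{<path>.meta.json} sidecar records species, temporal resolution,
#' scenario, units and grid shape so the file round-trips losslessly.
#'
#' @param field a \code{\link{ConcentrationField}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeField <- function(field, path) {
  v <- fieldValues(field)
  lat <- gridLat(field); lon <- gridLon(field)
  if (length(dim(v)) == 3L) {
    nt <- dim(v)[3]
    df <- data.frame(lat = rep(lat, times = length(lon) * nt),
                     lon = rep(rep(lon, each = length(lat)), times = nt),
                     time = rep(seq_len(nt), each = length(lat) * length(lon)),
                     value = as.vector(v))
  } else {
    df <- data.frame(lat = rep(lat, times = length(lon)),
                     lon = rep(lon, each = length(lat)),
                     value = as.vector(v))
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(species = speciesTag(field), temporal = temporalTag(field),
               scenario = scenarioTag(field),
               units = .units(speciesTag(field)),
               nlat = length(lat), nlon = length(lon),
               ntime = if (length(dim(v)) == 3L) dim(v)[3] else 1L)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a gridded field written by \code{\link{writeField}}
#'
#' @param path CSV path (the \code{.meta.json} sidecar must sit next to
#'   it).
#' @return A \code{\link{ConcentrationField}}.
#' @export
readField <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  dims <- c(meta$nlat, meta$nlon,
            if (meta$ntime > 1L) meta$ntime else NULL)
  ord <- if (meta$ntime > 1L)
    order(df$time, match(df$lon, lon), match(df$lat, lat))
  else order(match(df$lon, lon), match(df$lat, lat))
  ConcentrationField(array(df$value[ord], dims), lat, lon, meta$species,
                     meta$temporal, meta$scenario)
}

#' Write station series to CSV
#'
#' One row per station-timestamp with columns station_id, lat, lon, date,
#' observed, model_all, model_nofire.
#'
#' @param stations list of \code{\link{StationSeries}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeStationCSV <- function(stations, path) {
  df <- do.call(rbind, lapply(stations, function(s) {
    d <- stationData(s)
    data.frame(station_id = stationId(s), lat = s@lat, lon = s@lon,
               date = d$time, observed = d$observed,
               model_all = d$model_all, model_nofire = d$model_nofire)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read station series written by \code{\link{writeStationCSV}}
#'
#' @param path CSV path.
#' @param species species tag to attach (default \code{"PM10"}).
#' @return A list of \code{\link{StationSeries}}.
#' @export
readStationCSV <- function(path, species = "PM10") {
  df <- utils::read.csv(path)
  lapply(split(df, df$station_id), function(d) {
    d <- d[order(d$date), ]
    StationSeries(d$station_id[1L], d$lat[1L], d$lon[1L], species,
                  data.frame(time = as.Date(d$date), observed = d$observed,
                             model_all = d$model_all,
                             model_nofire = d$model_nofire))
  })
}

#' Serialize a SyntheticConfig to YAML
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
  lst <- list(
    latRange = config@domain[1:2], lonRange = config@domain[3:4],
    resolution = config@resolution,
    fireSeason = config@fireSeason, peakMonth = config@peakMonth,
    plumes = as.list(config@plumes), background = config@background,
    pm10Ratio = config@pm10Ratio, ozone = config@ozone,
    population = config@population,
    baseline = as.list(config@baseline), imr = config@imr,
    noise = config@noise, seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a SyntheticConfig from YAML
#'
#' @param path YAML path written by \code{\link{writeConfig}}.
#' @return A \code{\link{SyntheticConfig}}.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  syntheticConfig(
    latRange = y$latRange, lonRange = y$lonRange,
    resolution = y$resolution, fireSeason = y$fireSeason,
    peakMonth = y$peakMonth,
    plumes = as.data.frame(y$plumes), background = y$background,
    pm10Ratio = y$pm10Ratio, ozone = y$ozone, population = y$population,
    baseline = as.data.frame(y$baseline), imr = y$imr, noise = y$noise,
    seed = y$seed)
}
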