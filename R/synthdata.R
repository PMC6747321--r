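#' Synthetic scenario specification
#'
#' Defines a full synthetic study day with controlled ground truth: a
#' smooth latent outdoor concentration field sampled hourly at fixed
#' stations, a minute-cadence indoor monitor signal, a beacon ping log
#' with dropout, and a templated activity trace.  Defaults emulate a
#' Madrid-like PM2.5 day: 24 stations in a city-sized bounding box, a
#' gaussian-covariance field with mean 10 ug/m3, variance 4 and
#' correlation length 0.05 degrees, an indoor signal of 8 ug/m3 baseline
#' with 3 ug/m3 diurnal amplitude peaking at 14:00, 60 s monitor cadence,
#' 30 s beacon cadence with 5% dropout.
#'
#' @param seed integer seed; the same seed reproduces every stream
#'   byte-identically.
#' @param n_stations number of outdoor stations.
#' @param hours number of hourly field realizations (from midnight).
#' @param day calendar day of the scenario (`"YYYY-mm-dd"`).
#' @param bbox named vector `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param field list: `mean`, `variance`, `corr_length` (degrees),
#'   `model` (variogram shape), `nugget`.
#' @param indoor list: `base`, `amplitude` (ug/m3), `noise_sd`,
#'   `cadence_s`, `peak_minute` (minute of day of the diurnal maximum).
#' @param beacon list: `cadence_s`, `dropout` (per-ping i.i.d. drop
#'   probability).
#' @param trace_template data frame of segment offsets (`start_s`,
#'   `end_s` seconds from midnight, `lat`, `lon`, `activity`); default is
#'   the bundled example day's shape.
#' @param windows occupancy windows (data frame `start`, `end` POSIXct or
#'   offsets `start_s`, `end_s`); default mirrors the example day's seven
#'   workplace visits.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1, n_stations = 24, hours = 24,
                          day = "2017-03-24",
                          bbox = c(lon_min = -3.83, lon_max = -3.58,
                                   lat_min = 40.33, lat_max = 40.52),
                          field = list(), indoor = list(), beacon = list(),
                          trace_template = NULL, windows = NULL) {
  field <- modifyList(list(mean = 10, variance = 4, corr_length = 0.05,
                           model = "gaussian", nugget = 0), field)
  indoor <- modifyList(list(base = 8, amplitude = 3, noise_sd = 1,
                            cadence_s = 60, peak_minute = 14 * 60), indoor)
  beacon <- modifyList(list(cadence_s = 30, dropout = 0.05), beacon)
  stopifnot(field$variance >= 0, field$nugget >= 0, field$corr_length > 0,
            indoor$noise_sd >= 0, indoor$cadence_s > 0, beacon$cadence_s > 0,
            beacon$dropout >= 0, beacon$dropout < 1, n_stations >= 2,
            hours >= 1)
  day0 <- as.POSIXct(day, tz = "UTC")
  if (is.null(trace_template)) trace_template <- default_trace_template()
  if (is.null(windows)) windows <- default_occupancy_windows()
  if (!is.null(windows$start_s)) {
    windows <- data.frame(start = day0 + windows$start_s,
                          end = day0 + windows$end_s)
  }
  windows <- windows[order(windows$start), , drop = FALSE]
  if (nrow(windows) > 1 &&
      any(windows$start[-1] < windows$end[-nrow(windows)]))
    stop("occupancy windows overlap")
  structure(list(seed = as.integer(seed), n_stations = n_stations,
                 hours = hours, day = day0, bbox = bbox, field = field,
                 indoor = indoor, beacon = beacon,
                 trace_template = trace_template, windows = windows),
            class = "scenario_spec")
}

# the example day's shape: morning at home, walk + transport to the
# workplace, afternoon there, transport back, evening walks and rest
default_trace_template <- function() {
  hms <- function(h, m, s = 0) h * 3600 + m * 60 + s
  data.frame(
    start_s = c(0, hms(11, 55, 37), hms(11, 59, 20), hms(12, 4, 30),
                hms(12, 23, 44), hms(19, 52, 0), hms(20, 8, 40),
                hms(21, 13, 7), hms(21, 21, 55), hms(22, 32, 59), hms(22, 42, 51)),
    end_s = c(hms(11, 55, 37), hms(11, 59, 20), hms(12, 4, 30), hms(12, 23, 44),
              hms(19, 52, 0), hms(20, 8, 40), hms(21, 13, 7), hms(21, 21, 55),
              hms(22, 32, 59), hms(22, 42, 51), 86400),
    lat = c(40.4612, 40.4592, 40.4571, 40.4486, 40.4400, 40.4506,
            40.4612, 40.4594, 40.4575, 40.4594, 40.4612),
    lon = c(-3.7093, -3.7106, -3.7118, -3.7006, -3.6894, -3.6994,
            -3.7093, -3.7105, -3.7117, -3.7105, -3.7093),
    activity = c("rest", "walk", "rest", "transport", "rest", "transport",
                 "rest", "walk", "rest", "walk", "rest"),
    stringsAsFactors = FALSE)
}

default_occupancy_windows <- function() {
  hms <- function(h, m, s = 0) h * 3600 + m * 60 + s
  data.frame(
    start_s = c(hms(13, 16, 0), hms(14, 37, 46), hms(14, 59, 0), hms(16, 9, 0),
                hms(17, 12, 0), hms(17, 56, 0), hms(18, 46, 0)),
    end_s = c(hms(14, 3, 0), hms(14, 44, 59), hms(15, 58, 0), hms(17, 0, 0),
              hms(17, 41, 0), hms(18, 32, 0), hms(19, 19, 0)))
}

# one Gaussian-random-field realization at the given points, by covariance
# factorization: Sigma(d) = (nugget + variance) - gamma(d)
grf_draw <- function(lon, lat, field, metric = "euclidean") {
  vg <- variogram_spec(field$model, nugget = field$nugget,
                       partial_sill = field$variance, range = field$corr_length)
  D <- dist_matrix(lon, lat, lon, lat, metric = metric)
  Sigma <- (field$nugget + field$variance) - semivariance(vg, D)
  L <- chol(Sigma + diag(1e-8, nrow(Sigma)))
  drop(field$mean + crossprod(L, rnorm(length(lon))))
}

#' Generate hourly outdoor station readings (plus the latent field)
#'
#' Draws one Gaussian-random-field realization per hour, jointly at the
#' station sites and at any extra evaluation points, so the latent truth
#' is available exactly where later error measurement needs it.  Values
#' are truncated at zero (concentrations are non-negative), for readings
#' and truth alike.
#'
#' @param spec a [scenario_spec()].
#' @param eval_points optional data frame (`lon`, `lat`) of extra points
#'   at which the latent field is recorded.
#' @param pollutant pollutant code stamped on the readings.
#' @return list with `readings` (station CSV schema plus `hour`),
#'   `stations` (site coordinates) and `truth` (latent values at
#'   `eval_points` per hour; `NULL` when no points given).
#' @export
gen_outdoor <- function(spec, eval_points = NULL, pollutant = "PM2.5") {
  stopifnot(inherits(spec, "scenario_spec"))
  bb <- spec$bbox
  stations <- with_seed(spec$seed + 1L, data.frame(
    station_id = sprintf("st%02d", seq_len(spec$n_stations)),
    lon = runif(spec$n_stations, bb["lon_min"], bb["lon_max"]),
    lat = runif(spec$n_stations, bb["lat_min"], bb["lat_max"])))
  ep <- if (!is.null(eval_points))
    data.frame(lon = eval_points$lon, lat = eval_points$lat)
  all_lon <- c(stations$lon, ep$lon)
  all_lat <- c(stations$lat, ep$lat)
  ns <- nrow(stations)
  hours_ts <- spec$day + 3600 * (seq_len(spec$hours) - 1)
  draws <- with_seed(spec$seed + 2L,
    lapply(seq_len(spec$hours), function(h)
      pmax(grf_draw(all_lon, all_lat, spec$field), 0)))
  readings <- do.call(rbind, lapply(seq_len(spec$hours), function(h) {
    data.frame(station_id = stations$station_id,
               lon = stations$lon, lat = stations$lat,
               hour = hours_ts[h],
               datetime = format(hours_ts[h], "%Y-%m-%d %H:%M:%S"),
               pollutant = pollutant,
               value = draws[[h]][seq_len(ns)],
               stringsAsFactors = FALSE)
  }))
  truth <- if (!is.null(ep)) do.call(rbind, lapply(seq_len(spec$hours), function(h) {
    data.frame(lon = ep$lon, lat = ep$lat, hour = hours_ts[h],
               value = draws[[h]][ns + seq_len(nrow(ep))])
  }))
  list(readings = readings, stations = stations, truth = truth)
}

# deterministic diurnal component of the indoor signal, ug/m3, at minute-of-day m
indoor_signal <- function(indoor, m) {
  indoor$base + indoor$amplitude *
    sin(2 * pi * (m - (indoor$peak_minute - 360)) / 1440)
}

#' Closed-form time integral of the noise-free indoor signal
#'
#' Integrates the diurnal sinusoid between two instants, in
#' \eqn{\mu g/m^3 \cdot min}; the oracle against which the trapezoidal
#' aggregation of a noise-free generated stream can be checked.
#'
#' @param spec a [scenario_spec()].
#' @param from,to integration bounds (POSIXct).
#' @return integrated intensity.
#' @export
indoor_truth_sz <- function(spec, from, to) {
  ind <- spec$indoor
  m0 <- as.numeric(difftime(parse_ts(from), spec$day, units = "mins"))
  m1 <- as.numeric(difftime(parse_ts(to), spec$day, units = "mins"))
  w <- 2 * pi / 1440
  phase <- function(m) m - (ind$peak_minute - 360)
  ind$base * (m1 - m0) +
    ind$amplitude / w * (cos(w * phase(m0)) - cos(w * phase(m1)))
}

#' Generate the indoor monitor stream
#'
#' Sinusoid-plus-noise signal at fixed cadence over the scenario day, in
#' long form for PM2.5 (ug/m3), CO2 (ppm) and VOC (ppb); the secondary
#' species are scaled copies of the same diurnal shape with their own
#' noise.  Values truncate at zero.
#'
#' @param spec a [scenario_spec()].
#' @return long-form monitor data frame (`ts`, `pollutant`, `value`).
#' @export
gen_indoor <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ind <- spec$indoor
  ts <- seq(spec$day, spec$day + spec$hours * 3600 - 1, by = ind$cadence_s)
  m <- as.numeric(difftime(ts, spec$day, units = "mins"))
  base_sig <- indoor_signal(ind, m)
  with_seed(spec$seed + 3L, {
    pm25 <- pmax(base_sig + rnorm(length(ts), 0, ind$noise_sd), 0)
    co2 <- pmax(450 + 40 * (base_sig - ind$base) + rnorm(length(ts), 0, 10 * ind$noise_sd), 0)
    voc <- pmax(150 + 20 * (base_sig - ind$base) + rnorm(length(ts), 0, 5 * ind$noise_sd), 0)
    rbind(data.frame(ts = ts, pollutant = "PM2.5", value = pm25),
          data.frame(ts = ts, pollutant = "CO2", value = co2),
          data.frame(ts = ts, pollutant = "VOC", value = voc))
  })
}

#' Generate the beacon ping log
#'
#' Pings at the beacon cadence inside each occupancy window, with i.i.d.
#' dropout.  Consecutive windows are required to be separated by more than
#' the gap threshold so that segmentation recovers exactly one indoor
#' period per window when dropout is zero.
#'
#' @param spec a [scenario_spec()].
#' @param windows occupancy windows (default: the spec's).
#' @param gap_minutes segmentation gap threshold the silences must exceed.
#' @return data frame with `beacon_id`, `ts`, sorted.
#' @export
gen_pings <- function(spec, windows = NULL, gap_minutes = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  windows <- windows %||% spec$windows
  if (nrow(windows) > 1) {
    gaps <- minutes_between(windows$end[-nrow(windows)], windows$start[-1])
    if (any(gaps <= gap_minutes))
      warning("occupancy windows closer than the gap threshold will merge")
  }
  ts <- do.call(c, lapply(seq_len(nrow(windows)), function(i)
    seq(windows$start[i], windows$end[i], by = spec$beacon$cadence_s)))
  keep <- with_seed(spec$seed + 4L,
                    runif(length(ts)) >= spec$beacon$dropout)
  data.frame(beacon_id = "beacon01", ts = sort(ts[keep]))
}

#' Generate the activity trace from the scenario template
#'
#' @param spec a [scenario_spec()].
#' @return activity-segment data frame (see [load_trace()]).
#' @export
gen_trace <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tpl <- spec$trace_template
  data.frame(start = spec$day + tpl$start_s, end = spec$day + tpl$end_s,
             lat = tpl$lat, lon = tpl$lon, activity = tpl$activity,
             provenance = "tracked", stringsAsFactors = FALSE)
}

#' Generate a complete synthetic scenario
#'
#' Assembles all five input streams plus the latent ground truth at the
#' trace's representative locations.
#'
#' @param spec a [scenario_spec()].
#' @return list with `spec`, `outdoor` (readings), `stations`, `truth`,
#'   `indoor`, `pings`, `trace`, `windows`.
#' @export
gen_scenario <- function(spec) {
  trace <- gen_trace(spec)
  pts <- unique(trace[, c("lon", "lat")])
  od <- gen_outdoor(spec, eval_points = pts)
  list(spec = spec, outdoor = od$readings, stations = od$stations,
       truth = od$truth, indoor = gen_indoor(spec), pings = gen_pings(spec),
       trace = trace, windows = spec$windows)
}

#' Analytic total daily exposure of a scenario
#'
#' The ground-truth exposure implied by the latent scenario, independent of
#' the estimation pipeline: outdoor time (the trace minus the occupancy
#' windows) accumulates latent-field concentration x minutes at each
#' segment's location, and each occupancy window accumulates the
#' closed-form integral of the noise-free indoor sinusoid; both are
#' weighted by the activity's minute ventilation.
#'
#' @param scn output of [gen_scenario()].
#' @param ve a [ve_table()].
#' @return total exposure in micrograms.
#' @export
scenario_truth_exposure <- function(scn, ve = ve_table()) {
  spec <- scn$spec
  trace <- scn$trace
  win <- scn$windows
  truth_at <- function(lon, lat, hour) {
    i <- which(scn$truth$lon == lon & scn$truth$lat == lat &
                 scn$truth$hour == hour)
    if (!length(i)) stop("no latent truth at this location/hour")
    scn$truth$value[i[1]]
  }
  total <- 0
  for (i in seq_len(nrow(trace))) {
    seg <- trace[i, ]
    # subtract the occupancy windows from the segment
    cuts <- sort(unique(c(as.numeric(seg$start), as.numeric(seg$end),
                          as.numeric(win$start), as.numeric(win$end))))
    cuts <- cuts[cuts >= as.numeric(seg$start) & cuts <= as.numeric(seg$end)]
    for (j in seq_len(length(cuts) - 1)) {
      a <- as.POSIXct(cuts[j], origin = "1970-01-01", tz = "UTC")
      b <- as.POSIXct(cuts[j + 1], origin = "1970-01-01", tz = "UTC")
      mid <- cuts[j] / 2 + cuts[j + 1] / 2
      indoors <- any(as.numeric(win$start) <= mid & mid < as.numeric(win$end))
      vei <- lookup_ve(seg$activity, ve)
      if (indoors) {
        total <- total + vei * indoor_truth_sz(spec, a, b)
      } else {
        h <- floor_hour(a)
        while (h < b) {
          ov <- minutes_between(max(a, h), min(b, h + 3600))
          total <- total + vei * ov * truth_at(seg$lon, seg$lat, h)
          h <- h + 3600
        }
      }
    }
  }
  total
}

#' Write a scenario's five input streams to a directory
#'
#' Emits `outdoor.csv` (station readings), `indoor.csv` (wide monitor
#' form), `pings.csv`, `trace.csv` (tracking-app headers) and
#' `truth.json` (latent field values and generator parameters).
#'
#' @param scn output of [gen_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  od <- scn$outdoor[, c("station_id", "lon", "lat", "datetime", "pollutant", "value")]
  utils::write.csv(od, file.path(dir, "outdoor.csv"), row.names = FALSE, quote = FALSE)
  wide <- data.frame(datetime = format(unique(scn$indoor$ts), "%Y-%m-%d %H:%M:%S"))
  for (p in c("PM2.5", "CO2", "VOC")) {
    cn <- c(`PM2.5` = "pm25", CO2 = "co2", VOC = "voc")[[p]]
    sub <- scn$indoor[scn$indoor$pollutant == p, ]
    wide[[cn]] <- sub$value[match(wide$datetime, format(sub$ts, "%Y-%m-%d %H:%M:%S"))]
  }
  utils::write.csv(wide, file.path(dir, "indoor.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(beacon_id = scn$pings$beacon_id,
                              datetime = format(scn$pings$ts, "%Y-%m-%d %H:%M:%S")),
                   file.path(dir, "pings.csv"), row.names = FALSE, quote = FALSE)
  write_trace_csv(scn$trace, file.path(dir, "trace.csv"))
  truth <- list(seed = scn$spec$seed, field = scn$spec$field,
                indoor = scn$spec$indoor,
                truth = if (!is.null(scn$truth))
                  data.frame(lon = scn$truth$lon, lat = scn$truth$lat,
                             hour = format(scn$truth$hour, "%Y-%m-%d %H:%M:%S"),
                             value = scn$truth$value))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
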