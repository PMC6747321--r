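#' Minute-ventilation table
#'
#' Minute ventilation VE (m3 of air inhaled per minute) by activity type,
#' from published human inhalation rates.  Rest and transport share one
#' value because both involve minimal body movement.  The defaults cover
#' the activities of the bundled example day (rest/transport 0.00893,
#' walk 0.01326 m3/min); running and cycling values must be supplied by
#' the user when those activities occur.
#'
#' @param ve_rest_transport VE for `"rest"` and `"transport"` (m3/min).
#' @param ve_walk VE for `"walk"`.
#' @param ve_run VE for `"run"` (no default).
#' @param ve_cycle VE for `"cycle"` (no default).
#' @return object of class `ve_table`.
#' @export
ve_table <- function(ve_rest_transport = 0.00893, ve_walk = 0.01326,
                     ve_run = NA_real_, ve_cycle = NA_real_) {
  vals <- c(ve_rest_transport, ve_walk, ve_run, ve_cycle)
  if (any(!is.na(vals) & vals <= 0)) stop("minute ventilation values must be positive")
  structure(list(ve_rest_transport = ve_rest_transport, ve_walk = ve_walk,
                 ve_run = ve_run, ve_cycle = ve_cycle),
            class = "ve_table")
}

#' Look up the minute ventilation for an activity
#'
#' @param activity activity name (vectorized): `"rest"`, `"walk"`,
#'   `"run"`, `"cycle"` or `"transport"` (case-insensitive).
#' @param table a [ve_table()].
#' @return VE values (m3/min).
#' @export
lookup_ve <- function(activity, table = ve_table()) {
  stopifnot(inherits(table, "ve_table"))
  activity <- tolower(activity)
  bad <- setdiff(unique(activity), ACTIVITIES)
  if (length(bad)) stop("unknown activity type(s): ", paste(bad, collapse = ", "))
  ve <- unname(c(rest = table$ve_rest_transport, transport = table$ve_rest_transport,
                 walk = table$ve_walk, run = table$ve_run,
                 cycle = table$ve_cycle)[activity])
  if (anyNA(ve))
    stop("no minute-ventilation value configured for activity: ",
         paste(unique(activity[is.na(ve)]), collapse = ", "))
  ve
}

#' Exposure from integrated intensity and minute ventilation
#'
#' The personal exposure over a period is the time-integrated pollutant
#' intensity SZ (\eqn{\mu g/m^3 \cdot min}) times the minute ventilation
#' VE (\eqn{m^3/min}), yielding the inhaled mass in \eqn{\mu g}.
#'
#' @param sz integrated intensity, >= 0 (vectorized).
#' @param ve minute ventilation, > 0.
#' @return exposure in micrograms, full precision.
#' @export
compute_exposure <- function(sz, ve) {
  if (any(sz < 0)) stop("negative integrated intensity")
  if (any(ve <= 0)) stop("minute ventilation must be positive")
  sz * ve
}

#' Outdoor integrated intensity of an activity segment
#'
#' For each hour overlapped by the segment, looks up the concentration at
#' the segment's representative coordinates in that hour's pollution map
#' and accumulates concentration x overlap minutes.
#'
#' @param start,end segment bounds (POSIXct or parseable).
#' @param lon,lat segment coordinates.
#' @param maps named list of `pollution_map` objects keyed by hour
#'   (`"YYYY-mm-dd HH:00:00"`), or an unnamed list of hour-stamped maps.
#' @return integrated intensity in \eqn{\mu g/m^3 \cdot min}.
#' @export
outdoor_sz <- function(start, end, lon, lat, maps) {
  start <- parse_ts(start); end <- parse_ts(end)
  stopifnot(end >= start)
  maps <- map_set(maps)
  sz <- 0
  h <- floor_hour(start)
  while (h < end) {
    h_end <- h + 3600
    key <- hour_key(h)
    if (is.null(maps[[key]]))
      stop("no pollution map covers hour ", key)
    overlap <- minutes_between(max(start, h), min(end, h_end))
    sz <- sz + map_lookup(maps[[key]], lon, lat) * overlap
    h <- h_end
  }
  sz
}

#' Integrate indoor periods and the outdoor timeline into exposure records
#'
#' Re-partitions the gap-filled activity trace so that every indoor period
#' becomes one or more indoor records (split at trace-segment boundaries so
#' each piece inherits a single activity; intensity re-integrated from the
#' period's monitor samples over the piece) and the remaining time becomes
#' outdoor records whose intensity comes from the hourly pollution maps at
#' the enclosing segment's coordinates.  Every record gets the
#' activity-specific minute ventilation and `exposure = sz * ve`.  The
#' output records are sorted, non-overlapping and tile the trace exactly.
#'
#' @param trace activity segments (gap-filled with [fill_rest_gaps()]; if
#'   the trace does not tile its day it is gap-filled here).
#' @param indoor_periods list of `indoor_period` objects from
#'   [build_indoor_periods()] (may be empty for an outdoor-only run).
#' @param maps hourly pollution maps (see [outdoor_sz()]).
#' @param ve a [ve_table()].
#' @param pollutant pollutant taken from the indoor samples
#'   (default `"PM2.5"`, the species common to indoor and outdoor sources).
#' @return data frame of exposure records: `start`, `end`, `lat`, `lon`,
#'   `sz`, `environment`, `activity`, `ve`, `exposure`, `sz_source`
#'   (`"monitor"` or `"map"`).
#' @export
integrate_exposure <- function(trace, indoor_periods = list(), maps,
                               ve = ve_table(), pollutant = "PM2.5") {
  if (!nrow(trace)) stop("integrate_exposure(): empty trace")
  covered <- all(trace$start[-1] == trace$end[-nrow(trace)])
  if (!covered) trace <- fill_rest_gaps(trace)
  t0 <- trace$start[1]; t1 <- trace$end[nrow(trace)]

  p_start <- lapply(indoor_periods, `[[`, "start")
  p_end <- lapply(indoor_periods, `[[`, "end")
  for (i in seq_along(indoor_periods)) {
    if (p_start[[i]] < t0 || p_end[[i]] > t1)
      stop("indoor period ", format(p_start[[i]]), " .. ", format(p_end[[i]]),
           " lies outside the trace coverage ", format(t0), " .. ", format(t1))
  }

  cuts <- sort(unique(c(as.numeric(trace$start), as.numeric(trace$end),
                        vapply(p_start, as.numeric, numeric(1)),
                        vapply(p_end, as.numeric, numeric(1)))))
  cuts <- cuts[cuts >= as.numeric(t0) & cuts <= as.numeric(t1)]

  recs <- list()
  for (i in seq_len(length(cuts) - 1)) {
    a <- as.POSIXct(cuts[i], origin = "1970-01-01", tz = "UTC")
    b <- as.POSIXct(cuts[i + 1], origin = "1970-01-01", tz = "UTC")
    if (b <= a) next
    mid <- as.numeric(a) / 2 + as.numeric(b) / 2
    seg <- which(as.numeric(trace$start) <= mid & mid < as.numeric(trace$end))[1]
    per <- which(vapply(seq_along(indoor_periods), function(j)
      as.numeric(p_start[[j]]) <= mid && mid < as.numeric(p_end[[j]]), logical(1)))[1]
    if (!is.na(per)) {
      smp <- indoor_periods[[per]]$samples
      smp <- smp[smp$pollutant == pollutant, , drop = FALSE]
      if (!nrow(smp))
        stop("indoor period has no ", pollutant, " samples")
      sz <- aggregate_sz_window(smp$ts, smp$value, a, b)
      env <- "indoor"; src <- "monitor"
    } else {
      sz <- outdoor_sz(a, b, trace$lon[seg], trace$lat[seg], maps)
      env <- "outdoor"; src <- "map"
    }
    act <- trace$activity[seg]
    v <- lookup_ve(act, ve)
    recs[[length(recs) + 1]] <- data.frame(
      start = a, end = b, lat = trace$lat[seg], lon = trace$lon[seg],
      sz = sz, environment = env, activity = act, ve = v,
      exposure = compute_exposure(sz, v), sz_source = src,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Summarise exposure records
#'
#' Three summary modes mirroring the standard reporting views:
#' `"activity"` groups by activity type, `"environment_location"` by
#' (environment, latitude, longitude, activity), each reporting total
#' exposure (\eqn{\mu g}), total duration (minutes) and the percentage of
#' the tiled interval; `"time_series"` re-bins exposure into fixed bins
#' (default 1 minute), allocating each record's exposure proportionally to
#' its overlap with the bin.  All modes conserve the grand total exposure.
#'
#' @param records exposure records from [integrate_exposure()].
#' @param by summary mode.
#' @param bin bin width in minutes (`"time_series"` mode).
#' @return summary data frame.
#' @export
summarize_exposure <- function(records,
                               by = c("activity", "environment_location",
                                      "time_series"),
                               bin = 1) {
  by <- match.arg(by)
  dur <- minutes_between(records$start, records$end)
  total_dur <- sum(dur)
  if (by %in% c("activity", "environment_location")) {
    key <- if (by == "activity") records$activity
           else paste(records$environment, records$lat, records$lon,
                      records$activity, sep = "|")
    ids <- !duplicated(key)
    out <- data.frame(key = key[ids], stringsAsFactors = FALSE)
    if (by == "environment_location") {
      out$environment <- records$environment[ids]
      out$lat <- records$lat[ids]
      out$lon <- records$lon[ids]
    }
    out$activity <- records$activity[ids]
    out$exposure <- vapply(out$key, function(k) sum(records$exposure[key == k]), numeric(1))
    out$minutes <- vapply(out$key, function(k) sum(dur[key == k]), numeric(1))
    out$time_pct <- 100 * out$minutes / total_dur
    out$key <- NULL
    rownames(out) <- NULL
    return(out)
  }
  # time series: fixed bins spanning the records
  t0 <- min(as.numeric(records$start)); t1 <- max(as.numeric(records$end))
  edges <- seq(t0, t1, by = bin * 60)
  if (edges[length(edges)] < t1) edges <- c(edges, t1)
  n <- length(edges) - 1
  expo <- numeric(n)
  rs <- as.numeric(records$start); re <- as.numeric(records$end)
  for (i in seq_len(nrow(records))) {
    if (re[i] <= rs[i]) next
    j1 <- findInterval(rs[i], edges, rightmost.closed = TRUE)
    j2 <- findInterval(re[i], edges, left.open = TRUE, rightmost.closed = TRUE)
    for (j in j1:j2) {
      ov <- max(0, min(re[i], edges[j + 1]) - max(rs[i], edges[j]))
      expo[j] <- expo[j] + records$exposure[i] * ov / (re[i] - rs[i])
    }
  }
  data.frame(
    bin_start = as.POSIXct(edges[-length(edges)], origin = "1970-01-01", tz = "UTC"),
    bin_end = as.POSIXct(edges[-1], origin = "1970-01-01", tz = "UTC"),
    exposure = expo)
}

#' Write exposure records in the integrated-exposure table layout
#'
#' Columns `Start`, `End`, `Latitude`, `Longitude`, `PM2.5` (the
#' integrated intensity, \eqn{\mu g/m^3 \cdot min}), `Environment`,
#' `Activity`, `VE`, `Exposure`, with minute-resolution timestamps and
#' plain decimal number formatting.
#'
#' @param records exposure records (the `sz` column supplies the
#'   intensity column).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(records, path) {
  lines <- c("Start,End,Latitude,Longitude,PM2.5,Environment,Activity,VE,Exposure",
             sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s",
                     format(records$start, "%Y-%m-%d %H:%M"),
                     format(records$end, "%Y-%m-%d %H:%M"),
                     num_str(records$lat), num_str(records$lon),
                     num_str(records$sz),
                     capitalize(records$environment),
                     capitalize(records$activity),
                     num_str(records$ve), num_str(records$exposure)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an integrated-exposure CSV (the layout written by
#' [write_exposure_csv()])
#'
#' @param path CSV path.
#' @return exposure-records data frame (lower-case environment/activity).
#' @export
read_exposure_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(start = parse_ts(df$Start), end = parse_ts(df$End),
             lat = df$Latitude, lon = df$Longitude, sz = df[["PM2.5"]],
             environment = tolower(df$Environment),
             activity = tolower(df$Activity),
             ve = df$VE, exposure = df$Exposure, stringsAsFactors = FALSE)
}
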