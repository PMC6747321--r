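#' Segment beacon pings into indoor periods by a maximum-gap rule
#'
#' An individual is considered continuously indoors while consecutive
#' beacon pings are no more than `gap_minutes` apart; a gap *strictly*
#' longer than the threshold closes the current period and the next ping
#' opens a new one.  A gap of exactly the threshold does not split.
#'
#' @param ts ping timestamps (POSIXct or parseable strings); sorted
#'   internally.
#' @param gap_minutes maximum allowed inter-ping gap, in minutes
#'   (default 10).
#' @return list of sorted POSIXct vectors, one per indoor period (a lone
#'   ping yields a zero-length period with `start == end`).
#' @export
segment_periods <- function(ts, gap_minutes = 10) {
  ts <- sort(parse_ts(ts))
  if (!length(ts)) return(list())
  gaps <- diff(as.numeric(ts)) / 60
  run <- cumsum(c(0, gaps > gap_minutes))
  unname(split(ts, run))
}

#' Match a timestamp to the nearest monitor reading
#'
#' Returns the index of the stream reading minimising the absolute time
#' difference; exact ties break toward the earlier reading.
#'
#' @param ts timestamps to match (vectorized).
#' @param stream_ts sorted monitor reading timestamps.
#' @return integer indices into `stream_ts`.
#' @export
match_nearest <- function(ts, stream_ts) {
  if (!length(stream_ts)) stop("match_nearest(): empty monitor stream")
  ts <- as.numeric(parse_ts(ts))
  st <- as.numeric(parse_ts(stream_ts))
  if (is.unsorted(st)) stop("match_nearest(): monitor stream is not sorted")
  lo <- pmin(pmax(findInterval(ts, st), 1), length(st))
  hi <- pmin(lo + 1, length(st))
  # earlier reading wins ties: strict '<' keeps lo unless hi is strictly closer
  ifelse(abs(st[hi] - ts) < abs(st[lo] - ts), hi, lo)
}

#' Time-integrated pollutant intensity of a sample sequence
#'
#' Trapezoidal rule over an ordered sequence of (time, concentration)
#' samples: \eqn{SZ = \sum_i \frac{1}{2}(Z_{i+1} + Z_i)(t_{i+1} - t_i)}
#' with time differences in minutes, giving \eqn{\mu g/m^3 \cdot min} for a
#' \eqn{\mu g/m^3} signal.  The rule is exact for piecewise-linear signals
#' and additive under splits at any interior sample.  A single sample has
#' no interval to integrate and yields 0.
#'
#' @param t sample times (POSIXct, or numeric minutes).
#' @param z concentrations at `t`.
#' @return the integrated intensity (scalar).
#' @export
aggregate_sz <- function(t, z) {
  stopifnot(length(t) == length(z), length(t) >= 1)
  tm <- if (inherits(t, "POSIXt")) as.numeric(t) / 60 else as.numeric(t)
  if (is.unsorted(tm)) stop("aggregate_sz(): samples are not time-ordered")
  if (length(tm) == 1) return(0)
  dt <- diff(tm)
  sum(0.5 * (z[-1] + z[-length(z)]) * dt)
}

# trapezoid integral restricted to the window [from, to], with linear
# interpolation at the window edges; the window is clamped to the sample
# span so that splitting at any instant is exactly additive
aggregate_sz_window <- function(t, z, from, to) {
  tm <- if (inherits(t, "POSIXt")) as.numeric(t) / 60 else as.numeric(t)
  a <- if (inherits(from, "POSIXt")) as.numeric(from) / 60 else as.numeric(from)
  b <- if (inherits(to, "POSIXt")) as.numeric(to) / 60 else as.numeric(to)
  a <- max(a, min(tm)); b <- min(b, max(tm))
  if (b <= a || length(tm) < 2) return(0)
  inner <- tm > a & tm < b
  tt <- c(a, tm[inner], b)
  zz <- c(approx(tm, z, xout = a, ties = "ordered")$y,
          z[inner],
          approx(tm, z, xout = b, ties = "ordered")$y)
  aggregate_sz(tt, zz)
}

#' Build indoor periods from a ping log and a monitor stream
#'
#' Pipeline of the indoor model: pings are segmented into periods by the
#' maximum-gap rule, each ping is matched to the closest monitor reading,
#' duplicate matches collapse to one sample per distinct monitor timestamp,
#' and each period's samples are integrated by the trapezoidal rule, per
#' pollutant.
#'
#' With several beacons (one per micro-environment) segmentation runs per
#' beacon id; the single-beacon case ignores the id.
#'
#' @param pings data frame with column `ts` (and optionally `beacon_id`),
#'   or a vector of timestamps.
#' @param stream monitor readings in long form: data frame with columns
#'   `ts`, `pollutant`, `value` (see [read_monitor_csv()]).
#' @param gap_minutes see [segment_periods()].
#' @return list of `indoor_period` objects: each has `start`, `end`,
#'   `beacon_id`, `samples` (long-form data frame of matched readings) and
#'   `sz` (named vector, one intensity per pollutant).
#' @export
build_indoor_periods <- function(pings, stream, gap_minutes = 10) {
  if (is.data.frame(pings)) {
    ts <- parse_ts(pings$ts)
    bid <- if (!is.null(pings$beacon_id)) as.character(pings$beacon_id)
           else rep("beacon", length(ts))
  } else {
    ts <- parse_ts(pings)
    bid <- rep("beacon", length(ts))
  }
  if (!length(ts)) return(list())
  if (is.null(stream) || nrow(stream) == 0)
    stop("build_indoor_periods(): empty monitor stream (pings ",
         format(min(ts)), " .. ", format(max(ts)), " have no readings to match)")
  stream <- stream[order(stream$ts), , drop = FALSE]
  pollutants <- unique(as.character(stream$pollutant))

  out <- list()
  for (b in unique(bid)) {
    runs <- segment_periods(ts[bid == b], gap_minutes = gap_minutes)
    for (run in runs) {
      samples <- do.call(rbind, lapply(pollutants, function(p) {
        sub <- stream[stream$pollutant == p, , drop = FALSE]
        if (!nrow(sub))
          stop("no ", p, " readings to match for period starting ", format(run[1]))
        idx <- unique(match_nearest(run, sub$ts))
        data.frame(ts = sub$ts[idx], pollutant = p, value = sub$value[idx])
      }))
      samples <- samples[order(samples$pollutant, samples$ts), , drop = FALSE]
      rownames(samples) <- NULL
      sz <- vapply(pollutants, function(p) {
        s <- samples[samples$pollutant == p, , drop = FALSE]
        aggregate_sz(s$ts, s$value)
      }, numeric(1))
      out[[length(out) + 1]] <- structure(
        list(start = run[1], end = run[length(run)], beacon_id = b,
             samples = samples, sz = sz),
        class = "indoor_period")
    }
  }
  out[order(vapply(out, function(p) as.numeric(p$start), numeric(1)))]
}

#' @export
print.indoor_period <- function(x, ...) {
  cat(sprintf("<indoor_period %s .. %s (%s): %s>\n",
              format(x$start, "%H:%M:%S"), format(x$end, "%H:%M:%S"), x$beacon_id,
              paste(sprintf("%s=%.4g", names(x$sz), x$sz), collapse = "  ")))
  invisible(x)
}

#' Read a beacon ping CSV
#'
#' Columns: `beacon_id`, `datetime` (ISO 8601); the log is sorted on
#' ingestion.
#'
#' @param path CSV path.
#' @return data frame with `beacon_id` and POSIXct `ts`.
#' @export
read_ping_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("datetime", "ts", "timestamp"), names(df))[1]
  if (is.na(tcol)) stop("ping CSV needs a datetime column")
  out <- data.frame(beacon_id = as.character(df$beacon_id %||% "beacon"),
                    ts = parse_ts(df[[tcol]]))
  out[order(out$ts), , drop = FALSE]
}

#' Read an indoor monitor CSV (wide or long form)
#'
#' Wide form: columns `datetime`, `pm25`, `co2`, `voc` (any subset of the
#' pollutant columns).  Long form: columns `datetime`, `pollutant`,
#' `value`.  Units follow the device conventions: \eqn{\mu g/m^3} for
#' PM2.5, ppm for CO2, ppb for VOC.
#'
#' @param path CSV path.
#' @return long-form data frame with `ts`, `pollutant`, `value`, sorted by
#'   time.
#' @export
read_monitor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("datetime", "ts", "timestamp"), names(df))[1]
  if (is.na(tcol)) stop("monitor CSV needs a datetime column")
  ts <- parse_ts(df[[tcol]])
  if (all(c("pollutant", "value") %in% names(df))) {
    out <- data.frame(ts = ts, pollutant = as.character(df$pollutant),
                      value = as.numeric(df$value))
  } else {
    wide <- c(pm25 = "PM2.5", co2 = "CO2", voc = "VOC")
    have <- intersect(names(wide), names(df))
    if (!length(have)) stop("monitor CSV has neither long nor wide pollutant columns")
    out <- do.call(rbind, lapply(have, function(cn)
      data.frame(ts = ts, pollutant = wide[[cn]], value = as.numeric(df[[cn]]))))
  }
  if (any(out$value < 0, na.rm = TRUE)) stop("negative monitor reading")
  out <- out[order(out$ts), , drop = FALSE]
  rownames(out) <- NULL
  out
}
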