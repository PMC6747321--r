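ACTIVITIES <- c("rest", "walk", "run", "cycle", "transport")

#' Load and validate an activity/location trace
#'
#' Accepts a data frame or CSV path with tracking-app columns
#' `Start Time`, `End Time`, `Latitude`, `Longitude`, `Activity` (header
#' spelling is normalised; lower-case `start`/`end`/`lat`/`lon`/`activity`
#' also accepted).  Rows are validated (coordinates in range, activity in
#' the closed enum, start before end), zero-duration rows are dropped with
#' a warning, overlapping rows are an error naming the offending rows, and
#' the result is sorted by start time.
#'
#' @param x data frame or CSV file path.
#' @return data frame of activity segments with columns `start`, `end`
#'   (POSIXct), `lat`, `lon`, `activity` (lower-case) and `provenance`
#'   (`"tracked"`).
#' @export
load_trace <- function(x) {
  df <- if (is.character(x)) read.csv(x, check.names = FALSE, stringsAsFactors = FALSE) else x
  if (!nrow(df)) {
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(),
                      activity = character(), provenance = character()))
  }
  nm <- tolower(gsub("[ _.]", "", names(df)))
  pick <- function(keys) {
    i <- which(nm %in% keys)[1]
    if (is.na(i)) stop("trace lacks column: ", keys[1])
    df[[i]]
  }
  out <- data.frame(
    start = parse_ts(pick(c("starttime", "start"))),
    end = parse_ts(pick(c("endtime", "end"))),
    lat = as.numeric(pick(c("latitude", "lat"))),
    lon = as.numeric(pick(c("longitude", "lon", "lng"))),
    activity = tolower(trimws(as.character(pick(c("activity"))))),
    provenance = "tracked", stringsAsFactors = FALSE)

  bad <- which(out$lat < -90 | out$lat > 90 | out$lon < -180 | out$lon > 180)
  if (length(bad)) stop("trace row(s) with out-of-range coordinates: ",
                        paste(bad, collapse = ", "))
  bad <- which(!out$activity %in% ACTIVITIES)
  if (length(bad)) stop("trace row(s) with unknown activity: ",
                        paste(sprintf("%d (%s)", bad, out$activity[bad]), collapse = ", "))
  bad <- which(out$end < out$start)
  if (length(bad)) stop("trace row(s) ending before they start: ",
                        paste(bad, collapse = ", "))
  zero <- which(out$end == out$start)
  if (length(zero)) {
    warning("dropping ", length(zero), " zero-duration trace row(s)")
    out <- out[-zero, , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1) {
    ov <- which(out$start[-1] < out$end[-nrow(out)])
    if (length(ov)) stop("overlapping trace rows: ",
                         paste(sprintf("%d/%d", ov, ov + 1), collapse = ", "))
  }
  out
}

#' Fill untracked periods with rest segments
#'
#' Tracking apps leave the timeline incomplete; any period lacking
#' activity data is assumed to be spent at rest.  Every gap between
#' consecutive segments, and between the day bounds and the first/last
#' segment, becomes a rest segment located at the preceding segment's
#' coordinates (the following segment's for a leading gap), flagged
#' `provenance = "gap_filled"`.  The result tiles
#' `[day_start, day_end)` exactly, and the operation is idempotent.
#'
#' @param segments trace as from [load_trace()].
#' @param day_start,day_end bounds to tile; default to midnight-to-midnight
#'   of the first segment's calendar day.
#' @return gap-filled, tiling trace.
#' @export
fill_rest_gaps <- function(segments, day_start = NULL, day_end = NULL) {
  if (!nrow(segments)) {
    if (is.null(day_start) || is.null(day_end))
      stop("empty trace: day bounds must be given explicitly")
    return(data.frame(start = parse_ts(day_start), end = parse_ts(day_end),
                      lat = NA_real_, lon = NA_real_, activity = "rest",
                      provenance = "gap_filled", stringsAsFactors = FALSE))
  }
  day0 <- as.POSIXct(format(segments$start[1], "%Y-%m-%d"), tz = "UTC")
  day_start <- parse_ts(day_start %||% day0)
  day_end <- parse_ts(day_end %||% (day0 + 86400))
  gap <- function(s, e, lat, lon) {
    data.frame(start = s, end = e, lat = lat, lon = lon,
               activity = "rest", provenance = "gap_filled",
               stringsAsFactors = FALSE)
  }
  pieces <- list()
  if (segments$start[1] > day_start)
    pieces[[1]] <- gap(day_start, segments$start[1], segments$lat[1], segments$lon[1])
  for (i in seq_len(nrow(segments))) {
    pieces[[length(pieces) + 1]] <- segments[i, , drop = FALSE]
    nxt <- if (i < nrow(segments)) segments$start[i + 1] else day_end
    if (nxt > segments$end[i])
      pieces[[length(pieces) + 1]] <- gap(segments$end[i], nxt,
                                          segments$lat[i], segments$lon[i])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a trace back to CSV in the tracking-app column layout
#'
#' @param segments trace data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(segments, path) {
  df <- data.frame(
    `Start Time` = format(segments$start, "%Y-%m-%d %H:%M:%S"),
    `End Time` = format(segments$end, "%Y-%m-%d %H:%M:%S"),
    Latitude = num_str(segments$lat),
    Longitude = num_str(segments$lon),
    Activity = capitalize(segments$activity),
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
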