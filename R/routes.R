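#' Construct a candidate route option
#'
#' A route is an ordered sequence of timestamped waypoints plus the travel
#' activity (transport by default).  Either supply `waypoints` for
#' evaluation against pollution maps with [route_sz()], or a precomputed
#' integrated intensity `sz` (\eqn{\mu g/m^3 \cdot min}).
#'
#' @param label route name (the baseline is typically `"Actual"`).
#' @param waypoints data frame with columns `lat`, `lon`, `time`
#'   (nondecreasing).
#' @param activity travel activity for the VE lookup.
#' @param sz optional precomputed integrated intensity.
#' @return object of class `route_option`.
#' @export
route_option <- function(label, waypoints = NULL, activity = "transport",
                         sz = NULL) {
  if (is.null(waypoints) && is.null(sz))
    stop("route_option() needs waypoints or a precomputed sz")
  if (!is.null(waypoints)) {
    waypoints$time <- parse_ts(waypoints$time)
    if (is.unsorted(as.numeric(waypoints$time)))
      stop("route waypoint timestamps must be nondecreasing")
  }
  structure(list(label = label, waypoints = waypoints,
                 activity = tolower(activity), sz = sz),
            class = "route_option")
}

#' Integrated intensity along a route
#'
#' Space-time trapezoid: for each leg between consecutive waypoints the
#' concentration is the mean of the map lookups at the two endpoints (each
#' at its own timestamp's hourly map), and the leg contributes
#' concentration x leg minutes.
#'
#' @param route a [route_option()] with waypoints, or a waypoints data
#'   frame (`lat`, `lon`, `time`).
#' @param maps hourly pollution maps (see [outdoor_sz()]).
#' @return total integrated intensity (\eqn{\mu g/m^3 \cdot min}).
#' @export
route_sz <- function(route, maps) {
  wp <- if (inherits(route, "route_option")) route$waypoints else route
  if (is.null(wp) || nrow(wp) < 2)
    stop("route_sz() needs at least two waypoints")
  wp$time <- parse_ts(wp$time)
  maps <- map_set(maps)
  conc <- vapply(seq_len(nrow(wp)), function(i) {
    key <- hour_key(wp$time[i])
    if (is.null(maps[[key]])) stop("no pollution map covers hour ", key)
    map_lookup(maps[[key]], wp$lon[i], wp$lat[i])
  }, numeric(1))
  dt <- diff(as.numeric(wp$time)) / 60
  sum(0.5 * (conc[-1] + conc[-length(conc)]) * dt)
}

#' Synthesise constant-speed waypoint timestamps
#'
#' Helper for route inputs that carry geometry but no per-point times:
#' timestamps are spread between `start` and `end` proportionally to the
#' cumulative along-route distance.
#'
#' @param waypoints data frame with `lat`, `lon`.
#' @param start,end traversal start and end times.
#' @param metric see [dist_matrix()].
#' @return the waypoints with a `time` column added.
#' @export
route_with_times <- function(waypoints, start, end, metric = "euclidean") {
  start <- parse_ts(start); end <- parse_ts(end)
  n <- nrow(waypoints)
  stopifnot(n >= 2, end > start)
  step <- vapply(seq_len(n - 1), function(i)
    dist_matrix(waypoints$lon[i], waypoints$lat[i],
                waypoints$lon[i + 1], waypoints$lat[i + 1], metric = metric)[1, 1],
    numeric(1))
  cum <- c(0, cumsum(step))
  frac <- if (cum[n] == 0) seq(0, 1, length.out = n) else cum / cum[n]
  waypoints$time <- start + frac * as.numeric(difftime(end, start, units = "secs"))
  waypoints
}

#' Rank candidate routes by predicted exposure
#'
#' Each option's total exposure is its integrated intensity times the
#' minute ventilation of its activity.  Options are returned in ascending
#' exposure order (ties keep input order) with the percentage difference
#' relative to the designated baseline:
#' `(baseline - option) / baseline * 100`, positive for routes better than
#' the baseline.
#'
#' @param options list of [route_option()]s.
#' @param maps hourly pollution maps; required for options without a
#'   precomputed `sz`.
#' @param ve a [ve_table()].
#' @param baseline label of the baseline route (default `"Actual"`).
#' @return data frame with columns `route`, `sz`, `exposure`,
#'   `pct_vs_baseline`, sorted by exposure.
#' @export
rank_routes <- function(options, maps = NULL, ve = ve_table(),
                        baseline = "Actual") {
  stopifnot(length(options) >= 1)
  labels <- vapply(options, `[[`, character(1), "label")
  if (!baseline %in% labels)
    stop("baseline route ", baseline, " not among the options")
  sz <- vapply(options, function(o) {
    if (!is.null(o$sz)) o$sz
    else {
      if (is.null(maps)) stop("route ", o$label, " has no sz and no maps were given")
      route_sz(o, maps)
    }
  }, numeric(1))
  vev <- vapply(options, function(o) lookup_ve(o$activity, ve), numeric(1))
  exposure <- compute_exposure(sz, vev)
  base_e <- exposure[match(baseline, labels)]
  out <- data.frame(route = labels, sz = sz, exposure = exposure,
                    pct_vs_baseline = (base_e - exposure) / base_e * 100,
                    stringsAsFactors = FALSE)
  out <- out[order(out$exposure), , drop = FALSE]  # stable: ties keep input order
  rownames(out) <- NULL
  out
}

#' Read route waypoints from CSV
#'
#' Columns: `label`, `seq`, `lat`, `lon`, `datetime`; one row per waypoint,
#' ordered by `seq` within each label.
#'
#' @param path CSV path.
#' @param activity travel activity assigned to every route.
#' @return list of [route_option()]s.
#' @export
read_routes_csv <- function(path, activity = "transport") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$label), function(sub) {
    sub <- sub[order(sub$seq), , drop = FALSE]
    route_option(sub$label[1],
                 waypoints = data.frame(lat = sub$lat, lon = sub$lon,
                                        time = parse_ts(sub$datetime)),
                 activity = activity)
  })
}

#' Write a route ranking as CSV (Route, PM2.5, Exposure, PctVsBaseline)
#'
#' @param ranking data frame from [rank_routes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_route_ranking_csv <- function(ranking, path) {
  df <- data.frame(Route = ranking$route,
                   `PM2.5` = num_str(ranking$sz),
                   Exposure = num_str(ranking$exposure),
                   PctVsBaseline = num_str(ranking$pct_vs_baseline),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
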