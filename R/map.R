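#' Build an hourly gridded pollution map
#'
#' Predicts the concentration on every node of a regular lon/lat grid with
#' the given interpolator specification (typically the winner of
#' [cv_select_model()]).  Grid nodes that coincide with a station reproduce
#' the station value when the technique is exact (the kriging family).
#'
#' @param readings station readings for a single hour and pollutant
#'   (`lon`, `lat`, `value`; optionally `hour`, `pollutant`).
#' @param spec an [interp_spec()], or a `cv_selection` (its `best` spec and
#'   RMSE are used).
#' @param secondary collocated secondary readings (co-kriging only).
#' @param n_lon,n_lat grid resolution (default 100 x 100 nodes).
#' @param pad fractional padding of the station bounding box (default 5%).
#' @param grid_lons,grid_lats explicit grid node coordinates, overriding
#'   `n_lon`/`n_lat`/`pad`.
#' @param metric see [dist_matrix()].
#' @return object of class `pollution_map`: list with `hour`, `pollutant`,
#'   `grid_lons`, `grid_lats`, `values` (matrix, rows indexed by longitude,
#'   columns by latitude), `spec` and `cv_rmse`.
#' @export
build_pollution_map <- function(readings, spec, secondary = NULL,
                                n_lon = 100, n_lat = 100, pad = 0.05,
                                grid_lons = NULL, grid_lats = NULL,
                                metric = "euclidean") {
  if (is.null(readings) || nrow(readings) == 0)
    stop("build_pollution_map(): no readings for this hour")
  hour <- if (!is.null(readings$hour)) floor_hour(parse_ts(readings$hour[1])) else NULL
  pollutant <- if (!is.null(readings$pollutant)) as.character(readings$pollutant[1]) else NA_character_
  if (!is.null(readings$hour) && length(unique(hour_key(parse_ts(readings$hour)))) > 1)
    stop("build_pollution_map(): readings span more than one hour")
  cv_rmse <- NA_real_
  if (inherits(spec, "cv_selection")) {
    cv_rmse <- spec$best_rmse
    spec <- spec$best
  }
  if (is.null(grid_lons) || is.null(grid_lats)) {
    rl <- range(readings$lon); rt <- range(readings$lat)
    el <- diff(rl) * pad; et <- diff(rt) * pad
    grid_lons <- grid_lons %||% seq(rl[1] - el, rl[2] + el, length.out = n_lon)
    grid_lats <- grid_lats %||% seq(rt[1] - et, rt[2] + et, length.out = n_lat)
  }
  nodes <- expand.grid(lon = grid_lons, lat = grid_lats)  # lon varies fastest
  vals <- predict_at(readings, nodes$lon, nodes$lat, spec,
                     secondary = secondary, metric = metric)
  if (any(!is.finite(vals)))
    stop("build_pollution_map(): non-finite interpolated values")
  structure(list(hour = hour, pollutant = pollutant,
                 grid_lons = grid_lons, grid_lats = grid_lats,
                 values = matrix(vals, nrow = length(grid_lons)),
                 spec = spec, cv_rmse = cv_rmse),
            class = "pollution_map")
}

#' @export
print.pollution_map <- function(x, ...) {
  cat(sprintf("<pollution_map %s %s: %d x %d nodes, [%.3g, %.3g] %s>\n",
              x$pollutant %||% "?",
              if (is.null(x$hour)) "" else format(x$hour, "%Y-%m-%d %H:00"),
              length(x$grid_lons), length(x$grid_lats),
              min(x$values), max(x$values), "ug/m3"))
  invisible(x)
}

#' @export
plot.pollution_map <- function(x, ..., stations = NULL) {
  image(x$grid_lons, x$grid_lats, x$values, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "longitude", ylab = "latitude",
        main = paste(x$pollutant, if (!is.null(x$hour)) format(x$hour, "%Y-%m-%d %H:00")),
        ...)
  if (!is.null(stations)) points(stations$lon, stations$lat, pch = 3)
  invisible(x)
}

#' Bilinear lookup in a pollution map
#'
#' Interpolates between the four grid nodes surrounding the query point.
#' Points outside the grid bounding box are clamped to the nearest edge
#' with a warning.
#'
#' @param map a `pollution_map`.
#' @param lon,lat query coordinates (vectorized).
#' @return concentrations at the query points.
#' @export
map_lookup <- function(map, lon, lat) {
  stopifnot(inherits(map, "pollution_map"))
  gx <- map$grid_lons; gy <- map$grid_lats
  if (any(lon < min(gx) | lon > max(gx) | lat < min(gy) | lat > max(gy))) {
    warning("map_lookup(): point outside grid; clamped to nearest edge")
    lon <- pmin(pmax(lon, min(gx)), max(gx))
    lat <- pmin(pmax(lat, min(gy)), max(gy))
  }
  i <- pmin(pmax(findInterval(lon, gx), 1), length(gx) - 1)
  j <- pmin(pmax(findInterval(lat, gy), 1), length(gy) - 1)
  x1 <- gx[i]; x2 <- gx[i + 1]; y1 <- gy[j]; y2 <- gy[j + 1]
  tx <- (lon - x1) / (x2 - x1)
  ty <- (lat - y1) / (y2 - y1)
  v11 <- map$values[cbind(i, j)]
  v21 <- map$values[cbind(i + 1, j)]
  v12 <- map$values[cbind(i, j + 1)]
  v22 <- map$values[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * v11 + tx * (1 - ty) * v21 +
    (1 - tx) * ty * v12 + tx * ty * v22
}

#' Read a station-readings CSV
#'
#' Expected columns: `station_id`, `lon`, `lat`, `datetime` (ISO 8601),
#' `pollutant`, `value`.  One file may hold many hours and pollutants;
#' timestamps are truncated to the hour and duplicate
#' (station, hour, pollutant) triples are an error.
#'
#' @param path CSV file path.
#' @return data frame with a POSIXct `hour` column added.
#' @export
read_station_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "datetime", "pollutant", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("station CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$value < 0, na.rm = TRUE)) stop("negative concentration in station CSV")
  df$hour <- floor_hour(parse_ts(df$datetime))
  key <- paste(df$station_id, df$hour, df$pollutant)
  if (anyDuplicated(key))
    stop("duplicate (station, hour, pollutant) rows in station CSV")
  df
}

#' Write a pollution map as flat CSV (lon, lat, value)
#'
#' A sidecar JSON file (same path with extension `.json`) records the
#' hour, pollutant, interpolator specification and cross-validation RMSE.
#'
#' @param map a `pollution_map`.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path, sidecar = TRUE) {
  g <- expand.grid(lon = map$grid_lons, lat = map$grid_lats)
  g$value <- as.vector(map$values)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  if (sidecar) write_map_meta(map, sub("\\.csv$", ".json", path))
  invisible(path)
}

write_map_meta <- function(map, path) {
  spec <- map$spec
  meta <- list(hour = if (!is.null(map$hour)) format(map$hour, "%Y-%m-%d %H:00:00"),
               pollutant = map$pollutant,
               technique = spec$technique,
               idp = spec$idp, beta = spec$beta,
               variogram = if (!is.null(spec$variogram)) unclass(spec$variogram),
               cv_rmse = map$cv_rmse)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a pollution map as a GeoJSON grid-cell FeatureCollection
#'
#' Each grid cell becomes a Polygon feature whose `value` property is the
#' concentration at the cell's lower-left node.
#'
#' @param map a `pollution_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_geojson <- function(map, path) {
  gx <- map$grid_lons; gy <- map$grid_lats
  feats <- list()
  for (j in seq_len(length(gy) - 1)) for (i in seq_len(length(gx) - 1)) {
    ring <- list(c(gx[i], gy[j]), c(gx[i + 1], gy[j]),
                 c(gx[i + 1], gy[j + 1]), c(gx[i], gy[j + 1]), c(gx[i], gy[j]))
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(value = map$values[i, j]))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build one map per hour from a multi-hour readings table
#'
#' Splits the readings by hour, runs [cv_select_model()] on each hourly
#' dataset and interpolates the winning model on a common grid covering all
#' stations.
#'
#' @param readings station readings (as from [read_station_csv()]) for one
#'   pollutant.
#' @param secondary optional multi-hour secondary readings (co-kriging).
#' @param ... passed to [cv_select_model()] (grids, k, seed, ...).
#' @param n_lon,n_lat,pad grid geometry, see [build_pollution_map()].
#' @param metric see [dist_matrix()].
#' @return named list of `pollution_map` objects keyed by
#'   `"YYYY-mm-dd HH:00:00"`.
#' @export
build_hourly_maps <- function(readings, secondary = NULL, ...,
                              n_lon = 100, n_lat = 100, pad = 0.05,
                              metric = "euclidean") {
  if (is.null(readings$hour)) readings$hour <- floor_hour(parse_ts(readings$datetime))
  rl <- range(readings$lon); rt <- range(readings$lat)
  el <- diff(rl) * pad; et <- diff(rt) * pad
  glon <- seq(rl[1] - el, rl[2] + el, length.out = n_lon)
  glat <- seq(rt[1] - et, rt[2] + et, length.out = n_lat)
  keys <- sort(unique(hour_key(readings$hour)))
  maps <- lapply(keys, function(kk) {
    sub <- readings[hour_key(readings$hour) == kk, , drop = FALSE]
    sec <- if (!is.null(secondary))
      secondary[hour_key(floor_hour(parse_ts(secondary$hour %||% secondary$datetime))) == kk, , drop = FALSE]
    sel <- cv_select_model(sub, secondary = sec, metric = metric, ...)
    build_pollution_map(sub, sel, secondary = sec,
                        grid_lons = glon, grid_lats = glat, metric = metric)
  })
  names(maps) <- keys
  maps
}

# normalise a list of maps into a named-by-hour list
map_set <- function(maps) {
  if (inherits(maps, "pollution_map")) maps <- list(maps)
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, function(m) {
      if (is.null(m$hour)) stop("pollution map without an hour stamp")
      hour_key(m$hour)
    }, character(1))
  }
  maps
}
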