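`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse timestamps from the formats used by the input files
#'
#' Accepts `POSIXct` input unchanged, otherwise tries ISO 8601
#' (`YYYY-mm-dd HH:MM:SS`, with or without seconds, `T` separator allowed)
#' and the US `m/d/Y` form that some tracking-app exports mix in.
#' All times are treated as timezone-naive local clock time and stored as
#' UTC internally so that arithmetic is DST-free.
#'
#' @param x character vector (or POSIXct, returned as-is).
#' @return POSIXct vector.
#' @export
parse_ts <- function(x) {
  if (inherits(x, "POSIXt")) return(as.POSIXct(x))
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
            "%m/%d/%Y %H:%M:%OS", "%Y-%m-%d %H:%M", "%m/%d/%Y %H:%M",
            "%Y-%m-%d")
  for (f in fmts) {
    idx <- which(is.na(out) & nzchar(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(x[idx], format = f, tz = "UTC")
  }
  bad <- is.na(out) & nzchar(x)
  if (any(bad))
    stop("unparseable timestamp(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

# truncate a timestamp to its hour boundary
floor_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
}

hour_key <- function(ts) format(floor_hour(ts), "%Y-%m-%d %H:00:00")

# elapsed minutes between two timestamps (vectorized)
minutes_between <- function(a, b) as.numeric(difftime(b, a, units = "mins"))

#' Pairwise distances between two sets of lon/lat points
#'
#' The default metric is planar Euclidean distance on raw decimal degrees:
#' the study areas this package targets are city-sized (Madrid spans less
#' than 0.3 degrees) and the default variogram range grid is expressed in
#' degree units.  `"haversine_km"` switches to great-circle kilometres.
#'
#' @param lon1,lat1 coordinates of the first point set.
#' @param lon2,lat2 coordinates of the second point set.
#' @param metric `"euclidean"` (degrees) or `"haversine_km"`.
#' @return numeric matrix, `length(lon1)` x `length(lon2)`.
#' @export
dist_matrix <- function(lon1, lat1, lon2, lat2,
                        metric = c("euclidean", "haversine_km")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    dx <- outer(lon1, lon2, "-")
    dy <- outer(lat1, lat2, "-")
    sqrt(dx * dx + dy * dy)
  } else {
    m <- matrix(0, length(lon1), length(lon2))
    for (j in seq_along(lon2)) {
      m[, j] <- geosphere::distHaversine(cbind(lon1, lat1),
                                         c(lon2[j], lat2[j])) / 1000
    }
    m
  }
}

# format numbers the way the exposure-table writer expects: plain decimal
# notation, no trailing zeros, up to 15 significant digits
num_str <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE, digits = 15)
  }, character(1))
}

capitalize <- function(x) {
  ifelse(nzchar(x), paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x))), x)
}

# run code with a private RNG stream; restores the caller's .Random.seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
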