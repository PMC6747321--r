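#' Interpolator specification
#'
#' Bundles a spatial interpolation technique with exactly the parameters it
#' needs: the IDW power exponent `idp`, a [variogram_spec()] for the kriging
#' family, the known-mean / secondary-weight parameter `beta` (simple
#' kriging: optional known mean of the field; co-kriging: scalar weight of
#' the mean-centred collocated secondary variable) and, for co-kriging, the
#' name of the secondary pollutant.
#'
#' @param technique `"IDW"`, `"simple_kriging"`, `"ordinary_kriging"` or
#'   `"cokriging"`.
#' @param idp IDW power exponent (> 0; IDW only).
#' @param variogram a [variogram_spec()] (kriging family only).
#' @param beta known mean (simple kriging, optional) or secondary weight
#'   (co-kriging, required).
#' @param secondary_pollutant pollutant code of the secondary variable
#'   (co-kriging only).
#' @return object of class `interp_spec`.
#' @export
interp_spec <- function(technique = c("IDW", "simple_kriging",
                                      "ordinary_kriging", "cokriging"),
                        idp = NULL, variogram = NULL, beta = NULL,
                        secondary_pollutant = NULL) {
  technique <- match.arg(technique)
  if (technique == "IDW") {
    if (is.null(idp) || idp <= 0) stop("IDW requires a positive power exponent idp")
    if (!is.null(variogram)) stop("IDW takes no variogram")
  } else {
    if (!inherits(variogram, "variogram_spec"))
      stop(technique, " requires a variogram_spec")
    if (!is.null(idp)) stop("idp is an IDW-only parameter")
    if (technique == "cokriging") {
      if (is.null(beta)) stop("cokriging requires beta")
      if (beta < 0) stop("cokriging beta must be non-negative")
    }
  }
  structure(list(technique = technique, idp = idp, variogram = variogram,
                 beta = beta, secondary_pollutant = secondary_pollutant),
            class = "interp_spec")
}

#' @export
print.interp_spec <- function(x, ...) {
  cat("<interp_spec:", x$technique)
  if (!is.null(x$idp)) cat("  idp=", x$idp, sep = "")
  if (!is.null(x$beta)) cat("  beta=", x$beta, sep = "")
  cat(">\n")
  if (!is.null(x$variogram)) print(x$variogram)
  invisible(x)
}

# tolerance (degrees) below which a prediction target is treated as lying
# exactly on a station
COINCIDENCE_TOL <- 1e-9

# average readings that share (numerically identical) coordinates
dedupe_stations <- function(readings, warn = TRUE) {
  key <- paste(readings$lon, readings$lat)
  if (!anyDuplicated(key)) return(readings)
  if (warn) warning("duplicate station coordinates: averaging collocated values")
  agg <- aggregate(readings["value"], by = list(key = key), FUN = mean)
  first <- readings[!duplicated(key), , drop = FALSE]
  first$value <- agg$value[match(paste(first$lon, first$lat), agg$key)]
  first
}

#' Inverse-distance-weighted prediction
#'
#' \eqn{\hat z_0 = \sum_i \lambda_i X_i} with weights proportional to
#' \eqn{d_i^{-idp}} and normalised to sum to one; the weight of a reading
#' depends solely on its distance to the prediction location.  A target
#' coinciding with a station returns that station's value.
#'
#' @param readings data frame with columns `lon`, `lat`, `value`.
#' @param lon,lat target coordinates (vectorized).
#' @param idp power exponent, > 0.
#' @param metric see [dist_matrix()].
#' @return numeric vector of predictions.
#' @export
idw_predict <- function(readings, lon, lat, idp = 2, metric = "euclidean") {
  if (is.null(readings) || nrow(readings) < 1)
    stop("idw_predict() needs at least one reading")
  stopifnot(idp > 0)
  readings <- dedupe_stations(readings)
  d <- dist_matrix(readings$lon, readings$lat, lon, lat, metric = metric)
  dd <- dist_matrix(readings$lon, readings$lat, lon, lat)  # degrees, for coincidence
  w <- d^(-idp)
  out <- numeric(length(lon))
  for (j in seq_along(lon)) {
    hit <- which(dd[, j] < COINCIDENCE_TOL)
    if (length(hit)) {
      out[j] <- readings$value[hit[1]]
    } else {
      out[j] <- sum(w[, j] * readings$value) / sum(w[, j])
    }
  }
  out
}

# Solve the kriging linear system.
#  ordinary: Gmat is the semivariance matrix among stations (diag 0), rhs the
#    station-to-target semivariances; a Lagrange row enforces sum(lambda) = 1.
#  simple: Gmat is the covariance matrix C(d) = c0 + c - gamma(d), rhs the
#    station-to-target covariances.
# A tiny diagonal regularization guards the near-singular systems that the
# default nugget grid (down to 1e-5) produces.
krige_solve <- function(Gmat, rhs, type = c("ordinary", "simple"),
                        reg = 1e-10) {
  type <- match.arg(type)
  n <- nrow(Gmat)
  rhs <- as.matrix(rhs)
  if (type == "ordinary") {
    A <- rbind(cbind(Gmat + diag(reg, n), 1), c(rep(1, n), 0))
    b <- rbind(rhs, rep(1, ncol(rhs)))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("ill-conditioned kriging system: ", conditionMessage(e), call. = FALSE))
    list(lambda = sol[seq_len(n), , drop = FALSE],
         mu = sol[n + 1, ])
  } else {
    A <- Gmat + diag(reg, n)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("ill-conditioned kriging system: ", conditionMessage(e), call. = FALSE))
    list(lambda = sol, mu = NULL)
  }
}

#' Kriging prediction (simple or ordinary)
#'
#' Weights come from the standard kriging linear system built from the
#' semivariance model: ordinary kriging works in semivariance form with a
#' Lagrange multiplier enforcing \eqn{\sum_i \lambda_i = 1} (constant but
#' unknown mean); simple kriging works in covariance form
#' \eqn{C(d) = c_0 + c - \gamma(d)} around a known mean, taken from
#' `spec$beta` when supplied and otherwise the sample mean of the readings.
#' Both are exact interpolators: a target on a station returns the station
#' value with zero kriging variance.
#'
#' @param readings data frame with columns `lon`, `lat`, `value`.
#' @param lon,lat target coordinates (vectorized).
#' @param spec an [interp_spec()] with technique `"simple_kriging"` or
#'   `"ordinary_kriging"`.
#' @param metric see [dist_matrix()].
#' @param details if `TRUE` the result carries the weight matrix
#'   (`weights`, stations x targets) and, for ordinary kriging, the
#'   Lagrange multipliers (`mu`).
#' @return list with `value` and `variance` vectors (kriging variance,
#'   clamped at zero within numerical tolerance); plus `weights`/`mu` when
#'   `details = TRUE`.
#' @export
kriging_predict <- function(readings, lon, lat, spec, metric = "euclidean",
                            details = FALSE) {
  stopifnot(inherits(spec, "interp_spec"),
            spec$technique %in% c("simple_kriging", "ordinary_kriging"))
  if (is.null(readings) || nrow(readings) < 2)
    stop("kriging_predict() needs at least two readings")
  readings <- dedupe_stations(readings)
  vg <- spec$variogram
  D <- dist_matrix(readings$lon, readings$lat, readings$lon, readings$lat,
                   metric = metric)
  d0 <- dist_matrix(readings$lon, readings$lat, lon, lat, metric = metric)
  dd0 <- dist_matrix(readings$lon, readings$lat, lon, lat)
  G <- semivariance(vg, D)
  g0 <- semivariance(vg, d0)
  sill <- vg$nugget + vg$partial_sill

  if (spec$technique == "ordinary_kriging") {
    sol <- krige_solve(G, g0, "ordinary")
    pred <- drop(crossprod(sol$lambda, readings$value))
    vari <- colSums(sol$lambda * g0) + sol$mu
  } else {
    m <- spec$beta %||% mean(readings$value)
    Cmat <- sill - G
    c0v <- sill - g0
    sol <- krige_solve(Cmat, c0v, "simple")
    pred <- m + drop(crossprod(sol$lambda, readings$value - m))
    vari <- sill - colSums(sol$lambda * c0v)
  }
  vari <- pmax(vari, 0)

  # exact-interpolation shortcut for targets sitting on a station
  for (j in seq_along(lon)) {
    hit <- which(dd0[, j] < COINCIDENCE_TOL)
    if (length(hit)) {
      pred[j] <- readings$value[hit[1]]
      vari[j] <- 0
      if (details) {
        sol$lambda[, j] <- 0
        sol$lambda[hit[1], j] <- 1
      }
    }
  }
  out <- list(value = pred, variance = vari)
  if (details) {
    out$weights <- sol$lambda
    out$mu <- sol$mu
  }
  out
}

#' Collocated co-kriging prediction
#'
#' Simplified collocated form \eqn{\hat z_0 = \sum_i \lambda_i X_i +
#' \beta \sum_i \lambda_i (t_i - \bar t)}: the primary weights
#' \eqn{\lambda_i} come from ordinary kriging of the primary variable and
#' the mean-centred secondary variable \eqn{t}, collocated at the primary
#' stations, enters through the same weights scaled by the scalar `beta`.
#' With `beta = 0`, or with a spatially constant secondary variable, the
#' prediction reduces to ordinary kriging.  If secondary readings are
#' missing the function falls back to ordinary kriging with a warning.
#'
#' @param readings primary readings (`lon`, `lat`, `value`).
#' @param secondary secondary readings collocated with the primary
#'   stations: data frame with `lon`, `lat`, `value` (matched to stations
#'   by coordinates, or by `station_id` when both frames carry it).
#' @param lon,lat target coordinates.
#' @param spec an [interp_spec()] with technique `"cokriging"`.
#' @param metric see [dist_matrix()].
#' @return numeric vector of predictions.
#' @export
cokriging_predict <- function(readings, secondary, lon, lat, spec,
                              metric = "euclidean") {
  stopifnot(inherits(spec, "interp_spec"), spec$technique == "cokriging")
  ok_spec <- interp_spec("ordinary_kriging", variogram = spec$variogram)
  readings <- dedupe_stations(readings)
  t_vals <- match_secondary(readings, secondary)
  if (is.null(t_vals)) {
    warning("no collocated secondary data; falling back to ordinary kriging")
    return(kriging_predict(readings, lon, lat, ok_spec, metric = metric)$value)
  }
  kp <- kriging_predict(readings, lon, lat, ok_spec, metric = metric,
                        details = TRUE)
  kp$value + spec$beta * drop(crossprod(kp$weights, t_vals - mean(t_vals)))
}

# align secondary readings with the primary stations; NULL when nothing matches
match_secondary <- function(readings, secondary) {
  if (is.null(secondary) || nrow(secondary) == 0) return(NULL)
  if (!is.null(readings$station_id) && !is.null(secondary$station_id)) {
    idx <- match(readings$station_id, secondary$station_id)
  } else {
    idx <- match(paste(readings$lon, readings$lat),
                 paste(secondary$lon, secondary$lat))
  }
  if (anyNA(idx)) return(NULL)
  secondary$value[idx]
}

#' One-call prediction for any interpolator specification
#'
#' Dispatches to [idw_predict()], [kriging_predict()] or
#' [cokriging_predict()] according to `spec$technique`.
#'
#' @inheritParams kriging_predict
#' @param secondary secondary readings (co-kriging only).
#' @return numeric vector of predicted concentrations.
#' @export
predict_at <- function(readings, lon, lat, spec, secondary = NULL,
                       metric = "euclidean") {
  switch(spec$technique,
    IDW = idw_predict(readings, lon, lat, idp = spec$idp, metric = metric),
    simple_kriging = ,
    ordinary_kriging = kriging_predict(readings, lon, lat, spec,
                                       metric = metric)$value,
    cokriging = cokriging_predict(readings, secondary, lon, lat, spec,
                                  metric = metric))
}
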