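#' Variogram model specification
#'
#' Describes a semivariance model \eqn{\gamma(d)} by its shape
#' (`circular`, `spherical`, `exponential` or `gaussian`), nugget
#' \eqn{c_0}, partial sill \eqn{c} and range \eqn{\alpha} (written `r`
#' for the exponential/gaussian shapes).  All four models satisfy
#' \eqn{\gamma(0) = 0}; the bounded models (circular, spherical) plateau
#' at \eqn{c_0 + c} beyond the range.
#'
#' @param model one of `"circular"`, `"spherical"`, `"exponential"`,
#'   `"gaussian"`.
#' @param nugget nugget variance \eqn{c_0 \ge 0}.
#' @param partial_sill partial sill \eqn{c \ge 0}.
#' @param range range parameter, strictly positive, in the units of the
#'   distance metric (degrees by default).
#' @return an object of class `variogram_spec`.
#' @export
#' @examples
#' v <- variogram_spec("spherical", nugget = 0.1, partial_sill = 1, range = 2)
#' semivariance(v, c(0, 1, 3))
variogram_spec <- function(model = c("gaussian", "circular", "exponential", "spherical"),
                           nugget = 0, partial_sill = 1, range = 1) {
  model <- match.arg(model)
  stopifnot(is.numeric(nugget), nugget >= 0,
            is.numeric(partial_sill), partial_sill >= 0,
            is.numeric(range), range > 0)
  structure(list(model = model, nugget = nugget,
                 partial_sill = partial_sill, range = range),
            class = "variogram_spec")
}

#' @export
print.variogram_spec <- function(x, ...) {
  cat(sprintf("<variogram: %s  nugget=%g  partial_sill=%g  range=%g>\n",
              x$model, x$nugget, x$partial_sill, x$range))
  invisible(x)
}

# unit-sill shape g(d) in [0, 1] for d > 0; the nugget and sill are applied
# on top by semivariance().  Kept separate so the cross-validation search can
# reuse one shape evaluation across the whole sill x nugget grid.
semivar_shape <- function(model, d, range) {
  g <- d  # allocate with same shape
  switch(model,
    circular = {
      u <- pmin(d / range, 1)
      g[] <- 1 - (2 / pi) * acos(u) + (2 * u / pi) * sqrt(pmax(1 - u * u, 0))
    },
    spherical = {
      u <- pmin(d / range, 1)
      g[] <- 1.5 * u - 0.5 * u^3
    },
    exponential = {
      g[] <- 1 - exp(-d / range)
    },
    gaussian = {
      g[] <- 1 - exp(-(d * d) / (range * range))
    },
    stop("unknown variogram model: ", model))
  g
}

#' Evaluate a semivariance model
#'
#' Piecewise model definitions: for the circular and spherical shapes the
#' semivariance rises from 0 at `d = 0` to the full sill \eqn{c_0 + c} at
#' `d = range` and stays there; the exponential and gaussian shapes approach
#' the sill asymptotically.  At `d = 0` every model returns exactly 0 (the
#' nugget appears as a jump for any `d > 0`).
#'
#' @param spec a [variogram_spec()].
#' @param d vector or matrix of non-negative distances.
#' @return semivariances, same shape as `d`.
#' @export
semivariance <- function(spec, d) {
  stopifnot(inherits(spec, "variogram_spec"))
  if (any(d < 0)) stop("negative distance passed to semivariance()")
  g <- spec$nugget + spec$partial_sill * semivar_shape(spec$model, d, spec$range)
  g[d == 0] <- 0
  g
}

#' Empirical (Matheron) variogram of a set of station readings
#'
#' Classical method-of-moments estimator: station pairs are binned by
#' separation distance and each bin reports half the mean squared value
#' difference.  Empty bins are omitted.
#'
#' @param readings data frame with columns `lon`, `lat`, `value`.
#' @param n_bins number of equal-width distance bins.
#' @param max_dist upper cut-off distance; defaults to half the maximum
#'   pairwise distance (a common rule to keep bins well populated).
#' @param metric distance metric, see [dist_matrix()].
#' @return data frame with columns `dist` (bin centre), `gamma` (mean
#'   semivariance) and `n_pairs`.
#' @export
empirical_variogram <- function(readings, n_bins = 15, max_dist = NULL,
                                metric = "euclidean") {
  if (nrow(readings) < 2)
    stop("empirical_variogram() needs at least 2 stations")
  D <- dist_matrix(readings$lon, readings$lat, readings$lon, readings$lat,
                   metric = metric)
  ut <- upper.tri(D)
  d <- D[ut]
  sv <- 0.5 * (outer(readings$value, readings$value, "-")^2)[ut]
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d <= max_dist & d > 0
  if (!any(keep)) keep <- d > 0  # degenerate layouts: keep everything
  d <- d[keep]; sv <- sv[keep]
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1), n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(dist = mean(d[bin == b]),
               gamma = mean(sv[bin == b]),
               n_pairs = sum(bin == b))
  }))
  rownames(out) <- NULL
  out
}
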