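# Independent oracles, written against the mathematical definitions with
# plain loops; deliberately share no code with the package internals.

# semivariance by direct formula transcription
oracle_gamma <- function(model, d, c0, c, rg) {
  if (d == 0) return(0)
  u <- d / rg
  shape <- switch(model,
    gaussian = 1 - exp(-u^2),
    exponential = 1 - exp(-u),
    spherical = if (u >= 1) 1 else 1.5 * u - 0.5 * u^3,
    circular = if (u >= 1) 1 else
      1 - (2 / pi) * acos(u) + (2 * u / pi) * sqrt(1 - u^2))
  c0 + c * shape
}

# dense ordinary-kriging solve: semivariance system with a Lagrange row.
# The 1e-10 diagonal regularization is part of the method definition.
oracle_ok <- function(lon, lat, value, tlon, tlat, model, c0, c, rg) {
  n <- length(lon)
  A <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2)
    A[i, j] <- oracle_gamma(model, d, c0, c, rg)
  }
  diag(A)[1:n] <- diag(A)[1:n] + 1e-10
  A[n + 1, 1:n] <- 1
  A[1:n, n + 1] <- 1
  b <- numeric(n + 1)
  for (i in 1:n)
    b[i] <- oracle_gamma(model, sqrt((lon[i] - tlon)^2 + (lat[i] - tlat)^2),
                         c0, c, rg)
  b[n + 1] <- 1
  sol <- solve(A, b)
  list(lambda = sol[1:n], mu = sol[n + 1],
       pred = sum(sol[1:n] * value))
}

# dense simple-kriging solve in covariance form around a known mean
oracle_sk <- function(lon, lat, value, tlon, tlat, model, c0, c, rg, m) {
  n <- length(lon)
  sill <- c0 + c
  A <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2)
    A[i, j] <- sill - oracle_gamma(model, d, c0, c, rg)
  }
  diag(A) <- diag(A) + 1e-10
  b <- numeric(n)
  for (i in 1:n)
    b[i] <- sill - oracle_gamma(model, sqrt((lon[i] - tlon)^2 + (lat[i] - tlat)^2),
                                c0, c, rg)
  lam <- solve(A, b)
  list(lambda = lam, pred = m + sum(lam * (value - m)))
}

# brute-force nearest-timestamp scan, earlier reading on ties
oracle_nearest <- function(ts, stream_ts) {
  ts <- as.numeric(ts); stream_ts <- as.numeric(stream_ts)
  vapply(ts, function(x) {
    d <- abs(stream_ts - x)
    which(d == min(d))[1]
  }, integer(1))
}

# random station layout with a smooth latent surface for interpolator tests
random_readings <- function(n, seed) {
  set.seed(seed)
  data.frame(lon = runif(n, -3.8, -3.6), lat = runif(n, 40.35, 40.5),
             value = runif(n, 5, 15))
}
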