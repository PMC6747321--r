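gauss_spec <- function(c0 = 1e-5, c = 1, r = 1, technique = "ordinary_kriging") {
  interp_spec(technique, variogram = variogram_spec("gaussian", c0, c, r))
}

test_that("IDW worked examples: single station, symmetry, hand-computed weights", {
  one <- data.frame(lon = 0, lat = 0, value = 7)
  expect_equal(idw_predict(one, 3, 4), 7)
  two <- data.frame(lon = c(0, 1), lat = c(0, 0), value = c(4, 8))
  expect_equal(idw_predict(two, 0.5, 0, idp = 2), 6)
  expect_equal(idw_predict(two, 0.5, 2, idp = 0.7), 6)
  # 3 stations, idp = 2, off-centre target: weights 1/d^2, hand-computed
  three <- data.frame(lon = c(0, 1, 0), lat = c(0, 0, 1), value = c(1, 5, 9))
  d2 <- c(0.2^2 + 0.1^2, 0.8^2 + 0.1^2, 0.2^2 + 0.9^2)
  w <- (1 / d2) / sum(1 / d2)
  expect_equal(idw_predict(three, 0.2, 0.1, idp = 2), sum(w * three$value))
  expect_error(idw_predict(three[0, ], 0, 0), "at least one")
})

test_that("IDW is bounded by the data range and exact on stations", {
  r <- random_readings(8, seed = 21)
  set.seed(22)
  for (idp in c(0.1, 0.5, 2, 5)) {
    p <- idw_predict(r, runif(20, -3.9, -3.5), runif(20, 40.3, 40.55), idp = idp)
    expect_true(all(p >= min(r$value) - 1e-12 & p <= max(r$value) + 1e-12))
  }
  expect_equal(idw_predict(r, r$lon, r$lat, idp = 2), r$value)
})

test_that("kriging is an exact interpolator with zero variance at stations", {
  r <- random_readings(6, seed = 31)
  for (tech in c("ordinary_kriging", "simple_kriging")) {
    for (m in c("gaussian", "spherical", "exponential", "circular")) {
      sp <- interp_spec(tech, variogram = variogram_spec(m, 0.05, 2, 0.1))
      kp <- kriging_predict(r, r$lon, r$lat, sp)
      expect_lt(max(abs(kp$value - r$value)), 1e-6)
      expect_equal(kp$variance, rep(0, 6))
    }
  }
})

test_that("a constant field is reproduced everywhere by both kriging forms", {
  r <- random_readings(5, seed = 32)
  r$value <- 11
  set.seed(33)
  tl <- runif(6, -3.8, -3.6); tt <- runif(6, 40.35, 40.5)
  expect_equal(kriging_predict(r, tl, tt, gauss_spec())$value, rep(11, 6))
  expect_equal(kriging_predict(r, tl, tt, gauss_spec(technique = "simple_kriging"))$value,
               rep(11, 6), tolerance = 1e-6)
})

test_that("kriging weights and predictions match the dense-solve oracle", {
  # includes the 4-station gaussian toy layout (c0 = 1e-5, c = 1, r = 1)
  cases <- list(
    list(n = 4, model = "gaussian", c0 = 1e-5, c = 1, r = 1),
    list(n = 5, model = "spherical", c0 = 0.1, c = 2, r = 0.15),
    list(n = 6, model = "exponential", c0 = 0.05, c = 1.5, r = 0.08),
    list(n = 6, model = "circular", c0 = 0.2, c = 0.8, r = 0.2))
  for (cs in cases) {
    r <- random_readings(cs$n, seed = 40 + cs$n)
    sp <- interp_spec("ordinary_kriging",
                      variogram = variogram_spec(cs$model, cs$c0, cs$c, cs$r))
    tgt <- c(-3.7, 40.42)
    kp <- kriging_predict(r, tgt[1], tgt[2], sp, details = TRUE)
    orc <- oracle_ok(r$lon, r$lat, r$value, tgt[1], tgt[2],
                     cs$model, cs$c0, cs$c, cs$r)
    expect_lt(max(abs(kp$weights[, 1] - orc$lambda)), 1e-8)
    expect_lt(abs(kp$value - orc$pred), 1e-8)

    sks <- interp_spec("simple_kriging",
                       variogram = variogram_spec(cs$model, cs$c0, cs$c, cs$r))
    skp <- kriging_predict(r, tgt[1], tgt[2], sks, details = TRUE)
    sko <- oracle_sk(r$lon, r$lat, r$value, tgt[1], tgt[2],
                     cs$model, cs$c0, cs$c, cs$r, mean(r$value))
    expect_lt(max(abs(skp$weights[, 1] - sko$lambda)), 1e-8)
    expect_lt(abs(skp$value - sko$pred), 1e-8)
  }
})

test_that("ordinary-kriging weights sum to one and predictions are translation-equivariant", {
  r <- random_readings(7, seed = 51)
  set.seed(52)
  tl <- runif(10, -3.85, -3.55); tt <- runif(10, 40.3, 40.55)
  sp <- gauss_spec(c0 = 0.01, r = 0.1)
  kp <- kriging_predict(r, tl, tt, sp, details = TRUE)
  expect_lt(max(abs(colSums(kp$weights) - 1)), 1e-8)
  shifted <- r; shifted$value <- r$value + 5
  expect_equal(kriging_predict(shifted, tl, tt, sp)$value, kp$value + 5)
  expect_equal(idw_predict(shifted, tl, tt, idp = 2),
               idw_predict(r, tl, tt, idp = 2) + 5)
})

test_that("simple kriging uses beta as a known-mean override", {
  r <- random_readings(5, seed = 61)
  sp0 <- interp_spec("simple_kriging", variogram = variogram_spec("gaussian", 0.01, 1, 0.1))
  spb <- interp_spec("simple_kriging", variogram = variogram_spec("gaussian", 0.01, 1, 0.1),
                     beta = 25)
  p0 <- kriging_predict(r, -3.7, 40.42, sp0, details = TRUE)
  pb <- kriging_predict(r, -3.7, 40.42, spb, details = TRUE)
  # same weights, mean shifted by (1 - sum(lambda)) * (beta - xbar)
  expect_equal(pb$weights, p0$weights)
  expect_equal(pb$value - p0$value,
               (1 - sum(p0$weights)) * (25 - mean(r$value)))
})

test_that("duplicate station coordinates are averaged with a warning", {
  r <- data.frame(lon = c(0, 0, 1), lat = c(0, 0, 0), value = c(2, 4, 6))
  expect_warning(p <- idw_predict(r, 0.5, 0, idp = 2), "duplicate")
  expect_equal(p, mean(c(3, 6)))
})

test_that("collocated co-kriging reduces to ordinary kriging for beta = 0 or constant secondary", {
  r <- random_readings(5, seed = 71)
  sec <- r; set.seed(72); sec$value <- r$value * 0.5 + rnorm(5)
  vg <- variogram_spec("gaussian", 0.01, 1, 0.1)
  ok <- interp_spec("ordinary_kriging", variogram = vg)
  tl <- c(-3.75, -3.65); tt <- c(40.4, 40.45)
  p_ok <- kriging_predict(r, tl, tt, ok)$value
  ck0 <- interp_spec("cokriging", variogram = vg, beta = 0)
  expect_equal(cokriging_predict(r, sec, tl, tt, ck0), p_ok)
  const <- r; const$value <- 42
  ck <- interp_spec("cokriging", variogram = vg, beta = 0.7)
  expect_equal(cokriging_predict(r, const, tl, tt, ck), p_ok)
})

test_that("co-kriging applies beta to the weighted mean-centred secondary", {
  r <- random_readings(4, seed = 73)
  sec <- r; set.seed(74); sec$value <- 2 * r$value + rnorm(4, 0, 0.1)
  vg <- variogram_spec("gaussian", 0.01, 1, 0.1)
  ck <- interp_spec("cokriging", variogram = vg, beta = 0.3)
  ok <- interp_spec("ordinary_kriging", variogram = vg)
  kp <- kriging_predict(r, -3.7, 40.42, ok, details = TRUE)
  expected <- kp$value + 0.3 * sum(kp$weights[, 1] * (sec$value - mean(sec$value)))
  expect_equal(cokriging_predict(r, sec, -3.7, 40.42, ck), unname(expected))
  # missing secondary falls back to ordinary kriging with a warning
  expect_warning(fb <- cokriging_predict(r, sec[1:2, ], -3.7, 40.42, ck), "falling back")
  expect_equal(fb, unname(kp$value))
})
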