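# a flat map whose lookup is a known constant everywhere, stamped per hour
flat_maps <- function(values_by_hour, day = "2017-03-24") {
  maps <- lapply(seq_along(values_by_hour), function(i) {
    r <- data.frame(lon = c(-3.8, -3.6), lat = c(40.35, 40.5),
                    value = values_by_hour[i],
                    hour = sprintf("%s %02d:00:00", day, i - 1),
                    pollutant = "PM2.5")
    build_pollution_map(r, interp_spec("IDW", idp = 2),
                        grid_lons = seq(-3.9, -3.5, 0.1),
                        grid_lats = seq(40.3, 40.55, 0.05))
  })
  names(maps) <- sprintf("%s %02d:00:00", day, seq_along(values_by_hour) - 1)
  maps
}

test_that("minute ventilation lookup follows the activity table", {
  vt <- ve_table()
  expect_equal(lookup_ve("walk", vt), 0.01326)
  expect_equal(lookup_ve("rest", vt), 0.00893)
  expect_equal(lookup_ve("transport", vt), lookup_ve("rest", vt))
  expect_equal(lookup_ve("Rest", vt), 0.00893)  # case-insensitive
  expect_error(lookup_ve("cycle", vt), "cycle")  # no default for cycling
  expect_equal(lookup_ve("cycle", ve_table(ve_cycle = 0.02)), 0.02)
  expect_error(lookup_ve("swim", vt), "unknown activity")
  expect_error(ve_table(ve_walk = -1), "positive")
})

test_that("exposure is the exact product of intensity and ventilation", {
  expect_equal(round(compute_exposure(5354.15601, 0.00893), 5), 47.81261)
  expect_equal(round(compute_exposure(13.9543, 0.01326), 5), 0.18503)
  expect_equal(compute_exposure(0, 0.5), 0)
  expect_error(compute_exposure(-1, 0.5), "negative")
  expect_error(compute_exposure(1, 0), "positive")
})

test_that("outdoor intensity accumulates concentration x overlap minutes per hour", {
  maps <- flat_maps(c(10, 20))
  expect_equal(outdoor_sz("2017-03-24 00:00:00", "2017-03-24 01:00:00",
                          -3.7, 40.43, maps), 600)
  expect_equal(outdoor_sz("2017-03-24 00:30:00", "2017-03-24 01:30:00",
                          -3.7, 40.43, maps), 10 * 30 + 20 * 30)
  # partial-hour overlaps at second resolution
  expect_equal(outdoor_sz("2017-03-24 00:59:30", "2017-03-24 01:00:30",
                          -3.7, 40.43, maps), 10 * 0.5 + 20 * 0.5)
  expect_error(outdoor_sz("2017-03-24 02:00:00", "2017-03-24 03:00:00",
                          -3.7, 40.43, maps), "02:00")
})

day_trace <- function() {
  load_trace(data.frame(
    start = c("2017-03-24 00:00:00", "2017-03-24 01:00:00"),
    end = c("2017-03-24 01:00:00", "2017-03-24 03:00:00"),
    lat = c(40.42, 40.46), lon = c(-3.72, -3.65),
    activity = c("rest", "walk")))
}

test_that("a trace with no indoor periods integrates to all-outdoor records", {
  maps <- flat_maps(c(10, 20, 30))
  rec <- integrate_exposure(day_trace(), list(), maps)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$environment == "outdoor"))
  expect_true(all(rec$sz_source == "map"))
  expect_equal(rec$sz, c(600, 20 * 60 + 30 * 60))
  expect_equal(rec$exposure, rec$sz * c(0.00893, 0.01326))
})

indoor_period_for <- function(from, to, value = 5) {
  stream <- data.frame(ts = parse_ts(from) + 60 * (0:round(minutes_between(parse_ts(from), parse_ts(to)))),
                       pollutant = "PM2.5", value = value)
  pings <- data.frame(ts = seq(parse_ts(from), parse_ts(to), by = 30))
  build_indoor_periods(pings, stream)[[1]]
}

test_that("an indoor period covering a whole segment flips it to monitor-based intensity", {
  maps <- flat_maps(c(10, 20, 30))
  per <- indoor_period_for("2017-03-24 00:00:00", "2017-03-24 01:00:00", value = 5)
  rec <- integrate_exposure(day_trace(), list(per), maps)
  expect_equal(rec$environment, c("indoor", "outdoor"))
  expect_equal(rec$sz_source, c("monitor", "map"))
  expect_equal(rec$sz[1], 5 * 60)
  expect_equal(rec$activity, c("rest", "walk"))
})

test_that("an indoor period straddling a segment boundary splits, inheriting each activity", {
  maps <- flat_maps(c(10, 20, 30))
  per <- indoor_period_for("2017-03-24 00:30:00", "2017-03-24 01:30:00", value = 8)
  rec <- integrate_exposure(day_trace(), list(per), maps)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$environment, c("outdoor", "indoor", "indoor", "outdoor"))
  expect_equal(rec$activity, c("rest", "rest", "walk", "walk"))
  expect_equal(rec$sz[2], 8 * 30)
  expect_equal(rec$sz[3], 8 * 30)
  # partition: the records tile the trace exactly
  expect_equal(sum(minutes_between(rec$start, rec$end)), 180)
  expect_true(all(rec$start[-1] == rec$end[-4]))
  # a period outside the trace is a coverage error
  far <- indoor_period_for("2017-03-24 05:00:00", "2017-03-24 06:00:00")
  expect_error(integrate_exposure(day_trace(), list(far), maps), "outside the trace")
})

test_that("doubling the fields and the indoor signal doubles every exposure", {
  maps1 <- flat_maps(c(10, 20, 30))
  maps2 <- flat_maps(2 * c(10, 20, 30))
  per1 <- indoor_period_for("2017-03-24 00:30:00", "2017-03-24 01:30:00", value = 8)
  per2 <- indoor_period_for("2017-03-24 00:30:00", "2017-03-24 01:30:00", value = 16)
  r1 <- integrate_exposure(day_trace(), list(per1), maps1)
  r2 <- integrate_exposure(day_trace(), list(per2), maps2)
  expect_equal(r2$exposure, 2 * r1$exposure)
})

test_that("summaries conserve total exposure across all modes", {
  maps <- flat_maps(c(10, 20, 30))
  per <- indoor_period_for("2017-03-24 00:30:00", "2017-03-24 01:30:00", value = 8)
  rec <- integrate_exposure(day_trace(), list(per), maps)
  total <- sum(rec$exposure)
  for (mode in c("activity", "environment_location")) {
    s <- summarize_exposure(rec, mode)
    expect_lt(abs(sum(s$exposure) - total), 1e-9)
    expect_equal(sum(s$time_pct), 100)
  }
  ts <- summarize_exposure(rec, "time_series", bin = 1)
  expect_lt(abs(sum(ts$exposure) - total), 1e-9)
  # a uniform single record spreads equally across bins
  one <- rec[1, ]
  u <- summarize_exposure(one, "time_series", bin = 5)
  expect_equal(u$exposure, rep(one$exposure / nrow(u), nrow(u)))
})

test_that("per-activity totals equal an independent column sum of the example table", {
  rec <- read_exposure_csv(pape_example("exposure_day.csv"))
  s <- summarize_exposure(rec, "activity")
  expect_setequal(s$activity, c("rest", "walk", "transport"))
  expect_equal(sum(s$exposure), sum(rec$exposure))
  for (a in s$activity) {
    expect_equal(s$exposure[s$activity == a],
                 sum(rec$exposure[rec$activity == a]))
  }
})

test_that("single-record summary owns 100% of the time", {
  rec <- data.frame(start = parse_ts("2017-03-24 08:00:00"),
                    end = parse_ts("2017-03-24 09:00:00"),
                    lat = 40.4, lon = -3.7, sz = 600, environment = "outdoor",
                    activity = "rest", ve = 0.00893, exposure = 600 * 0.00893)
  s <- summarize_exposure(rec, "activity")
  expect_equal(nrow(s), 1)
  expect_equal(s$time_pct, 100)
})
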