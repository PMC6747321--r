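D <- "2017-03-24 "

test_that("a gap strictly longer than the threshold starts a new indoor period", {
  # the documented boundary case: pings through 14:44:59, next at 14:59:00
  pings <- paste0(D, c("14:37:46", "14:40:00", "14:44:59", "14:59:00", "15:03:00"))
  runs <- segment_periods(pings)
  expect_length(runs, 2)
  expect_equal(format(runs[[1]][length(runs[[1]])], "%H:%M:%S"), "14:44:59")
  expect_equal(format(runs[[2]][1], "%H:%M:%S"), "14:59:00")
})

test_that("gap threshold boundary: exactly 10 min keeps the period, 10 min + 1 s splits", {
  keep <- segment_periods(paste0(D, c("10:00:00", "10:10:00")))
  expect_length(keep, 1)
  split <- segment_periods(paste0(D, c("10:00:00", "10:10:01")))
  expect_length(split, 2)
})

test_that("degenerate ping logs: empty list, single ping, dense hour", {
  expect_identical(segment_periods(character(0)), list())
  one <- segment_periods(paste0(D, "09:00:00"))
  expect_length(one, 1)
  expect_equal(one[[1]][1], one[[1]][length(one[[1]])])
  dense <- segment_periods(paste0(D, sprintf("09:%02d:00", 0:59)), gap_minutes = 10)
  expect_length(dense, 1)
})

test_that("nearest-timestamp matching takes the closest reading, earlier on ties", {
  st <- parse_ts(paste0(D, sprintf("10:%02d:00", 0:10)))
  expect_equal(match_nearest(paste0(D, "10:03:00"), st), 4)  # exact hit
  expect_equal(match_nearest(paste0(D, "10:03:30"), st), 4)  # midway: earlier wins
  expect_equal(match_nearest(paste0(D, "10:03:31"), st), 5)
  expect_error(match_nearest(paste0(D, "10:00:00"), parse_ts(character(0))), "empty")
})

test_that("nearest matching agrees with a brute-force scan and stays within half a cadence", {
  st <- parse_ts(paste0(D, "08:00:00")) + 60 * (0:120)
  set.seed(91)
  ts <- parse_ts(paste0(D, "08:00:00")) + runif(50, 0, 7200)
  idx <- match_nearest(ts, st)
  expect_equal(idx, oracle_nearest(ts, st))
  expect_true(all(abs(as.numeric(st[idx]) - as.numeric(ts)) <= 30))
})

test_that("trapezoidal aggregation: constants, the 0-10 ramp, and irregular linear signals", {
  expect_equal(aggregate_sz(c(0, 4, 10), c(5, 5, 5)), 50)   # c * T
  expect_equal(aggregate_sz(c(0, 10), c(0, 10)), 50)        # 1/2 * 10 * 10
  expect_equal(aggregate_sz(5, 3), 0)                        # single sample
  # trapezoid is exact for linear signals at arbitrary sample times
  t <- c(0, 0.7, 2.3, 5.1, 9)
  z <- 2 + 3 * t
  expect_equal(aggregate_sz(t, z), 2 * 9 + 3 * 81 / 2)
  expect_error(aggregate_sz(c(3, 1), c(1, 1)), "ordered")
})

test_that("aggregation is additive under splits and monotone in the signal", {
  set.seed(92)
  t <- cumsum(runif(20, 0.1, 3))
  z <- runif(20, 0, 12)
  total <- aggregate_sz(t, z)
  for (cut in c(2, 7, 19)) {
    expect_equal(aggregate_sz(t[1:cut], z[1:cut]) +
                   aggregate_sz(t[cut:20], z[cut:20]), total)
  }
  z2 <- z + runif(20, 0, 1)   # pointwise larger
  expect_gte(aggregate_sz(t, z2), total)
  # linear time-unit rescaling scales SZ linearly
  expect_equal(aggregate_sz(t * 60, z), total * 60)
})

test_that("windowed aggregation splits exactly and clamps to the sample span", {
  t <- c(0, 2, 5, 9); z <- c(1, 4, 2, 6)
  total <- aggregate_sz(t, z)
  for (cut in c(0.5, 2, 3.7, 8.99)) {
    expect_equal(pape:::aggregate_sz_window(t, z, 0, cut) +
                   pape:::aggregate_sz_window(t, z, cut, 9), total)
  }
  expect_equal(pape:::aggregate_sz_window(t, z, -5, 20), total)
  expect_equal(pape:::aggregate_sz_window(t, z, 10, 20), 0)
})

monitor_const <- function(value = 5, from = "13:00:00", n = 120, by = 60) {
  data.frame(ts = parse_ts(paste0(D, from)) + by * (0:(n - 1)),
             pollutant = "PM2.5", value = value)
}

test_that("indoor periods carry the aggregated intensity of matched readings", {
  pings <- parse_ts(paste0(D, "13:10:00")) + 30 * (0:20)  # 13:10:00..13:20:00
  per <- build_indoor_periods(data.frame(ts = pings), monitor_const(5))
  expect_length(per, 1)
  expect_equal(per[[1]]$sz[["PM2.5"]], 50)  # 5 ug/m3 x 10 min
  expect_equal(format(per[[1]]$start, "%H:%M:%S"), "13:10:00")
})

test_that("the split scenario yields two periods with no samples from the silent gap", {
  pings <- c(parse_ts(paste0(D, "14:37:46")) + 30 * (0:14),   # ..14:44:46
             parse_ts(paste0(D, "14:59:00")) + 30 * (0:10))
  stream <- monitor_const(4, from = "14:30:00", n = 60)
  per <- build_indoor_periods(data.frame(ts = pings), stream)
  expect_length(per, 2)
  gap_lo <- parse_ts(paste0(D, "14:45:30"))
  gap_hi <- parse_ts(paste0(D, "14:58:30"))
  for (p in per) {
    expect_true(all(p$samples$ts <= gap_lo | p$samples$ts >= gap_hi))
  }
  expect_error(build_indoor_periods(data.frame(ts = pings), stream[0, ]),
               "empty monitor stream")
})

test_that("multi-beacon logs segment per beacon id", {
  pings <- data.frame(
    beacon_id = rep(c("office", "meeting"), each = 5),
    ts = c(parse_ts(paste0(D, "09:00:00")) + 60 * (0:4),
           parse_ts(paste0(D, "09:02:00")) + 60 * (0:4)))
  per <- build_indoor_periods(pings, monitor_const(2, from = "09:00:00"))
  expect_length(per, 2)
  expect_setequal(vapply(per, `[[`, character(1), "beacon_id"),
                  c("office", "meeting"))
})

test_that("monitor CSV readers accept wide and long forms with fixed units", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,pm25,co2,voc",
               "2017-03-24 10:00:00,8.1,450,150",
               "2017-03-24 10:01:00,8.3,452,151"), tmp)
  wide <- read_monitor_csv(tmp)
  expect_setequal(unique(wide$pollutant), c("PM2.5", "CO2", "VOC"))
  expect_equal(nrow(wide), 6)
  writeLines(c("datetime,pollutant,value",
               "2017-03-24 10:00:00,PM2.5,8.1",
               "2017-03-24 10:01:00,PM2.5,-1"), tmp)
  expect_error(read_monitor_csv(tmp), "negative")
})
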