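# Steps 4-5: thresholds, gap filling, indoor/outdoor, sleep, smoothing

test_that("quantile thresholds use the linear-interpolation convention", {
  expect_equal(derive_threshold(1:100, 0.25), 25.75)
  expect_equal(derive_threshold(rep(7, 50), 0.9), 7)
  expect_error(derive_threshold(c(NA_real_, NA_real_), 0.5), "all-missing")
  # per-participant: different distributions give different thresholds
  expect_false(derive_threshold(1:100, .5) == derive_threshold(101:200, .5))
})

test_that("the centred derivative of a constant series is zero", {
  expect_equal(centred_derivative(rep(5, 30)), rep(0, 30))
  d <- centred_derivative(c(1, 2, 4, 8))
  expect_equal(d[2], (4 - 1) / 2)
})

make_gap_trace <- function(n = 60) {
  tr <- make_trace(n, lon = 0, lat = 45)
  tr <- project_utm(tr)
  tr
}

test_that("short near-stationary gaps fill with the last-known static
           label", {
  tr <- make_gap_trace(60)
  tr$x[1:60] <- 0; tr$y[1:60] <- 0
  tr$x[16:45] <- NA; tr$y[16:45] <- NA
  tr$lon[16:45] <- NA; tr$lat[16:45] <- NA
  tr$x[46:60] <- 20  # endpoints 20 m apart
  labels <- rep("home", 60); labels[16:45] <- NA
  out <- interpolate_gaps(tr, labels)
  expect_equal(out$labels[16:45], rep("home", 30))
  expect_true(all(out$fill[16:45]))
  expect_equal(out$trace$x[16:45], rep(0, 30))
  # observed fixes are never overwritten
  expect_equal(out$trace$x[46:60], rep(20, 15))
})

test_that("gaps with distant endpoints become transit candidates and long
           gaps stay unclassified", {
  tr <- make_gap_trace(40)
  tr$x[] <- 0; tr$y[] <- 0
  tr$x[16:25] <- NA; tr$y[16:25] <- NA
  tr$lon[16:25] <- NA; tr$lat[16:25] <- NA
  tr$x[26:40] <- 5000
  labels <- rep("home", 40); labels[16:25] <- NA
  out <- interpolate_gaps(tr, labels)
  expect_true(all(out$transit_candidate[16:25]))
  expect_true(all(is.na(out$labels[16:25])))
  # a gap longer than max_gap stays unclassified
  tr2 <- make_gap_trace(400)
  tr2$x[] <- 0; tr2$y[] <- 0
  mid <- 51:350
  tr2$x[mid] <- NA; tr2$y[mid] <- NA
  tr2$lon[mid] <- NA; tr2$lat[mid] <- NA
  lab2 <- rep("home", 400); lab2[mid] <- NA
  out2 <- interpolate_gaps(tr2, lab2)
  expect_true(all(is.na(out2$labels[mid])))
  # leading gaps are never extrapolated
  tr3 <- make_gap_trace(30)
  tr3$lon[1:5] <- NA; tr3$lat[1:5] <- NA
  tr3$x[1:5] <- NA; tr3$y[1:5] <- NA
  lab3 <- rep("home", 30); lab3[1:5] <- NA
  out3 <- interpolate_gaps(tr3, lab3)
  expect_true(all(is.na(out3$labels[1:5])))
})

test_that("indoor/outdoor splits on joint satellite and activity
           thresholds", {
  tr <- make_trace(120)
  tr <- project_utm(tr)
  tr$n_sat <- c(rep(2, 60), rep(9, 60))
  tr$accel <- c(rep(0.02, 60), rep(0.8, 60))
  labels <- rep("home", 120)
  thr <- list(sat_thr = 6, accel_thr = 0.3, mic_thr = .1, dpm10_thr = 1)
  out <- classify_indoor_outdoor(tr, labels, thr)
  expect_equal(out[1:60], rep("home_in", 60))
  expect_equal(out[61:120], rep("home_out", 60))
})

test_that("short indoor/outdoor flicker is merged into its neighbours", {
  tr <- make_trace(60)
  tr <- project_utm(tr)
  tr$n_sat <- rep(2, 60); tr$accel <- rep(0.02, 60)
  tr$n_sat[30:31] <- 9; tr$accel[30:31] <- 0.9  # 2-minute blip
  thr <- list(sat_thr = 6, accel_thr = 0.3)
  out <- classify_indoor_outdoor(tr, rep("home", 60), thr,
                                 ta_config(io_min_run_min = 5))
  expect_equal(out, rep("home_in", 60))
})

test_that("sleep requires quiet, stillness and stable coarse particles,
           within home_in only", {
  n <- 120
  tr <- make_trace(n)
  tr <- project_utm(tr)
  tr$mic <- rep(0.05, n); tr$accel <- rep(0.02, n)
  tr$pm10 <- rep(8, n)
  labels <- rep("home_in", n)
  labels[1:10] <- "other_in"
  thr <- list(mic_thr = 0.2, accel_thr = 0.1, dpm10_thr = 1)
  out <- classify_sleep(tr, labels, thr)
  expect_true(all(out[11:n] == "sleep"))
  expect_true(all(out[1:10] == "other_in"))  # sleep only inside home_in
  # evening cooking: particles rising sharply blocks sleep
  tr2 <- tr
  tr2$pm10 <- 8 + seq(0, 3 * (n - 1), by = 3)
  out2 <- classify_sleep(tr2, rep("home_in", n), thr)
  expect_false(any(out2 == "sleep"))
})

test_that("rolling majority smoothing removes minority blips and keeps
           majorities", {
  sleep <- rep(TRUE, 60)
  sleep[30:32] <- FALSE  # 3-minute wake blip
  expect_true(all(smooth_binary(sleep, 10)))
  long_blip <- rep(TRUE, 30)
  long_blip[11:16] <- FALSE  # 6 of 10: a majority where it sits
  sm <- smooth_binary(long_blip, 10)
  expect_true(any(!sm[11:16]))
  expect_equal(smooth_binary(rep(FALSE, 40), 10), rep(FALSE, 40))
})

test_that("smoothing is idempotent for runs at least as long as the
           window", {
  set.seed(30)
  for (rep in 1:20) {
    # build series whose runs are all >= window
    runs <- sample(10:20, 6, replace = TRUE)
    vals <- rep(c(TRUE, FALSE), 3)
    x <- inverse.rle(list(lengths = runs, values = vals))
    s1 <- smooth_binary(x, 10)
    expect_equal(smooth_binary(s1, 10), s1)
  }
})

test_that("thresholds are derived from each participant's own data", {
  a <- simulate_participant(scenario(seed = 41))
  b <- simulate_participant(scenario(seed = 42, sat_indoor_mean = 3))
  ta <- derive_thresholds(resample_minutely(a$trace))
  tb <- derive_thresholds(resample_minutely(b$trace))
  expect_false(isTRUE(all.equal(ta$sat_thr, tb$sat_thr)) &&
               isTRUE(all.equal(ta$mic_thr, tb$mic_thr)))
})
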