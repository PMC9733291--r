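# Step 6: journeys, segmentation, features, selection, RF, cross-validation

test_that("journeys merge across stops shorter than 20 minutes", {
  mv <- function(m) rep(TRUE, m); st <- function(m) rep(FALSE, m)
  j1 <- split_journeys(c(st(5), mv(10), st(15), mv(10), st(5)))
  expect_equal(nrow(j1), 1)
  expect_equal(j1$end - j1$start + 1, 35)
  j2 <- split_journeys(c(st(5), mv(10), st(25), mv(10)))
  expect_equal(nrow(j2), 2)
  # boundary: exactly 20 minutes of stop splits (strict <)
  j3 <- split_journeys(c(mv(10), st(20), mv(10)))
  expect_equal(nrow(j3), 2)
  j4 <- split_journeys(c(mv(10), st(19), mv(10)))
  expect_equal(nrow(j4), 1)
})

test_that("segmentation finds the change point in a two-regime series", {
  set.seed(50)
  x <- c(rnorm(20, 1.2, 0.1), rnorm(20, 18, 0.1))
  lv <- lavielle_segments(x, lmin = 5, kmax = 8)
  expect_equal(lv$k, 2)
  expect_lte(abs(lv$breaks - 21), 1)
  # constant series: a single segment
  lv0 <- lavielle_segments(rep(3, 40), lmin = 5, kmax = 8)
  expect_equal(lv0$k, 1)
  expect_length(lv0$breaks, 0)
  # too-short series: single segment
  expect_equal(lavielle_segments(rnorm(4), lmin = 3)$k, 1)
})

test_that("the dynamic program equals exhaustive enumeration", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(12:28, 1)
    lmin <- sample(2:4, 1)
    x <- rnorm(n) + rep(c(0, sample(0:4, 1)), each = ceiling(n / 2))[1:n]
    lv <- lavielle_segments(x, lmin = lmin, kmax = 4)
    for (K in 1:3) {
      if (n < K * lmin) next
      expect_equal(lv$contrast[K], oracle_lavielle(x, K, lmin),
                   tolerance = 1e-8)
    }
    # returned breakpoints respect the minimum segment length
    seg_len <- lv$segments$end - lv$segments$start + 1
    expect_true(all(seg_len >= lmin))
    expect_equal(sum(seg_len), n)
  }
})

make_track <- function(x, y, valid = TRUE) {
  tr <- make_trace(length(x))
  tr$x <- x; tr$y <- y
  tr$lon <- x / 1e5; tr$lat <- 45 + y / 1e5
  if (!all(valid)) {
    tr$lon[!valid] <- NA; tr$lat[!valid] <- NA
    tr$x[!valid] <- NA; tr$y[!valid] <- NA
  }
  attr(tr, "utm_zone") <- 31L
  tr
}

test_that("movement features on canonical geometries", {
  # straight east-bound at 60 m/min
  tr <- make_track(60 * (0:9), rep(0, 10))
  f <- movement_features(tr)
  expect_equal(f$speed_mean, 1)
  expect_equal(f$rel_angle_mean_abs, 0)
  expect_equal(f$straightness, 1)
  expect_equal(f$abs_angle_mean, 0)
  # square loop: returns to start, right angles at corners
  sq <- rbind(c(0, 0), c(60, 0), c(120, 0), c(120, 60), c(120, 120),
              c(60, 120), c(0, 120), c(0, 60), c(0, 0))
  f2 <- movement_features(make_track(sq[, 1], sq[, 2]))
  expect_equal(f2$straightness, 0)
  expect_equal(f2$rel_angle_p95, 90)
  expect_true(all(abs(f2$rel_angle_median_abs) <= 90))
  # fewer than two fixes: all missing
  f3 <- movement_features(make_track(c(0, 60), c(0, 0), valid = c(TRUE, FALSE)))
  expect_true(all(is.na(unlist(f3))))
})

test_that("movement aggregates equal recomputation from raw points", {
  set.seed(52)
  x <- cumsum(rnorm(30, 10, 20)); y <- cumsum(rnorm(30, 0, 20))
  f <- movement_features(make_track(x, y))
  step <- sqrt(diff(x)^2 + diff(y)^2)
  expect_equal(f$dist_total, sum(step))
  expect_equal(f$speed_p95, quantile(step / 60, .95, names = FALSE))
  expect_equal(f$dist_net, sqrt((x[30] - x[1])^2 + (y[30] - y[1])^2))
  expect_equal(f$straightness, f$dist_net / f$dist_total)
})

test_that("network features measure overlap fractions and stop counts", {
  sc <- scenario()
  nw_ll <- scenario_network(sc)
  f <- tempfile(fileext = ".geojson")
  write_network(nw_ll, f)
  nw <- read_network(f, zone = utm_zone(sc$base_lonlat[1]))
  # fixes exactly on the railway
  rail <- Filter(function(l) l$kind == "railway", nw$lines)[[1]]$coords
  steps <- seq(0, 1, length.out = 12)
  rx <- approx(seq_len(nrow(rail)), rail[, 1], n = 12)$y
  ry <- approx(seq_len(nrow(rail)), rail[, 2], n = 12)$y
  tr <- make_track(rx, ry)
  g <- network_features(tr, nw)
  expect_equal(g$frac_railway, 1)
  expect_equal(g$n_train_stops, 2)
  # far from every layer: all zero
  tr2 <- make_track(rx + 5000, ry - 7000)
  g2 <- network_features(tr2, nw)
  expect_true(all(unlist(g2) == 0))
  # empty network: all zero
  g3 <- network_features(tr, list(lines = list(), stops = list()))
  expect_true(all(unlist(g3) == 0))
  # oracle check of the distance computation
  d_first <- timeactivity:::.dist_to_polyline(rx[1] + 30, ry[1], rail)
  expect_lte(abs(d_first - 30), 30)  # within segment-geometry tolerance
})

test_that("the feature vector has exactly the 60 documented names", {
  expect_length(feature_names(), 60)
  expect_length(unique(feature_names()), 60)
  sc <- scenario()
  p <- simulate_trip("walk", sc, seed = 3)
  tr <- project_utm(p$trace)
  fv <- extract_segment_features(tr, seq_len(nrow(tr)),
                                 list(car_owner = 1, bike_owner = 0,
                                      pt_freq = 2), NULL)
  expect_equal(colnames(fv), feature_names())
})

test_that("a dominant predictor is selected alone from noise", {
  set.seed(53)
  n <- 150
  X <- as.data.frame(matrix(rnorm(n * 11), n, 11))
  names(X) <- c("signal", paste0("noise", 1:10))
  y <- factor(ifelse(X$signal > 0, "a", "b"))  # perfectly separable
  sel <- select_predictors(X, y, n_runs = 8, ntree = 80, seed = 2)
  expect_equal(sel$final_kept, "signal")
  expect_true(all(sel$final_kept %in% sel$step2_kept))
  expect_true(all(sel$step2_kept %in% sel$step1_kept))
  expect_gt(sel$stepwise_threshold, 0)
})

test_that("the mode model is exact on separable training data and
           probabilistic", {
  set.seed(54)
  n <- 60
  X <- data.frame(speed = c(runif(n, 0, 2), runif(n, 10, 20)),
                  z = rnorm(2 * n))
  y <- rep(c("walk", "car"), each = n)
  m <- train_mode_classifier(X, y, n_trees = 100, seed = 3)
  pr <- predict(m, X, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 2 * n), tolerance = 1e-9)
  expect_equal(as.character(predict(m, X)), y)
  expect_error(predict(m, X[, "z", drop = FALSE]), "missing")
})

test_that("training is invariant to row permutation under a fixed seed", {
  set.seed(55)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- rep(c("walk", "car"), 40)
  m1 <- train_mode_classifier(X, y, n_trees = 60, seed = 7)
  perm <- sample(80)
  m2 <- train_mode_classifier(X[perm, ], y[perm], n_trees = 60, seed = 7)
  Xn <- data.frame(a = rnorm(40), b = rnorm(40))
  expect_identical(predict(m1, Xn, type = "prob"),
                   predict(m2, Xn, type = "prob"))
})

test_that("folds are mutually exclusive, exhaustive and near-equal", {
  set.seed(56)
  X <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- rep(c("walk", "car"), 50)
  cv <- crossvalidate(X, y, k = 10, seed = 4, n_trees = 30)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_true(all(table(cv$fold) == 10))
  # every observation is validated exactly once
  expect_false(anyNA(cv$pred))
  # grouped folds never split a group
  g <- rep(1:20, each = 5)
  cvg <- crossvalidate(X, y, k = 10, seed = 4, groups = g, n_trees = 30)
  expect_true(all(tapply(cvg$fold, g, function(v) length(unique(v))) == 1))
})
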