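# Step 2: time-scaled distance, adaptive neighbours, hulls, isopleths, motion

test_that("time-scaled distance reduces to Euclidean and is hand-checkable", {
  expect_equal(time_scaled_distance(3, 4, 0, 1, 5), 5)       # dt = 0
  expect_equal(time_scaled_distance(3, 4, 999, 0, 5), 5)     # s = 0
  expect_equal(time_scaled_distance(300, 400, 60, 1, 5),
               sqrt(500^2 + 300^2))                           # 583.095...
  # symmetric, dominates Euclidean, monotone in |dt|
  set.seed(1)
  for (i in 1:20) {
    dx <- rnorm(1); dy <- rnorm(1); dt <- runif(1, 0, 100)
    expect_equal(time_scaled_distance(dx, dy, dt, .3, 2),
                 time_scaled_distance(-dx, -dy, -dt, .3, 2))
    expect_gte(time_scaled_distance(dx, dy, dt, .3, 2), sqrt(dx^2 + dy^2))
    expect_gte(time_scaled_distance(dx, dy, dt + 1, .3, 2),
               time_scaled_distance(dx, dy, dt, .3, 2))
  }
})

make_projected <- function(x, y, t_min = seq_along(x)) {
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  tr <- make_trace(length(x), t0 = t0)
  tr$t <- t0 + 60 * t_min
  tr$x <- x; tr$y <- y
  attr(tr, "utm_zone") <- 31L; attr(tr, "utm_south") <- FALSE
  tr
}

test_that("adaptive neighbour selection follows the cumulative rule", {
  # neighbours at TSD 10, 20, 30 from the parent; a = 35 keeps the first two
  tr <- make_projected(c(0, 10, -20, 30), c(0, 0, 0, 0), t_min = rep(1, 4))
  nn <- adaptive_neighbors(tr, list(s = 0, v_char = 1, a_value = 35))
  expect_equal(nn$neighbors[[1]], c(1L, 2L, 3L))
  # a below the nearest TSD leaves the parent alone
  nn2 <- adaptive_neighbors(tr, list(s = 0, v_char = 1, a_value = 5))
  expect_equal(nn2$neighbors[[1]], 1L)
})

test_that("adaptive neighbours equal the brute-force oracle on random sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 40
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    tmin <- sort(runif(n, 0, 600))
    tr <- make_projected(x, y, t_min = tmin)
    svt <- 0.05 * 2
    a <- runif(1, 50, 400)
    nn <- adaptive_neighbors(tr, list(s = 0.05, v_char = 2, a_value = a))
    ora <- oracle_adaptive_nn(x, y, tmin * 60, svt, a)
    for (i in seq_len(n)) expect_equal(nn$neighbors[[i]], ora[[i]])
  }
})

test_that("larger radii never shrink neighbour sets", {
  set.seed(12)
  tr <- make_projected(runif(60, 0, 300), runif(60, 0, 300))
  n1 <- adaptive_neighbors(tr, list(s = 0.05, v_char = 1, a_value = 100))
  n2 <- adaptive_neighbors(tr, list(s = 0.05, v_char = 1, a_value = 200))
  for (i in 1:60)
    expect_true(all(n1$neighbors[[i]] %in% n2$neighbors[[i]]))
})

test_that("the automatic radius reaches the target median neighbourhood", {
  set.seed(13)
  tr <- make_projected(rnorm(200, 0, 40), rnorm(200, 0, 40))
  a <- auto_a_value(tr, s = 0.05, v_char = 1, target = 10)
  nn <- adaptive_neighbors(tr, list(s = 0.05, v_char = 1, a_value = a))
  expect_gte(median(lengths(nn$neighbors)), 10)
})

test_that("hull geometry: eccentricity from the covariance ellipse", {
  # collinear members are degenerate with ecc 1
  tr <- make_projected(1:5 * 10, 1:5 * 10)
  nn <- adaptive_neighbors(tr, list(s = 0, v_char = 1, a_value = 1e6))
  h <- build_hulls(tr, nn)
  expect_true(all(h$metrics$ecc == 1))
  expect_true(all(h$metrics$degenerate))
  expect_true(all(is.infinite(h$metrics$par)))
  # points on a circle are nearly isotropic
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  trc <- make_projected(100 * cos(th), 100 * sin(th), t_min = rep(1, 40))
  nnc <- adaptive_neighbors(trc, list(s = 0, v_char = 1, a_value = 1e9))
  hc <- build_hulls(trc, nnc)
  expect_lt(hc$metrics$ecc[1], 0.15)
  # 2x1 rectangle corners: eigenvalue ratio 1/4, ecc sqrt(0.75)
  trr <- make_projected(c(0, 2, 2, 0), c(0, 0, 1, 1), t_min = rep(1, 4))
  nnr <- adaptive_neighbors(trr, list(s = 0, v_char = 1, a_value = 1e9))
  hr <- build_hulls(trr, nnr)
  expect_equal(hr$metrics$ecc[1], sqrt(0.75), tolerance = 1e-12)
})

test_that("eccentricity agrees with an eigen-decomposition oracle", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n) * runif(1, 0.1, 2)
    ev <- eigen(cov(cbind(x, y)))$values
    ora <- if (min(ev) <= 0) 1 else sqrt(1 - min(ev) / max(ev))
    expect_equal(timeactivity:::.scatter_ecc(x, y), ora, tolerance = 1e-9)
  }
})

test_that("hull polygons enclose all their member points", {
  set.seed(15)
  tr <- make_projected(runif(80, 0, 200), runif(80, 0, 200))
  nn <- adaptive_neighbors(tr, list(s = 0.05, v_char = 1, a_value = 300))
  h <- build_hulls(tr, nn)
  for (i in sample(80, 25)) {
    poly <- h$polygons[[i]]
    mem <- nn$neighbors[[i]]
    if (nrow(poly) < 3) next
    for (m in mem)
      expect_true(oracle_in_hull(tr$x[m], tr$y[m], poly))
  }
})

test_that("isopleth accumulation stops at the smallest sufficient prefix", {
  set.seed(16)
  tr <- make_projected(c(rnorm(90, 0, 10), rnorm(10, 500, 10)),
                       c(rnorm(90, 0, 10), rnorm(10, 500, 10)))
  nn <- adaptive_neighbors(tr, list(s = 0, v_char = 1, a_value = 200))
  h <- build_hulls(tr, nn)
  iso <- merge_isopleths(h, "density", level = 0.95)
  expect_gte(length(iso$enclosed), 95)
  # the prefix is minimal: dropping the last hull goes below the level
  pre <- iso$hull_order[-length(iso$hull_order)]
  if (length(pre))
    expect_lt(length(unique(unlist(h$members[pre]))), 95)
  # enclosed counts match a brute-force union at every prefix
  ord <- iso$hull_order
  acc <- integer(0)
  for (k in seq_along(ord)) {
    acc <- union(acc, h$members[[ord[k]]])
    expect_equal(length(acc),
                 length(unique(unlist(h$members[ord[seq_len(k)]]))))
  }
  # at level 1 there are no outliers
  iso1 <- merge_isopleths(h, "density", level = 1)
  expect_length(iso1$outliers, 0)
  # share is monotone in level
  iso80 <- merge_isopleths(h, "density", level = 0.80)
  expect_lte(length(iso80$enclosed), length(iso$enclosed))
})

test_that("a single all-covering hull saturates the isopleth", {
  tr <- make_projected(c(0, 1, 2), c(0, 1, 0), t_min = rep(1, 3))
  nn <- adaptive_neighbors(tr, list(s = 0, v_char = 1, a_value = 1e9))
  h <- build_hulls(tr, nn)
  iso <- merge_isopleths(h, "density", level = 0.95)
  expect_length(iso$outliers, 0)
  expect_equal(length(iso$hull_order), 1)
})

test_that("motion classification separates elongation extremes", {
  h <- list(metrics = data.frame(
    parent = 1:4,
    ecc = c(0.99, 0.05, 0.98, 0.10),
    density = c(3, 80, 4, 70)))
  m <- classify_motion(h, ecc_quantile = 0.5, density_quantile = 0.5)
  expect_equal(m$motion[h$metrics$ecc > 0.9], c("movement", "movement"))
  expect_equal(m$motion[h$metrics$ecc < 0.2], c("static", "static"))
})
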