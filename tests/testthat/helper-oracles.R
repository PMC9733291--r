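# Brute-force oracles, independent of the implementation paths they check.

# adaptive neighbour selection: sort-and-accumulate per parent
oracle_adaptive_nn <- function(x, y, t, svt, a) {
  n <- length(x)
  lapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2 + (svt * (t - t[i]))^2)
    d[i] <- Inf
    ord <- order(d)
    keep <- i
    acc <- 0
    for (j in ord) {
      if (!is.finite(d[j])) break
      acc <- acc + d[j]
      if (acc > a) break
      keep <- c(keep, j)
    }
    sort(keep)
  })
}

# visit runs by linear scan
oracle_visit_runs <- function(times_sec, ivg_sec) {
  sizes <- integer(0)
  cur <- 1
  for (i in seq_along(times_sec)[-1]) {
    if (times_sec[i] - times_sec[i - 1] >= ivg_sec) {
      sizes <- c(sizes, cur); cur <- 1
    } else cur <- cur + 1
  }
  c(sizes, cur)
}

# confusion tally minute by minute
oracle_confusion <- function(pred, truth, positive) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (is.na(truth[i])) next
    p <- !is.na(pred[i]) && pred[i] == positive
    a <- truth[i] == positive
    if (p && a) tp <- tp + 1
    else if (p && !a) fp <- fp + 1
    else if (!p && a) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# exhaustive optimal segmentation: minimum within-segment SSE over all
# placements of K segments with minimum length lmin
oracle_lavielle <- function(x, K, lmin) {
  n <- length(x)
  sse <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  best <- Inf
  rec <- function(start, k, acc) {
    if (acc >= best) return()
    if (k == 1) {
      if (n - start + 1 >= lmin) best <<- min(best, acc + sse(start, n))
      return()
    }
    for (end in (start + lmin - 1):(n - (k - 1) * lmin)) {
      rec(end + 1, k - 1, acc + sse(start, end))
    }
  }
  if (n >= K * lmin) rec(1, K, 0)
  best
}

# naive density-based clustering (label propagation from core points)
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  core <- rowSums(d <= eps) >= min_pts
  cl <- rep(0L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cl[i] != 0) next
    k <- k + 1L
    frontier <- i
    cl[i] <- k
    while (length(frontier)) {
      nxt <- integer(0)
      for (q in frontier) {
        if (!core[q]) next
        nb <- which(d[q, ] <= eps & cl == 0)
        cl[nb] <- k
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  cl
}

# point-in-convex-polygon (cross products, tolerant)
oracle_in_hull <- function(px, py, poly) {
  n <- nrow(poly)
  if (n < 3) return(TRUE)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (abs(cr) < 1e-9) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s
    else if (s != sgn) return(FALSE)
  }
  TRUE
}

# small synthetic trace builder for rule tests
make_trace <- function(n, t0 = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                       lon = 0, lat = 45, n_sat = 9, accel = 0.1, mic = 0.3,
                       dock_v = FALSE, ...) {
  df <- data.frame(t = t0 + 60 * (seq_len(n) - 1), lon = lon, lat = lat,
                   n_sat = n_sat, accel = accel, mic = mic, dock_v = dock_v,
                   ...)
  structure(df, class = c("ta_trace", "data.frame"),
            participant_id = "t", tz_offset_minutes = 0L, n_malformed = 0L)
}
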