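# Step 6: journeys, penalized-contrast segmentation, segment features,
# three-step variable selection and random-forest mode classification.

#' Split transit minutes into journeys
#'
#' Maximal transit runs are merged across embedded static runs shorter than
#' `stop_max_min` (a stop is part of a journey if the participant stayed
#' static for less than that; the threshold is a strict `<`). Longer static
#' runs split journeys.
#'
#' @param transit Logical per-minute transit flags.
#' @param stop_max_min Stop threshold in minutes (default 20).
#' @return Data frame with `journey`, `start`, `end` (minute indices; the
#'   span may contain embedded stop minutes).
#' @export
split_journeys <- function(transit, stop_max_min = 20) {
  n <- length(transit)
  idx <- which(transit)
  if (!length(idx)) {
    return(data.frame(journey = integer(0), start = integer(0),
                      end = integer(0)))
  }
  r <- rle(transit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  tr_runs <- which(r$values)
  j_start <- starts[tr_runs[1]]; j_end <- ends[tr_runs[1]]
  out <- list()
  for (k in tail(tr_runs, -1)) {
    gap <- starts[k] - j_end - 1
    if (gap < stop_max_min) {
      j_end <- ends[k]
    } else {
      out[[length(out) + 1]] <- c(j_start, j_end)
      j_start <- starts[k]; j_end <- ends[k]
    }
  }
  out[[length(out) + 1]] <- c(j_start, j_end)
  m <- do.call(rbind, out)
  data.frame(journey = seq_len(nrow(m)), start = m[, 1], end = m[, 2])
}

#' Penalized-contrast segmentation of a series
#'
#' Dynamic programming partition of a numeric series minimizing the
#' within-segment sum of squared deviations from segment means, with a
#' minimum segment length. The number of segments K is chosen by the elbow
#' rule on the normalized contrast curve: the largest K whose second
#' difference of the normalized contrast exceeds `threshold`.
#'
#' @param x Numeric series (per-minute movement signal, e.g. speed).
#' @param lmin Minimum segment length (default 3).
#' @param kmax Maximum number of segments considered (default 10).
#' @param threshold Elbow threshold on the normalized contrast decrease.
#' @return List with `k` (chosen segments), `breaks` (start indices of
#'   segments 2..k; empty when k = 1), `contrast` (optimal contrast per K)
#'   and `segments` (data frame `start`, `end`).
#' @export
lavielle_segments <- function(x, lmin = 3, kmax = 10, threshold = 0.75) {
  n <- length(x)
  one <- list(k = 1L, breaks = integer(0), contrast = NA_real_,
              segments = data.frame(start = 1L, end = n))
  if (n < 2 * lmin) return(one)
  x[is.na(x)] <- median(x, na.rm = TRUE)
  kmax <- max(1L, min(kmax, n %/% lmin))
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  cost <- function(i, j) {
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    max(s2 - s^2 / (j - i + 1), 0)
  }
  # I[k, j]: best contrast for x[1..j] in k segments; B[k, j]: last break
  I <- matrix(Inf, kmax, n); B <- matrix(NA_integer_, kmax, n)
  for (j in lmin:n) I[1, j] <- cost(1, j)
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (j in (k * lmin):n) {
        hs <- ((k - 1) * lmin):(j - lmin)
        vals <- I[k - 1, hs] + vapply(hs, function(h) cost(h + 1, j),
                                      numeric(1))
        b <- which.min(vals)
        I[k, j] <- vals[b]; B[k, j] <- hs[b]
      }
    }
  }
  J <- I[, n]
  k_opt <- .choose_k(J, threshold)
  breaks <- integer(0)
  if (k_opt > 1) {
    j <- n
    for (k in k_opt:2) {
      h <- B[k, j]
      breaks <- c(h + 1L, breaks)
      j <- h
    }
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, n)
  list(k = as.integer(k_opt), breaks = breaks, contrast = J,
       segments = data.frame(start = starts, end = ends))
}

# Elbow rule on the normalized contrast curve.
.choose_k <- function(J, threshold) {
  kmax <- length(J)
  if (kmax == 1 || !is.finite(J[1])) return(1L)
  span <- J[1] - J[kmax]
  if (span <= .Machine$double.eps * max(J[1], 1)) return(1L)
  Jn <- (J - J[kmax]) / span * (kmax - 1) + 1
  if (kmax == 2) return(if (Jn[1] - Jn[2] > threshold * (kmax - 1)) 2L else 1L)
  D <- Jn[1:(kmax - 2)] - 2 * Jn[2:(kmax - 1)] + Jn[3:kmax]  # D[K-1] for K>=2
  ok <- which(D > threshold)
  if (!length(ok)) 1L else as.integer(max(ok) + 1L)
}

# --- feature extraction -----------------------------------------------------

MOVEMENT_FEATURES <- c("speed_mean", "speed_median", "speed_p95", "speed_sd",
                       "speed_max", "step_mean", "dist_total", "dist_net",
                       "straightness", "abs_angle_mean", "abs_angle_sd",
                       "rel_angle_mean_abs", "rel_angle_median_abs",
                       "rel_angle_sd", "rel_angle_p95", "turn_frac",
                       "hull_ecc_mean", "hull_ecc_median", "hull_par_median")

SENSOR_FEATURES <- c("hour_start", "hour_mid", "duration_min",
                     paste0("accel_", c("mean", "sd", "min", "max", "p5",
                                        "p25", "median", "p75", "p95")),
                     paste0("mic_", c("mean", "sd", "min", "max", "p5",
                                      "p25", "median", "p75", "p95")),
                     paste0("sat_", c("mean", "sd", "min", "max", "modal")),
                     "fix_valid_frac", "n_valid_fixes", "x_sd", "y_sd",
                     "dock_frac")

QUESTIONNAIRE_FEATURES <- c("car_owner", "bike_owner", "pt_freq")

GIS_FEATURES <- c("frac_highway", "frac_railway", "frac_sidewalk",
                  "frac_cycleway", "frac_busway", "n_bus_stops",
                  "n_train_stops")

#' Names of the 60 candidate predictors
#'
#' 31 sensor summaries, 3 questionnaire answers, 19 movement metrics and 7
#' GIS projections.
#'
#' @return Character vector of length 60.
#' @export
feature_names <- function() {
  c(SENSOR_FEATURES, QUESTIONNAIRE_FEATURES, MOVEMENT_FEATURES, GIS_FEATURES)
}

.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Movement features of a segment
#'
#' Per-minute step distances, speeds, absolute headings and relative turning
#' angles between consecutive valid fixes, aggregated over the segment,
#' plus local-hull shape aggregates when hull metrics are supplied.
#'
#' @param seg Trace rows of the segment (projected).
#' @param hull_metrics Optional data frame with `parent` (row index into
#'   `seg`) and `ecc`, `par` columns.
#' @return One-row data frame of the 19 movement features (all `NA` when the
#'   segment has fewer than 2 valid fixes).
#' @export
movement_features <- function(seg, hull_metrics = NULL) {
  out <- as.data.frame(setNames(as.list(rep(NA_real_,
                                            length(MOVEMENT_FEATURES))),
                                MOVEMENT_FEATURES))
  ok <- which(valid_fix(seg))
  if (length(ok) < 2) return(out)
  x <- seg$x[ok]; y <- seg$y[ok]
  dt <- diff(as.numeric(seg$t[ok]))
  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step / dt
  heading <- atan2(dy, dx) * 180 / pi
  rel <- .wrap180(diff(heading))
  qs <- function(v, p) quantile(v, p, names = FALSE, na.rm = TRUE)
  out$speed_mean <- mean(speed); out$speed_median <- median(speed)
  out$speed_p95 <- qs(speed, .95); out$speed_sd <- sd(speed)
  out$speed_max <- max(speed)
  out$step_mean <- mean(step)
  out$dist_total <- sum(step)
  out$dist_net <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  out$straightness <- if (out$dist_total > 0) out$dist_net / out$dist_total
                      else NA_real_
  mc <- mean(cos(heading * pi / 180)); ms <- mean(sin(heading * pi / 180))
  out$abs_angle_mean <- (atan2(ms, mc) * 180 / pi) %% 360
  R <- min(sqrt(mc^2 + ms^2), 1)
  out$abs_angle_sd <- sqrt(max(-2 * log(max(R, 1e-12)), 0)) * 180 / pi
  if (length(rel)) {
    out$rel_angle_mean_abs <- mean(abs(rel))
    out$rel_angle_median_abs <- median(abs(rel))
    out$rel_angle_sd <- if (length(rel) > 1) sd(rel) else 0
    out$rel_angle_p95 <- qs(abs(rel), .95)
    out$turn_frac <- mean(abs(rel) > 30)
  }
  if (!is.null(hull_metrics) && nrow(hull_metrics)) {
    ecc <- hull_metrics$ecc
    par <- hull_metrics$par[is.finite(hull_metrics$par)]
    out$hull_ecc_mean <- mean(ecc, na.rm = TRUE)
    out$hull_ecc_median <- median(ecc, na.rm = TRUE)
    out$hull_par_median <- if (length(par)) median(par) else NA_real_
  }
  out
}

#' Sensor summary features of a segment
#'
#' @param seg Trace rows of the segment.
#' @param tz_offset Minutes from UTC to local clock.
#' @return One-row data frame of the 31 sensor features.
#' @export
sensor_features <- function(seg, tz_offset = 0L) {
  qs <- function(v, p) if (all(is.na(v))) NA_real_ else
    quantile(v, p, names = FALSE, na.rm = TRUE)
  st <- function(v) c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
                      suppressWarnings(min(v, na.rm = TRUE)),
                      suppressWarnings(max(v, na.rm = TRUE)),
                      qs(v, .05), qs(v, .25), qs(v, .5),
                      qs(v, .75), qs(v, .95))
  local <- seg$t + tz_offset * 60
  hr <- as.numeric(format(local, "%H", tz = "UTC")) +
    as.numeric(format(local, "%M", tz = "UTC")) / 60
  ok <- valid_fix(seg)
  sat <- seg$n_sat[!is.na(seg$n_sat)]
  modal <- if (length(sat)) as.numeric(names(which.max(table(sat))))
           else NA_real_
  vals <- c(hr[1], hr[ceiling(length(hr) / 2)], nrow(seg),
            st(seg$accel), st(seg$mic),
            mean(seg$n_sat, na.rm = TRUE), sd(seg$n_sat, na.rm = TRUE),
            suppressWarnings(min(seg$n_sat, na.rm = TRUE)),
            suppressWarnings(max(seg$n_sat, na.rm = TRUE)), modal,
            mean(ok), sum(ok), sd(seg$x[ok]), sd(seg$y[ok]),
            mean(seg$dock_v, na.rm = TRUE))
  vals[!is.finite(vals)] <- NA_real_
  out <- as.data.frame(as.list(setNames(vals, SENSOR_FEATURES)))
  out
}

.dist_to_polyline <- function(px, py, coords) {
  # minimum distance from each point to a polyline (point-segment distances)
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1)) {
    ax <- coords[i, 1]; ay <- coords[i, 2]
    bx <- coords[i + 1, 1]; by <- coords[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
         else 0
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    best <- pmin(best, d)
  }
  best
}

#' GIS network features of a segment
#'
#' For each of the five line layers, the fraction of the segment's valid
#' fixes lying within the line buffer; for the two stop layers, the count of
#' distinct stops within the stop buffer of the path. Empty layers give 0.
#'
#' @param seg Trace rows of the segment (projected).
#' @param network Network from [read_network()] (projected metres); may be
#'   `NULL` or empty.
#' @param cfg Configuration: `gis_buffer_line_m`, `gis_buffer_stop_m`.
#' @return One-row data frame of the 7 GIS features.
#' @export
network_features <- function(seg, network, cfg = ta_config()) {
  out <- as.data.frame(setNames(as.list(rep(0, length(GIS_FEATURES))),
                                GIS_FEATURES))
  ok <- which(valid_fix(seg))
  if (!length(ok) || is.null(network)) return(out)
  px <- seg$x[ok]; py <- seg$y[ok]
  kinds <- c(highway = "frac_highway", railway = "frac_railway",
             sidewalk = "frac_sidewalk", cycleway = "frac_cycleway",
             busway = "frac_busway")
  for (kd in names(kinds)) {
    lns <- Filter(function(l) identical(l$kind, kd), network$lines)
    if (!length(lns)) next
    best <- rep(Inf, length(px))
    for (ln in lns) {
      if (!is.matrix(ln$coords) || nrow(ln$coords) < 2)
        stop("malformed geometry in network layer: ", kd)
      best <- pmin(best, .dist_to_polyline(px, py, ln$coords))
    }
    out[[kinds[kd]]] <- mean(best <= cfg$gis_buffer_line_m)
  }
  stops <- list(bus_stop = "n_bus_stops", train_stop = "n_train_stops")
  for (kd in names(stops)) {
    sts <- Filter(function(s) identical(s$kind, kd), network$stops)
    cnt <- 0
    for (st in sts) {
      d <- sqrt((px - st$coords[1])^2 + (py - st$coords[2])^2)
      if (any(d <= cfg$gis_buffer_stop_m)) cnt <- cnt + 1
    }
    out[[stops[[kd]]]] <- cnt
  }
  out
}

#' Full 60-variable feature vector for a segment
#'
#' @param trace Projected minute trace.
#' @param rows Minute row indices of the segment.
#' @param questionnaire List `car_owner`, `bike_owner`, `pt_freq` (or `NULL`).
#' @param network Projected network (or `NULL`).
#' @param cfg Configuration.
#' @param hull_metrics Optional hull metrics for the segment rows.
#' @return One-row data frame with the 60 features of [feature_names()].
#' @export
extract_segment_features <- function(trace, rows, questionnaire = NULL,
                                     network = NULL, cfg = ta_config(),
                                     hull_metrics = NULL) {
  seg <- trace[rows, , drop = FALSE]
  sf <- sensor_features(seg, attr(trace, "tz_offset_minutes") %||% 0L)
  qf <- data.frame(
    car_owner = as.numeric(questionnaire$car_owner %||% NA),
    bike_owner = as.numeric(questionnaire$bike_owner %||% NA),
    pt_freq = as.numeric(questionnaire$pt_freq %||% NA))
  mf <- movement_features(seg, hull_metrics)
  gf <- network_features(seg, network, cfg)
  cbind(sf, qf, mf, gf)[, feature_names()]
}

# --- variable selection -----------------------------------------------------

.rf_fit <- function(X, y, ntree, seed, importance = FALSE) {
  set.seed(seed)
  randomForest::randomForest(x = X, y = y, ntree = ntree,
                             importance = importance)
}

.rf_oob <- function(X, y, vars, ntree, seed) {
  rf <- .rf_fit(X[, vars, drop = FALSE], y, ntree, seed)
  as.numeric(tail(rf$err.rate[, "OOB"], 1))
}

#' Three-step variable selection for random-forest classification
#'
#' (1) Preliminary elimination and ranking: variables ranked by permutation
#' importance averaged over `n_runs` forests; variables whose mean importance
#' does not exceed the noise level (the best mean importance among appended
#' shuffled-copy probe variables) are dropped. (2) Interpretation: nested
#' forests over the ranked prefixes; the smallest prefix within one standard
#' deviation of the minimum out-of-bag (OOB) error is kept. (3) Prediction:
#' an ascending sequence of forests adds the remaining variables stepwise; a
#' variable is retained only if the OOB error decreases by more than a
#' data-driven threshold, the mean absolute OOB variation observed when
#' adding noise variables.
#'
#' @param X Feature data frame (complete cases are used).
#' @param y Class factor with at least 2 classes.
#' @param n_runs Forests averaged for the importance ranking.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @param n_probes Number of shuffled-copy probe variables.
#' @return A selection report: `vi_mean`, `vi_sd`, `step1_kept`,
#'   `step2_kept`, `final_kept`, `oob_curve`, `stepwise_threshold`. The kept
#'   sets are nested: final within step2 within step1.
#' @export
select_predictors <- function(X, y, n_runs = 50, ntree = 100, seed = 1L,
                              n_probes = 5) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes for variable selection")
  keep_rows <- complete.cases(X)
  X <- X[keep_rows, , drop = FALSE]; y <- y[keep_rows]
  p <- ncol(X)
  n_probes <- min(n_probes, p)
  probe_src <- sample(seq_len(p), n_probes)
  vi <- matrix(NA_real_, n_runs, p + n_probes)
  for (r in seq_len(n_runs)) {
    probes <- as.data.frame(lapply(probe_src, function(j)
      sample(X[[j]])))
    names(probes) <- paste0(".probe_", seq_len(n_probes))
    rf <- .rf_fit(cbind(X, probes), y, ntree, seed * 100 + r,
                  importance = TRUE)
    vi[r, ] <- randomForest::importance(rf, type = 1)[, 1]
  }
  vi_mean <- colMeans(vi)
  vi_sd <- apply(vi, 2, sd)
  names(vi_mean) <- names(vi_sd) <- c(names(X),
                                      paste0(".probe_", seq_len(n_probes)))
  noise_level <- max(vi_mean[p + seq_len(n_probes)], 0)
  real <- vi_mean[seq_len(p)]
  ranked <- names(sort(real, decreasing = TRUE))
  step1 <- ranked[real[ranked] > noise_level]
  if (!length(step1)) step1 <- ranked[1]
  # step 2: nested OOB over ranked prefixes
  oob_curve <- vapply(seq_along(step1), function(k)
    mean(vapply(1:3, function(r)
      .rf_oob(X, y, step1[seq_len(k)], ntree, seed * 1000 + k * 10 + r),
      numeric(1))), numeric(1))
  names(oob_curve) <- step1
  sd_min <- sd(vapply(1:5, function(r)
    .rf_oob(X, y, step1[seq_len(which.min(oob_curve))], ntree,
            seed * 2000 + r), numeric(1)))
  step2 <- step1[seq_len(min(which(oob_curve <= min(oob_curve) + sd_min)))]
  # stepwise threshold: mean absolute OOB variation when adding noise
  # variables (the ranked-out remainder, probes if none remain)
  noise_vars <- setdiff(ranked, step1)
  err_prev <- oob_curve[length(step2)]
  jumps <- numeric(0)
  Xn <- X
  pool <- head(noise_vars, 5)
  if (length(pool) < 2) {
    for (j in seq_len(3)) {
      nm <- paste0(".probe_sw_", j)
      Xn[[nm]] <- sample(X[[probe_src[((j - 1) %% n_probes) + 1]]])
      pool <- c(pool, nm)
    }
  }
  base_vars <- step2
  e_prev <- err_prev
  for (v in pool) {
    e_new <- .rf_oob(Xn, y, c(base_vars, v), ntree,
                     seed * 3000 + length(base_vars))
    jumps <- c(jumps, abs(e_new - e_prev))
    base_vars <- c(base_vars, v); e_prev <- e_new
  }
  threshold <- mean(jumps)
  # step 3: ascending stepwise over the interpretation set
  final <- step2[1]
  err <- .rf_oob(X, y, final, ntree, seed * 4000)
  for (v in tail(step2, -1)) {
    e_new <- .rf_oob(X, y, c(final, v), ntree, seed * 4000 + length(final))
    if (err - e_new > threshold) {
      final <- c(final, v); err <- e_new
    }
  }
  list(vi_mean = vi_mean, vi_sd = vi_sd, step1_kept = step1,
       step2_kept = step2, final_kept = final, oob_curve = oob_curve,
       stepwise_threshold = threshold)
}

# --- classifier and cross-validation ----------------------------------------

#' Train the transport-mode random forest
#'
#' Probabilistic classification over the five transport modes; predictions
#' take the class of highest probability with ties broken by the fixed class
#' order of [ta_modes()]. Training rows are canonicalised (sorted) before
#' the seeded fit, so the model is invariant to input row order.
#'
#' @param X Feature data frame.
#' @param y Mode labels (character or factor).
#' @param n_trees Trees (default 500).
#' @param mtry Variables tried per split (default `sqrt(p)`).
#' @param max_nodes Optional maximum number of terminal nodes per tree
#'   (depth control).
#' @param seed Integer seed.
#' @return A `mode_model` object.
#' @export
train_mode_classifier <- function(X, y, n_trees = 500, mtry = NULL,
                                  max_nodes = NULL, seed = 1L) {
  classes <- TA_MODES[TA_MODES %in% unique(as.character(y))]
  if (!length(classes)) classes <- sort(unique(as.character(y)))
  y <- factor(as.character(y), levels = classes)
  ord <- do.call(order, c(unname(as.list(X)), list(as.integer(y))))
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  set.seed(seed)
  X <- randomForest::na.roughfix(X)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = mtry,
    maxnodes = max_nodes)
  structure(list(rf = rf, features = colnames(X), classes = classes),
            class = "mode_model")
}

#' Predict transport modes
#'
#' @param object A `mode_model`.
#' @param newdata Feature data frame containing the training features.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted modes, or a probability matrix (rows sum
#'   to 1).
#' @export
predict.mode_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop("features missing at predict time: ", paste(miss, collapse = ", "))
  nd <- newdata[, object$features, drop = FALSE]
  if (anyNA(nd)) nd <- randomForest::na.roughfix(nd)
  pr <- predict(object$rf, nd, type = "prob")
  pr <- pr[, object$classes, drop = FALSE]
  if (type == "prob") return(pr)
  idx <- apply(pr, 1, which.max)  # first max: fixed class-order tie-break
  factor(object$classes[idx], levels = object$classes)
}

.make_folds <- function(y, k, seed, groups = NULL) {
  n <- length(y)
  set.seed(seed)
  if (is.null(groups)) {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    return(fold)
  }
  gu <- unique(groups)
  gu <- sample(gu)
  sizes <- table(groups)[as.character(gu)]
  fsize <- numeric(k)
  gf <- integer(length(gu))
  for (i in order(sizes, decreasing = TRUE)) {
    f <- which.min(fsize)
    gf[i] <- f
    fsize[f] <- fsize[f] + sizes[i]
  }
  gf[match(groups, gu)]
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' k-fold cross-validation of the mode classifier
#'
#' The data are split into k mutually exclusive folds of (near) equal size;
#' each fold is held out once, a forest is trained on the rest, and pooled
#' held-out predictions give one-vs-rest confusion counts per mode. When
#' `groups` is given (e.g. trip ids) whole groups are held out together so
#' minutes of one trip never straddle the train/validation split. If a class
#' is absent from some training fold the split is redone stratified by
#' class, with a warning.
#'
#' @param X Feature data frame.
#' @param y Mode labels.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param groups Optional grouping vector (same length as `y`).
#' @param n_trees Trees per fold model.
#' @return List with `fold` assignment, `pred`, pooled `confusion` and
#'   `metrics` per class, `fold_errors`, `mean_error` and `macro_f1`.
#' @export
crossvalidate <- function(X, y, k = 10, seed = 1L, groups = NULL,
                          n_trees = 100) {
  y <- factor(as.character(y))
  n <- length(y)
  stopifnot(n >= k)
  fold <- .make_folds(y, k, seed, groups)
  bad <- any(vapply(seq_len(k), function(f)
    !all(levels(y) %in% y[fold != f]), logical(1)))
  if (bad) {
    warning("a class was absent from a training fold; refolding stratified",
            " by class")
    fold <- .stratified_folds(y, k, seed)
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_errors <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- train_mode_classifier(X[tr, , drop = FALSE], y[tr],
                               n_trees = n_trees, seed = seed + f)
    ph <- predict(m, X[!tr, , drop = FALSE])
    pred[!tr] <- as.character(ph)
    fold_errors[f] <- mean(as.character(ph) != as.character(y[!tr]))
  }
  conf <- lapply(levels(y), function(cl)
    confusion(as.character(pred), as.character(y), positive = cl))
  names(conf) <- levels(y)
  mets <- lapply(conf, classification_metrics)
  macro_f1 <- mean(vapply(mets, function(m) m$f1, numeric(1)), na.rm = TRUE)
  list(fold = fold, pred = pred, confusion = conf, metrics = mets,
       fold_errors = fold_errors, mean_error = mean(fold_errors),
       macro_f1 = macro_f1)
}
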