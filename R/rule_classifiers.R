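# Steps 4-5: rule-based GPS gap interpolation, indoor/outdoor separation and
# sleep detection, all driven by participant-specific quantile thresholds so
# that sensor units never matter.

#' Participant-specific quantile threshold
#'
#' @param series Numeric per-minute series (missing-aware).
#' @param q Quantile in (0, 1); linear interpolation convention.
#' @return Scalar threshold.
#' @export
derive_threshold <- function(series, q) {
  v <- series[!is.na(series)]
  if (!length(v)) stop("cannot derive a threshold from an all-missing series")
  quantile(v, q, names = FALSE, type = 7)
}

#' Centred first difference per minute
#'
#' Derivative of a channel (e.g. PM10) on the minute grid; endpoints use
#' one-sided differences. The derivative of a constant series is identically
#' zero.
#'
#' @param x Numeric series on a regular 1-minute grid.
#' @return Numeric derivative (units per minute).
#' @export
centred_derivative <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Derive the full participant threshold set
#'
#' @param trace Resampled trace (>= 1 day recommended).
#' @param cfg Configuration: quantiles `sat_q`, `accel_q`, `mic_q`, `dpm10_q`.
#' @return List with `sat_thr` (on valid-fix satellite counts), `accel_thr`,
#'   `mic_thr` and `dpm10_thr` (on `|dPM10/dt|`; `NA` when PM10 absent).
#' @export
derive_thresholds <- function(trace, cfg = ta_config()) {
  ok <- valid_fix(trace)
  dpm <- if (!is.null(trace$pm10) && any(!is.na(trace$pm10)))
    derive_threshold(abs(centred_derivative(trace$pm10)), cfg$dpm10_q)
  else NA_real_
  list(sat_thr = derive_threshold(trace$n_sat[ok], cfg$sat_q),
       accel_thr = derive_threshold(trace$accel, cfg$accel_q),
       mic_thr = derive_threshold(trace$mic, cfg$mic_q),
       dpm10_thr = dpm, method = "quantile")
}

#' Interpolate GPS gaps
#'
#' For each run of missing-fix minutes bounded by valid fixes: if the
#' bounding fixes are within `fill_radius_m` of each other and the run is no
#' longer than `max_gap_min`, the run is filled with the last-known position
#' and inherits its static label (the unit did not move); if the bounding
#' fixes are far apart the run is a transit candidate; runs longer than
#' `max_gap_min` and leading/trailing runs stay unclassified (no
#' extrapolation).
#'
#' @param trace Projected trace on the minute grid.
#' @param labels Character labels per minute (static microenvironment labels
#'   from Steps 1-3; `NA` where unknown).
#' @param cfg Configuration: `max_gap_min`, `fill_radius_m`.
#' @return List with `trace` (positions filled), `labels` (propagated),
#'   `fill` (logical: minute was imputed), `transit_candidate` (logical).
#' @export
interpolate_gaps <- function(trace, labels, cfg = ta_config()) {
  ok <- valid_fix(trace)
  n <- nrow(trace)
  fill <- logical(n)
  transit_candidate <- logical(n)
  static_labels <- c("home", "work", "home_in", "home_out", "work_in",
                     "work_out", "other_in", "other_out", "sleep")
  is_static <- function(l) !is.na(l) & (l %in% static_labels |
                                        startsWith(l, "other"))
  r <- rle(!ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == n) next            # no extrapolation
    len <- i1 - i0 + 1
    if (len > cfg$max_gap_min) next
    a <- i0 - 1; b <- i1 + 1
    disp <- sqrt((trace$x[b] - trace$x[a])^2 + (trace$y[b] - trace$y[a])^2)
    if (disp <= cfg$fill_radius_m) {
      trace$x[i0:i1] <- trace$x[a]
      trace$y[i0:i1] <- trace$y[a]
      fill[i0:i1] <- TRUE
      lab <- if (is_static(labels[a])) labels[a]
             else if (is_static(labels[b])) labels[b] else NA_character_
      if (!is.na(lab)) labels[i0:i1] <- lab
    } else {
      transit_candidate[i0:i1] <- TRUE
    }
  }
  list(trace = trace, labels = labels, fill = fill,
       transit_candidate = transit_candidate)
}

# Merge runs shorter than min_run into their neighbours, shortest run first.
.merge_short_runs <- function(flags, min_run) {
  if (!length(flags) || min_run <= 1) return(flags)
  repeat {
    r <- rle(flags)
    if (length(r$lengths) <= 1) return(flags)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(flags)
    k <- short[which.min(r$lengths[short])]
    r$values[k] <- !r$values[k]
    flags <- inverse.rle(r)
  }
}

#' Separate indoor from outdoor static minutes
#'
#' A static minute is outdoor iff the satellite count and the acceleration
#' both reach their participant-specific thresholds (good sky view and a
#' person moving about outside); runs shorter than `io_min_run_min` are
#' merged into their neighbours to suppress flicker. Applied within the
#' static microenvironments so home/work/other each split into `_in`/`_out`.
#'
#' @param trace Minute-grid trace (gap-filled).
#' @param labels Labels with static microenvironment names (`home`, `work`,
#'   `other_k`).
#' @param thr Threshold set from [derive_thresholds()].
#' @param cfg Configuration: `io_min_run_min`.
#' @return Character labels with static minutes suffixed `_in`/`_out`.
#' @export
classify_indoor_outdoor <- function(trace, labels, thr, cfg = ta_config()) {
  static <- !is.na(labels) & (labels %in% c("home", "work") |
                              startsWith(labels, "other"))
  if (!any(static)) return(labels)
  sat <- trace$n_sat
  outdoor <- !is.na(sat) & sat >= thr$sat_thr &
    !is.na(trace$accel) & trace$accel >= thr$accel_thr
  # merge short runs inside each contiguous static block
  blocks <- rle(static)
  ends <- cumsum(blocks$lengths); starts <- ends - blocks$lengths + 1
  for (k in seq_along(blocks$lengths)) {
    if (!blocks$values[k]) next
    span <- starts[k]:ends[k]
    outdoor[span] <- .merge_short_runs(outdoor[span], cfg$io_min_run_min)
  }
  suff <- ifelse(outdoor, "_out", "_in")
  base <- labels
  base[static & startsWith(labels, "other")] <- "other"
  labels[static] <- paste0(base[static], suff[static])
  labels
}

#' Smooth a binary series with a rolling majority vote
#'
#' Centred rolling window; a strict majority of TRUE (FALSE) forces TRUE
#' (FALSE); ties keep the prior value. Removes small disruptions such as
#' brief wake blips inside a sleep block.
#'
#' @param flags Logical vector.
#' @param window Window width in minutes (default 10).
#' @return Smoothed logical vector.
#' @export
smooth_binary <- function(flags, window = 10) {
  n <- length(flags)
  if (n == 0 || window <= 1) return(flags)
  half_lo <- floor(window / 2)
  half_hi <- ceiling(window / 2) - 1
  cs <- cumsum(c(0, as.integer(flags)))
  out <- flags
  for (i in seq_len(n)) {
    a <- max(1, i - half_lo); b <- min(n, i + half_hi)
    ntrue <- cs[b + 1] - cs[a]
    w <- b - a + 1
    if (2 * ntrue > w) out[i] <- TRUE
    else if (2 * ntrue < w) out[i] <- FALSE
    # tie: keep prior value
  }
  out
}

#' Detect sleep within the indoor home microenvironment
#'
#' A minute is sleep iff noise and movement are below their
#' participant-specific thresholds and, when PM10 is measured, the coarse
#' particle concentration is not changing rapidly (resuspension of large
#' particles indicates physical activity in the room). The binary series is
#' then smoothed over a rolling window. Sleep is only claimed within
#' `home_in` minutes.
#'
#' @param trace Minute-grid trace.
#' @param labels Labels after indoor/outdoor separation.
#' @param thr Threshold set from [derive_thresholds()].
#' @param cfg Configuration: `sleep_smooth_min`.
#' @return Labels with sleeping `home_in` minutes relabelled `sleep`.
#' @export
classify_sleep <- function(trace, labels, thr, cfg = ta_config()) {
  home_in <- !is.na(labels) & labels == "home_in"
  quiet <- !is.na(trace$mic) & trace$mic < thr$mic_thr &
    !is.na(trace$accel) & trace$accel < thr$accel_thr
  if (!is.null(trace$pm10) && !is.na(thr$dpm10_thr)) {
    dpm <- abs(centred_derivative(trace$pm10))
    quiet <- quiet & (is.na(trace$pm10) | dpm < thr$dpm10_thr)
  }
  sleep <- smooth_binary(home_in & quiet, cfg$sleep_smooth_min)
  labels[sleep & home_in] <- "sleep"
  labels
}
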