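#' Default model configuration
#'
#' All tunable thresholds and seeds of the six-step classifier in one flat
#' list. Values can be overridden per call or loaded from a JSON file with
#' [load_config()].
#'
#' @param ... Named overrides of individual keys.
#' @return Named list of configuration values.
#' @details Keys (units in brackets):
#'   * Step 1 `night_window` (local clock hours, half-open), `sep_min_m`,
#'     `minor_frac`, `spread_clamp_m`, `min_night_points`, `seed`.
#'   * Step 2 `s` (time-scaling coefficient), `a_target_neighbors`,
#'     `isopleth_level`, `ecc_quantile`, `density_quantile`.
#'   * Step 3 `ivg_hours`, `eps_m`, `min_pts`, `work_min_visits`,
#'     `work_min_duration_min`, `mnlv_static_min`.
#'   * Steps 4-5 `max_gap_min`, `fill_radius_m`, `sat_q`, `accel_q`, `mic_q`,
#'     `dpm10_q`, `sleep_smooth_min`, `io_min_run_min`.
#'   * Step 6 `stop_max_min`, `lavielle_lmin`, `lavielle_kmax`,
#'     `lavielle_threshold`, `n_trees`, `vi_runs`, `gis_buffer_line_m`,
#'     `gis_buffer_stop_m`, `cv_folds`.
#' @export
ta_config <- function(...) {
  cfg <- list(
    # Step 1: home identification
    night_window = c(2, 4), sep_min_m = 300, minor_frac = 0.10,
    spread_clamp_m = c(60, 500), min_night_points = 30, seed = 1L,
    # Step 2: space use
    s = 0.05, a_target_neighbors = 10, isopleth_level = 0.95,
    ecc_quantile = 0.75, density_quantile = 0.50,
    # Step 3: time use
    ivg_hours = 12, eps_m = 150, min_pts = 10, work_min_visits = 3,
    work_min_duration_min = 60, mnlv_static_min = 10,
    # Steps 4-5: gap filling, indoor/outdoor, sleep
    max_gap_min = 240, fill_radius_m = 100, sat_q = 0.60, accel_q = 0.70,
    mic_q = 0.30, dpm10_q = 0.80, sleep_smooth_min = 10, io_min_run_min = 5,
    # Step 6: transit
    stop_max_min = 20, lavielle_lmin = 3, lavielle_kmax = 10,
    lavielle_threshold = 0.75, n_trees = 500, vi_runs = 50,
    gis_buffer_line_m = 25, gis_buffer_stop_m = 50, cv_folds = 10
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Load configuration from a JSON file
#'
#' Missing keys fall back to [ta_config()] defaults.
#'
#' @param path JSON file with a flat object of config keys.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ta_config, raw)
}

#' Save configuration to a JSON file
#'
#' @param cfg Configuration list as returned by [ta_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
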