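# Step 1: home identification from night-time docked records and the
# elliptical home buffer zone.

#' Night-time docked record subset
#'
#' Indices of minutes where the unit is docked, the local clock falls inside
#' the night window (half-open), and the fix is valid. Most people are at
#' home in the small hours, so these fixes scatter around the home location.
#'
#' @param trace Resampled trace.
#' @param window Local-clock window in hours, half-open `[from, to)`
#'   (default `c(2, 4)`); configurable for shift workers.
#' @param tz_offset Minutes added to UTC to obtain local time (defaults to
#'   the trace attribute).
#' @return Integer row indices (possibly empty).
#' @export
night_dock_subset <- function(trace, window = c(2, 4), tz_offset = NULL) {
  tz_offset <- tz_offset %||% attr(trace, "tz_offset_minutes") %||% 0L
  local <- trace$t + tz_offset * 60
  hr <- as.numeric(format(local, "%H", tz = "UTC")) +
    as.numeric(format(local, "%M", tz = "UTC")) / 60
  in_win <- if (window[1] <= window[2]) hr >= window[1] & hr < window[2]
            else hr >= window[1] | hr < window[2]  # window across midnight
  which(in_win & !is.na(trace$dock_v) & trace$dock_v & valid_fix(trace))
}

#' Fit the elliptical home zone
#'
#' Centre-based clustering (k-means, k = 2) decides whether the night-time
#' docked fixes form a single cluster: they do iff the two centres are closer
#' than `sep_min_m` or the minor cluster holds less than `minor_frac` of the
#' points. A single cluster yields the home centroid and per-axis spread
#' distances ([home_zone_from_points()]), clamped to the observed plausible range
#' of 60-500 m; otherwise home is undetermined and is recovered from time-use
#' metrics in Step 3.
#'
#' @param x,y Projected night-dock fixes (metres).
#' @param cfg Configuration ([ta_config()]): `sep_min_m`, `minor_frac`,
#'   `spread_clamp_m`, `min_night_points`, `seed`.
#' @return A `home_zone` list (`cx`, `cy`, `d_x`, `d_y`,
#'   `determined_in_step1 = TRUE`) or `NULL` when undetermined.
#' @export
fit_home_zone <- function(x, y, cfg = ta_config()) {
  n <- length(x)
  if (n < cfg$min_night_points) return(NULL)
  pts <- cbind(x, y)
  single <- TRUE
  if (nrow(unique(pts)) > 1) {
    set.seed(cfg$seed)
    km <- kmeans(pts, centers = 2, nstart = 5)
    sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
    minor <- min(km$size) / n
    single <- sep < cfg$sep_min_m || minor < cfg$minor_frac
    if (single && minor < cfg$minor_frac && sep >= cfg$sep_min_m) {
      # a tiny far-away cluster is outlier noise; drop it from the estimate
      keep <- km$cluster == which.max(km$size)
      pts <- pts[keep, , drop = FALSE]
    }
  }
  if (!single) return(NULL)
  home_zone_from_points(pts[, 1], pts[, 2], cfg = cfg,
                        determined_in_step1 = TRUE)
}

#' Build a home zone from a point cloud
#'
#' Centroid plus per-axis spread distances, clamped (with a warning) to the
#' configured range. The spread is 2.45 x the MAD-based robust SD per axis:
#' the radius enclosing 95% of an isotropic bivariate normal scatter, so the
#' ellipse covers the bulk of the night-time fixes while resisting GPS
#' outliers.
#'
#' @param x,y Projected points (metres).
#' @param cfg Configuration list.
#' @param determined_in_step1 Provenance flag stored on the zone.
#' @return A `home_zone` list.
#' @export
home_zone_from_points <- function(x, y, cfg = ta_config(),
                                  determined_in_step1 = TRUE) {
  lo <- cfg$spread_clamp_m[1]; hi <- cfg$spread_clamp_m[2]
  d_x <- 2.45 * mad(x)
  d_y <- 2.45 * mad(y)
  if (d_x > hi || d_y > hi)
    warning("home spread exceeds ", hi, " m; clamped")
  structure(list(cx = mean(x), cy = mean(y),
                 d_x = min(max(d_x, lo), hi),
                 d_y = min(max(d_y, lo), hi),
                 determined_in_step1 = determined_in_step1),
            class = "home_zone")
}

#' Elliptical home-zone membership
#'
#' @param zone A `home_zone`.
#' @param x,y Projected coordinates.
#' @return Logical vector: inside the ellipse
#'   `((dx/d_x)^2 + (dy/d_y)^2) <= 1` (FALSE where coordinates are missing).
#' @export
in_home_zone <- function(zone, x, y) {
  r <- ((x - zone$cx) / zone$d_x)^2 + ((y - zone$cy) / zone$d_y)^2
  !is.na(r) & r <= 1
}

#' Label home minutes
#'
#' Every valid-fix minute inside the home ellipse is labelled `home`
#' (indoor/outdoor separation is deferred to Step 4); other minutes are left
#' unlabelled.
#'
#' @param trace Projected trace.
#' @param zone A `home_zone`.
#' @return Character vector, one per row: `"home"` or `NA`.
#' @export
label_home <- function(trace, zone) {
  lab <- rep(NA_character_, nrow(trace))
  ok <- valid_fix(trace)
  inside <- in_home_zone(zone, trace$x, trace$y)
  lab[ok & inside] <- "home"
  lab
}
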