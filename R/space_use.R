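# Step 2: space-use analysis with time-scaled-distance local convex hulls.
#
# Hulls built from a parent point and its adaptive nearest neighbours are
# local in both space and time; their geometry (bounding-ellipse
# eccentricity, perimeter-to-area ratio) and density separate directional
# movement from static clusters.

#' Time-scaled distance
#'
#' Pseudo-distance combining spatial separation with a velocity-scaled
#' temporal separation: `sqrt(dx^2 + dy^2 + (s * v_char * dt)^2)`. Symmetric,
#' always at least the Euclidean distance, and reduces to it when `dt = 0`
#' or `s = 0`.
#'
#' @param dx,dy Coordinate differences in metres.
#' @param dt Time difference in seconds.
#' @param s Dimensionless time-scaling coefficient.
#' @param v_char Characteristic velocity of the individual (m/s).
#' @return Distance in metres (vectorized).
#' @export
time_scaled_distance <- function(dx, dy, dt, s, v_char) {
  sqrt(dx^2 + dy^2 + (s * v_char * dt)^2)
}

#' Characteristic velocity of a trace
#'
#' Median of the strictly positive speeds between consecutive valid fixes.
#'
#' @param trace Projected trace (with `x`, `y`).
#' @return Speed in m/s (0 if no positive speeds exist).
#' @export
characteristic_velocity <- function(trace) {
  ok <- which(valid_fix(trace))
  if (length(ok) < 2) return(0)
  dx <- diff(trace$x[ok]); dy <- diff(trace$y[ok])
  dt <- diff(as.numeric(trace$t[ok]))
  v <- sqrt(dx^2 + dy^2) / dt
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) return(0)
  median(v)
}

#' Automatic adaptive radius
#'
#' The smallest cumulative-distance radius `a` such that the median
#' neighbour-set size reaches `target` points: the median over parents of
#' the cumulative time-scaled distance to each parent's `target` nearest
#' neighbours.
#'
#' @param trace Projected trace (valid fixes are used).
#' @param s,v_char Time-scaling parameters.
#' @param target Desired median neighbour count (default 10).
#' @return Radius `a` in metres.
#' @export
auto_a_value <- function(trace, s, v_char, target = 10) {
  ok <- which(valid_fix(trace))
  if (length(ok) < 2) return(1)
  a <- cpp_a_for_k(trace$x[ok], trace$y[ok], as.numeric(trace$t[ok]),
                   s * v_char, as.integer(target))
  max(median(a), .Machine$double.eps)
}

#' Adaptive nearest-neighbour selection
#'
#' For each parent point, neighbours sorted by time-scaled distance are
#' included while their cumulative TSD stays within `a`; the parent itself is
#' always a member. Dense areas therefore yield larger neighbour sets than
#' sparse areas.
#'
#' @param trace Projected trace; only valid fixes take part.
#' @param params List with `s`, `v_char`, `a_value` (see [space_use_params()]).
#' @return List with `idx` (row indices of the valid fixes used) and
#'   `neighbors` (list of index vectors into `idx`, parent included).
#' @export
adaptive_neighbors <- function(trace, params) {
  ok <- which(valid_fix(trace))
  nn <- cpp_adaptive_nn(trace$x[ok], trace$y[ok], as.numeric(trace$t[ok]),
                        params$s * params$v_char, params$a_value)
  list(idx = ok, neighbors = nn)
}

#' Derive space-use parameters for a trace
#'
#' @param trace Projected trace.
#' @param cfg Configuration list ([ta_config()]).
#' @return List with `s`, `v_char`, `a_value`, `isopleth_level`.
#' @export
space_use_params <- function(trace, cfg = ta_config()) {
  v <- characteristic_velocity(trace)
  a <- auto_a_value(trace, cfg$s, v, cfg$a_target_neighbors)
  list(s = cfg$s, v_char = v, a_value = a,
       isopleth_level = cfg$isopleth_level)
}

# Bounding-ellipse eccentricity from the 2x2 covariance of member points:
# ecc = sqrt(1 - lambda2/lambda1), eigenvalues analytic. Rank-deficient
# scatter (collinear or singleton members) has ecc 1 by convention.
.scatter_ecc <- function(x, y) {
  n <- length(x)
  if (n < 3) return(1)
  vx <- var(x); vy <- var(y); vxy <- cov(x, y)
  tr <- vx + vy
  if (tr <= 0) return(1)
  disc <- sqrt(max((vx - vy)^2 / 4 + vxy^2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(1)
  if (l2 <= 0) return(1)
  sqrt(max(1 - l2 / l1, 0))
}

.poly_area_perim <- function(p) {
  # p: matrix of hull vertices in order (not closed)
  n <- nrow(p)
  if (n < 3) return(c(area = 0, perim = 0))
  xs <- p[, 1]; ys <- p[, 2]
  j <- c(2:n, 1)
  area <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  perim <- sum(sqrt((xs[j] - xs)^2 + (ys[j] - ys)^2))
  c(area = area, perim = perim)
}

#' Build local convex hulls
#'
#' Binds each parent point and its adaptive nearest neighbours into a minimum
#' convex polygon and computes its geometry and visit metrics.
#'
#' @param trace Projected trace.
#' @param nn Neighbour structure from [adaptive_neighbors()].
#' @param ivg_hours Inter-visit gap defining separate visits (default 12 h).
#' @return List with `metrics` (data frame: `parent` row index, `density`
#'   member count, `area` m^2, `perim` m, `par` 1/m (`Inf` for degenerate
#'   zero-area hulls), `ecc`, `nsv`, `mnlv`, `degenerate`), `polygons`
#'   (list of vertex matrices), and `members` (list of trace row indices).
#' @export
build_hulls <- function(trace, nn, ivg_hours = 12) {
  idx <- nn$idx
  n <- length(idx)
  tt <- trace$t[idx]
  xs <- trace$x[idx]; ys <- trace$y[idx]
  density <- integer(n); area <- numeric(n); perim <- numeric(n)
  ecc <- numeric(n); nsv <- integer(n); mnlv <- numeric(n)
  polys <- vector("list", n); members <- vector("list", n)
  for (i in seq_len(n)) {
    m <- nn$neighbors[[i]]
    px <- xs[m]; py <- ys[m]
    density[i] <- length(m)
    h <- chull(px, py)
    poly <- cbind(px[h], py[h])
    ap <- .poly_area_perim(poly)
    area[i] <- ap["area"]; perim[i] <- ap["perim"]
    ecc[i] <- .scatter_ecc(px, py)
    vm <- visit_metrics(sort(tt[m]), ivg_hours = ivg_hours)
    nsv[i] <- vm$nsv; mnlv[i] <- vm$mnlv
    polys[[i]] <- poly
    members[[i]] <- idx[m]
  }
  par <- ifelse(area > 0, perim / area, Inf)
  list(metrics = data.frame(parent = idx, density = density, area = area,
                            perim = perim, par = par, ecc = ecc, nsv = nsv,
                            mnlv = mnlv, degenerate = area <= 0),
       polygons = polys, members = members)
}

#' Merge hulls into isopleths
#'
#' Hulls sorted by a key are accumulated until the union of their member
#' points first encloses at least `level` of all points; the remaining points
#' are outliers.
#'
#' @param hulls Hull set from [build_hulls()].
#' @param sort_key `"density"` (descending) or `"eccentricity"` (descending).
#' @param level Fraction of points to enclose (default 0.95).
#' @param decreasing Sort direction for the key.
#' @return List with `hull_order` (indices of hulls in the isopleth, in
#'   accumulation order), `enclosed` (trace row indices of enclosed points),
#'   `outliers` (row indices left out), `level`, `sort_key`.
#' @export
merge_isopleths <- function(hulls, sort_key = c("density", "eccentricity"),
                            level = 0.95, decreasing = TRUE) {
  sort_key <- match.arg(sort_key)
  stopifnot(length(hulls$members) > 0, level > 0, level <= 1)
  key <- if (sort_key == "density") hulls$metrics$density else
    hulls$metrics$ecc
  ord <- order(key, decreasing = decreasing)
  all_pts <- unique(unlist(hulls$members))
  need <- level * length(all_pts)
  enclosed <- integer(0)
  taken <- integer(0)
  for (i in ord) {
    taken <- c(taken, i)
    enclosed <- union(enclosed, hulls$members[[i]])
    if (length(enclosed) >= need) break
  }
  list(hull_order = taken, enclosed = sort(enclosed),
       outliers = sort(setdiff(all_pts, enclosed)),
       level = level, sort_key = sort_key)
}

#' Classify minutes as static or in movement
#'
#' A parent minute is in movement iff its hull eccentricity reaches the
#' participant-specific eccentricity threshold and its density does not
#' exceed the density threshold; all other hull minutes are static.
#' Thresholds are quantiles of the participant's own hull metrics.
#'
#' @param hulls Hull set from [build_hulls()].
#' @param ecc_quantile Quantile of hull eccentricity for the cut (default .75).
#' @param density_quantile Quantile of hull density for the cut (default .50).
#' @return Data frame with `row` (trace row index of the parent) and `motion`
#'   (`"static"` or `"movement"`), plus attributes `ecc_threshold`,
#'   `density_threshold`.
#' @export
classify_motion <- function(hulls, ecc_quantile = 0.75,
                            density_quantile = 0.50) {
  m <- hulls$metrics
  ecc_thr <- quantile(m$ecc, ecc_quantile, na.rm = TRUE, names = FALSE)
  den_thr <- quantile(m$density, density_quantile, na.rm = TRUE,
                      names = FALSE)
  movement <- m$ecc >= ecc_thr & m$density <= den_thr
  structure(data.frame(row = m$parent,
                       motion = ifelse(movement, "movement", "static")),
            ecc_threshold = ecc_thr, density_threshold = den_thr)
}
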