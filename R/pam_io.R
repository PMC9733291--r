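# Reading, resampling, projecting and writing personal-monitor traces.
#
# A trace is a data frame (class `ta_trace`) with one row per sample/minute:
#   t      POSIXct, UTC
#   lon,lat degrees WGS84 (NA when the fix is missing)
#   n_sat  visible satellite count
#   accel  acceleration magnitude (sensor units)
#   mic    noise level (sensor units)
#   dock_v logical: unit docked in its charging base station
#   pm10, pm25, o3, no, no2, rh, temp  optional channels
# Attributes: participant_id, tz_offset_minutes, n_malformed.

TA_MANDATORY <- c("t", "accel", "mic", "n_sat", "dock_v")
TA_CHANNELS <- c("lon", "lat", "n_sat", "accel", "mic",
                 "pm10", "pm25", "o3", "no", "no2", "rh", "temp")

.ta_trace <- function(df, participant_id = "p1", tz_offset = 0L,
                      n_malformed = 0L) {
  rownames(df) <- NULL
  structure(df, class = c("ta_trace", "data.frame"),
            participant_id = participant_id,
            tz_offset_minutes = as.integer(tz_offset),
            n_malformed = as.integer(n_malformed))
}

.keep_trace_attrs <- function(df, template) {
  .ta_trace(as.data.frame(df),
            participant_id = attr(template, "participant_id"),
            tz_offset = attr(template, "tz_offset_minutes") %||% 0L,
            n_malformed = attr(template, "n_malformed") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a fix valid?
#'
#' A fix is valid iff longitude and latitude are present and the satellite
#' count is at least 3 (the minimum for a positional solution). Fix validity
#' is itself a classifier input: loss of valid fixes indicates indoor
#' microenvironments.
#'
#' @param trace A trace data frame.
#' @return Logical vector, one element per row.
#' @export
valid_fix <- function(trace) {
  !is.na(trace$lon) & !is.na(trace$lat) &
    !is.na(trace$n_sat) & trace$n_sat >= 3
}

#' Load a trace CSV
#'
#' Comma-separated, ISO-8601 timestamps (UTC), `.` decimal, header mandatory.
#' Rows are time-sorted; duplicate timestamps are collapsed by averaging
#' (docking by majority); rows with unparseable timestamps are dropped and
#' counted in the `n_malformed` attribute. A row with only one of lon/lat
#' present has its position marked missing.
#'
#' @param path CSV file with columns
#'   `t,lon,lat,n_sat,accel,mic,dock_v,pm10,pm25,o3,no,no2,rh,temp`
#'   (optional columns may be absent).
#' @param tz_offset Minutes to add to UTC to obtain the participant's local
#'   clock (used by the night-window rule).
#' @param participant_id Identifier stored on the trace.
#' @return A `ta_trace` data frame.
#' @export
load_trace <- function(path, tz_offset = 0L, participant_id = "p1") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trace file: ", path)
  miss <- setdiff(TA_MANDATORY, names(df))
  if (length(miss))
    stop("trace file missing mandatory columns: ", paste(miss, collapse = ", "))
  t <- as.POSIXct(df$t, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad <- is.na(t)
  n_malformed <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  df$t <- t[!bad]
  if (nrow(df) == 0) stop("no parseable rows in: ", path)
  for (ch in intersect(TA_CHANNELS, names(df)))
    df[[ch]] <- suppressWarnings(as.numeric(df[[ch]]))
  df$dock_v <- as.logical(df$dock_v)
  # a position needs both coordinates
  half <- xor(is.na(df$lon), is.na(df$lat))
  df$lon[half] <- NA_real_
  df$lat[half] <- NA_real_
  out_of_range <- !is.na(df$lon) &
    (abs(df$lon) > 180 | abs(df$lat) > 90)
  df$lon[out_of_range] <- NA_real_
  df$lat[out_of_range] <- NA_real_
  df <- df[order(df$t), , drop = FALSE]
  if (anyDuplicated(df$t)) df <- .collapse_dups(df)
  keep <- c("t", intersect(TA_CHANNELS, names(df)), "dock_v")
  .ta_trace(df[, keep, drop = FALSE], participant_id = participant_id,
            tz_offset = tz_offset, n_malformed = n_malformed)
}

.collapse_dups <- function(df) {
  key <- as.numeric(df$t)
  num <- intersect(TA_CHANNELS, names(df))
  agg <- lapply(df[num], function(v) tapply(v, key, mean, na.rm = TRUE))
  dock <- tapply(df$dock_v, key, function(v) mean(v, na.rm = TRUE) >= 0.5)
  uk <- sort(unique(key))
  out <- data.frame(t = as.POSIXct(uk, origin = "1970-01-01", tz = "UTC"))
  for (ch in num) out[[ch]] <- as.numeric(agg[[ch]][as.character(uk)])
  out$dock_v <- as.logical(dock[as.character(uk)])
  for (ch in num) out[[ch]][is.nan(out[[ch]])] <- NA_real_
  out
}

#' Resample a trace to a 1-minute cadence
#'
#' Numeric channels are averaged over the samples available in each calendar
#' minute (missing-aware); the position mean uses only samples with a present
#' position; docking is decided by majority; minutes with no samples are
#' absent from the result.
#'
#' @param trace A `ta_trace` at cadence <= 60 s.
#' @return A `ta_trace` with one row per observed calendar minute.
#' @export
resample_minutely <- function(trace) {
  minute <- floor(as.numeric(trace$t) / 60) * 60
  num <- intersect(TA_CHANNELS, names(trace))
  uk <- sort(unique(minute))
  out <- data.frame(t = as.POSIXct(uk, origin = "1970-01-01", tz = "UTC"))
  f <- factor(minute, levels = uk)
  for (ch in num) {
    m <- tapply(trace[[ch]], f, mean, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[[ch]] <- as.numeric(m)
  }
  # position mean only over samples with valid coordinates (pairwise)
  has_pos <- !is.na(trace$lon) & !is.na(trace$lat)
  out$lon <- as.numeric(tapply(ifelse(has_pos, trace$lon, NA), f, mean,
                               na.rm = TRUE))
  out$lat <- as.numeric(tapply(ifelse(has_pos, trace$lat, NA), f, mean,
                               na.rm = TRUE))
  out$lon[is.nan(out$lon)] <- NA_real_
  out$lat[is.nan(out$lat)] <- NA_real_
  if ("n_sat" %in% names(out)) out$n_sat <- round(out$n_sat)
  out$dock_v <- as.logical(
    tapply(trace$dock_v, f, function(v) mean(v, na.rm = TRUE) >= 0.5))
  .keep_trace_attrs(out, trace)
}

#' Project a trace to UTM metres
#'
#' The zone is fixed for the whole trace from the centroid longitude of its
#' valid fixes (a conformal projection is shape-preserving at city scale even
#' when a trace straddles a zone boundary). Missing fixes stay missing.
#'
#' @param trace A `ta_trace` with at least one valid fix.
#' @return The trace with `x`, `y` columns (metres) and attributes
#'   `utm_zone`, `utm_south`.
#' @export
project_utm <- function(trace) {
  ok <- valid_fix(trace)
  if (!any(ok)) stop("no valid fixes to project")
  zone <- utm_zone(mean(trace$lon[ok]))
  south <- mean(trace$lat[ok]) < 0
  xy <- lonlat_to_utm(trace$lon, trace$lat, zone, south)
  trace$x <- ifelse(ok, xy$x, NA_real_)
  trace$y <- ifelse(ok, xy$y, NA_real_)
  attr(trace, "utm_zone") <- zone
  attr(trace, "utm_south") <- south
  trace
}

#' Write and re-read per-minute labels
#'
#' @param labels Data frame with columns `t`, `label`, `provenance`.
#' @param path CSV path.
#' @return `path` invisibly (`write_labels`); the labels data frame
#'   (`read_labels`).
#' @export
write_labels <- function(labels, path) {
  out <- data.frame(t = format(labels$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    label = labels$label,
                    provenance = labels$provenance)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$t <- as.POSIXct(df$t, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  df
}

#' Export classification results
#'
#' Writes the per-minute labels as CSV and the hulls (or isopleths) as a
#' GeoJSON FeatureCollection of WGS84 polygons carrying the hull metrics as
#' properties.
#'
#' @param labels Data frame `t,label,provenance`.
#' @param hulls Hull set from [build_hulls()] (may be empty), with polygons in
#'   projected metres.
#' @param out_dir Output directory (created if needed).
#' @param zone,south UTM zone of the hull coordinates.
#' @return Named character vector of written paths, invisibly.
#' @export
export_results <- function(labels, hulls, out_dir, zone = 31L, south = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lab_path <- file.path(out_dir, "labels.csv")
  write_labels(labels, lab_path)
  gj_path <- file.path(out_dir, "hulls.geojson")
  write_hulls_geojson(hulls, gj_path, zone = zone, south = south)
  invisible(c(labels = lab_path, hulls = gj_path))
}

#' Write hulls as GeoJSON
#'
#' @inheritParams export_results
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_hulls_geojson <- function(hulls, path, zone = 31L, south = FALSE) {
  feats <- list()
  if (!is.null(hulls) && length(hulls$polygons)) {
    m <- hulls$metrics
    for (i in seq_along(hulls$polygons)) {
      poly <- hulls$polygons[[i]]
      ll <- utm_to_lonlat(poly[, 1], poly[, 2], zone, south)
      ring <- cbind(ll$lon, ll$lat)
      ring <- rbind(ring, ring[1, , drop = FALSE])  # closed ring
      feats[[i]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(r) ring[r, ]))),
        properties = list(eccentricity = m$ecc[i], par = m$par[i],
                          density = m$density[i], nsv = m$nsv[i],
                          mnlv = m$mnlv[i]))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a GIS network GeoJSON file
#'
#' Expects a FeatureCollection of LineString features with property
#' `kind` in highway/railway/sidewalk/cycleway/busway and Point features with
#' `kind` in bus_stop/train_stop. Coordinates are WGS84 and are projected to
#' the given UTM zone.
#'
#' @param path GeoJSON file.
#' @param zone,south UTM zone to project into.
#' @return List with `lines` (named list of coordinate matrices per kind,
#'   possibly several per kind) and `stops` (named list of point matrices).
#' @export
read_network <- function(path, zone, south = FALSE) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lines <- list(); stops <- list()
  for (ft in gj$features %||% list()) {
    kind <- ft$properties$kind %||% NA_character_
    geom <- ft$geometry
    if (is.null(geom) || is.na(kind)) next
    if (identical(geom$type, "LineString")) {
      cc <- do.call(rbind, lapply(geom$coordinates,
                                  function(p) c(p[[1]], p[[2]])))
      xy <- lonlat_to_utm(cc[, 1], cc[, 2], zone, south)
      lines[[length(lines) + 1]] <- list(kind = kind,
                                         coords = cbind(xy$x, xy$y))
    } else if (identical(geom$type, "Point")) {
      xy <- lonlat_to_utm(geom$coordinates[[1]], geom$coordinates[[2]],
                          zone, south)
      stops[[length(stops) + 1]] <- list(kind = kind,
                                         coords = c(xy$x, xy$y))
    } else {
      stop("unsupported geometry type in network feature: ", geom$type)
    }
  }
  list(lines = lines, stops = stops)
}

#' Write a GIS network to GeoJSON
#'
#' @param network List as returned by [read_network()] but in WGS84 lon/lat
#'   (`coords` matrices of lon/lat), or as built by [scenario_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  feats <- list()
  for (ln in network$lines) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(ln$coords)),
                                           function(r) ln$coords[r, ])),
      properties = list(kind = ln$kind))
  }
  for (st in network$stops) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = st$coords),
      properties = list(kind = st$kind))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write a trace as CSV
#'
#' @param trace A `ta_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- as.data.frame(trace)
  out$x <- NULL; out$y <- NULL
  out$t <- format(out$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-channel completeness report
#'
#' Fraction of minutes with a non-missing value, per channel.
#'
#' @param trace A `ta_trace`.
#' @return Named numeric vector of completeness fractions.
#' @export
channel_completeness <- function(trace) {
  ch <- intersect(TA_CHANNELS, names(trace))
  vapply(trace[ch], function(v) mean(!is.na(v)), numeric(1))
}
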