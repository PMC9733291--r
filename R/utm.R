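# Conformal Universal Transverse Mercator projection on the WGS84 ellipsoid,
# series expansion form (USGS professional paper 1395 conventions).
# Round-trip error is far below the 1e-6 degree contract used downstream.

.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563, k0 = 0.9996)

.utm_consts <- function() {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f)
  list(a = a, e2 = e2, ep2 = e2 / (1 - e2), k0 = .wgs84$k0)
}

#' UTM zone for a longitude
#'
#' @param lon Longitude in degrees.
#' @return Integer zone number (1-60).
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

.merid_arc <- function(phi, cst) {
  e2 <- cst$e2
  cst$a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
           (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
           (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
           (35 * e2^3 / 3072) * sin(6 * phi))
}

#' Project geographic coordinates to UTM
#'
#' @param lon,lat Degrees (WGS84); vectors, may contain `NA`.
#' @param zone UTM zone number; all points are projected into this zone.
#' @param south Logical; `TRUE` applies the southern false northing.
#' @return Data frame with columns `x`, `y` in metres.
#' @export
lonlat_to_utm <- function(lon, lat, zone, south = FALSE) {
  cst <- .utm_consts()
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- (zone * 6 - 183) * pi / 180
  e2 <- cst$e2; ep2 <- cst$ep2; k0 <- cst$k0
  N <- cst$a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- .merid_arc(phi, cst)
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
             (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) y <- y + 1e7
  data.frame(x = x, y = y)
}

#' Inverse UTM projection
#'
#' @param x,y Metres (UTM easting/northing); vectors, may contain `NA`.
#' @param zone UTM zone number used for the forward projection.
#' @param south Logical; `TRUE` if the southern false northing was applied.
#' @return Data frame with columns `lon`, `lat` in degrees.
#' @export
utm_to_lonlat <- function(x, y, zone, south = FALSE) {
  cst <- .utm_consts()
  e2 <- cst$e2; ep2 <- cst$ep2; k0 <- cst$k0; a <- cst$a
  if (south) y <- y - 1e7
  xs <- x - 500000
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- xs / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam0 <- (zone * 6 - 183) * pi / 180
  lam <- lam0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                 (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
                 D^5 / 120) / cos(phi1)
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}
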