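# trace loading, minute resampling, projection, export

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("load_trace parses, sorts and flags half-missing positions", {
  f <- write_csv_fixture(c(
    "t,lon,lat,n_sat,accel,mic,dock_v",
    "2024-03-04T10:02:00,0.101,51.5,8,0.2,0.4,FALSE",
    "2024-03-04T10:00:00,0.100,51.5,9,0.1,0.3,TRUE",
    "2024-03-04T10:01:00,0.102,,7,0.3,0.5,FALSE"))
  tr <- load_trace(f)
  expect_equal(nrow(tr), 3)
  expect_true(!is.unsorted(tr$t))
  expect_equal(tr$accel, c(0.1, 0.3, 0.2))
  # row with lat blank has its whole position marked missing
  expect_true(is.na(tr$lon[2]) && is.na(tr$lat[2]))
  expect_false(anyNA(tr$lon[c(1, 3)]))
})

test_that("load_trace errors on missing mandatory columns and empty files", {
  f <- write_csv_fixture(c("t,lon,lat", "2024-03-04T10:00:00,0.1,51.5"))
  expect_error(load_trace(f), "mandatory")
  f2 <- write_csv_fixture(character(0))
  expect_error(load_trace(f2))
})

test_that("duplicate timestamps collapse by averaging", {
  f <- write_csv_fixture(c(
    "t,lon,lat,n_sat,accel,mic,dock_v",
    "2024-03-04T10:00:00,0.1,51.5,9,1,0.3,TRUE",
    "2024-03-04T10:00:00,0.1,51.5,9,3,0.5,TRUE"))
  tr <- load_trace(f)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$accel, 2)
  expect_equal(tr$mic, 0.4)
})

test_that("resampling averages within minutes, missing-aware", {
  t0 <- as.POSIXct("2024-03-04 10:00:00", tz = "UTC")
  tr <- make_trace(3, t0 = t0)
  tr$t <- t0 + c(0, 20, 40)
  tr$accel <- c(1, 2, 3)
  tr$lon <- c(0.1, NA, 0.3); tr$lat <- c(51, NA, 52)
  out <- resample_minutely(tr)
  expect_equal(nrow(out), 1)
  expect_equal(out$accel, 2)
  expect_equal(out$lon, 0.2)   # mean over the two present fixes only
  expect_equal(out$lat, 51.5)
})

test_that("resampling a 20 s trace matches a group-by-minute oracle and
           conserves channel mass", {
  set.seed(42)
  n <- 3 * 180  # one hour at 20 s
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  tr <- make_trace(n, t0 = t0)
  tr$t <- t0 + 20 * (seq_len(n) - 1)
  tr$accel <- runif(n)
  tr$mic <- rnorm(n)
  out <- resample_minutely(tr)
  key <- floor(as.numeric(tr$t) / 60)
  oracle <- tapply(tr$accel, key, mean)
  expect_equal(out$accel, as.numeric(oracle))
  # mass conservation: minute means times sample counts recover the total
  counts <- as.numeric(table(key))
  expect_equal(sum(out$accel * counts), sum(tr$accel))
  expect_equal(sum(out$mic * counts), sum(tr$mic))
})

test_that("UTM projection round-trips and preserves local distances", {
  set.seed(1)
  lon <- runif(1000, -0.5, 0.5); lat <- runif(1000, 51, 52)
  xy <- lonlat_to_utm(lon, lat, zone = 31)
  ll <- utm_to_lonlat(xy$x, xy$y, zone = 31)
  expect_lt(max(abs(ll$lon - lon)), 1e-6)
  expect_lt(max(abs(ll$lat - lat)), 1e-6)
  # 0.001 degrees of latitude is ~111 m
  a <- lonlat_to_utm(0.1, 51.5, zone = 31)
  b <- lonlat_to_utm(0.1, 51.501, zone = 31)
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  if (requireNamespace("geosphere", quietly = TRUE)) {
    ref <- geosphere::distGeo(c(0.1, 51.5), c(0.1, 51.501))
  } else ref <- 111.2
  expect_lt(abs(d - ref) / ref, 0.01)
})

test_that("projecting identical fixes gives identical coordinates", {
  tr <- make_trace(5, lon = 0.25, lat = 51.6)
  out <- project_utm(tr)
  expect_equal(length(unique(out$x)), 1)
  expect_equal(length(unique(out$y)), 1)
  tr$lon[] <- NA; tr$lat[] <- NA
  expect_error(project_utm(tr), "no valid fixes")
})

test_that("labels round-trip through CSV and hull export is valid GeoJSON", {
  labels <- data.frame(
    t = as.POSIXct("2024-03-04 00:00:00", tz = "UTC") + 60 * 0:9,
    label = rep(c("home_in", "walk"), 5),
    provenance = rep("step1", 10))
  d <- tempfile(); dir.create(d)
  out <- export_results(labels, NULL, d, zone = 31)
  back <- read_labels(out[["labels"]])
  expect_equal(back$label, labels$label)
  expect_equal(as.numeric(back$t), as.numeric(labels$t))
  # re-exporting the re-read labels is a fixed point
  f2 <- tempfile(fileext = ".csv")
  write_labels(back, f2)
  expect_equal(read_labels(f2), back)
  # empty hull set: a valid empty FeatureCollection
  gj <- jsonlite::read_json(out[["hulls"]])
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 0)
  # one triangular hull: a closed 4-point ring
  tri <- list(metrics = data.frame(ecc = 0.5, par = 0.1, density = 3,
                                   nsv = 1, mnlv = 3),
              polygons = list(cbind(c(0, 100, 0) + 500000,
                                    c(0, 0, 100) + 5700000)))
  f3 <- tempfile(fileext = ".geojson")
  write_hulls_geojson(tri, f3, zone = 31)
  gj2 <- jsonlite::read_json(f3)
  ring <- gj2$features[[1]]$geometry$coordinates[[1]]
  expect_equal(length(ring), 4)
  expect_equal(unlist(ring[[1]]), unlist(ring[[4]]))
})

test_that("channel completeness reports per-channel fractions", {
  tr <- make_trace(10)
  tr$lon[1:4] <- NA; tr$lat[1:4] <- NA
  cc <- channel_completeness(tr)
  expect_equal(unname(cc["lon"]), 0.6)
  expect_equal(unname(cc["accel"]), 1)
})
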