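# Ground-truthed synthetic participant-weeks emulating a wearable
# multichannel monitor: minute-cadence GPS with indoor dropout, satellite
# counts, accelerometer, microphone, docking state and a coarse-particle
# channel, over a home/work/other weekly schedule with five transport modes.
#
# The generator's defaults are the study conditions every downstream stage
# is tested under: ~1-week traces at 1-min cadence, ~40% GPS dropout
# indoors, home-dominated time budgets and diurnal commuting structure.

# Per-context deterministic channel levels (unitless sensor scales; every
# downstream threshold is quantile-based so only the ordering matters).
.CTX <- data.frame(
  ctx   = c("sleep", "home_awake", "work", "other_in", "out_static",
            "walk", "cycle", "car", "bus", "train_metro"),
  accel = c(0.02, 0.08, 0.08, 0.08, 0.70, 0.90, 1.30, 0.45, 0.55, 0.60),
  mic   = c(0.05, 0.40, 0.45, 0.50, 0.50, 0.55, 0.55, 0.70, 0.70, 0.70),
  stringsAsFactors = FALSE)

.MODE_SPEED <- list(walk = c(0.8, 1.8), cycle = c(3, 7), car = c(6, 15),
                    bus = c(5, 12), train_metro = c(10, 30))

#' Build a simulation scenario
#'
#' Sites and routes live in a local metric frame around `base_lonlat`.
#' Defaults describe an office worker's week: nightly sleep at home,
#' weekday commutes rotating through the five transport modes, a lunchtime
#' break outdoors at work, evening shop visits, garden interludes and a
#' weekend park walk.
#'
#' @param n_days Days simulated (default 7, starting on a Monday).
#' @param seed Integer seed; the whole participant is deterministic given it.
#' @param home_xy,work_xy Site coordinates in metres.
#' @param commute_modes Modes cycled over weekday commutes.
#' @param gps_noise_sd Isotropic GPS noise SD in metres.
#' @param indoor_dropout_p,outdoor_dropout_p Per-minute probability that an
#'   indoor (outdoor) minute loses its fix.
#' @param sat_indoor_mean,sat_outdoor_mean Poisson means of the satellite
#'   count indoors / outdoors.
#' @param sleep_window Local clock interval `c("HH:MM","HH:MM")` of nightly
#'   sleep (crossing midnight allowed).
#' @param home_share Optional target fraction of minutes spent indoors at
#'   home (sleep included); weekday work-end times are adjusted to meet it.
#' @param sleep_away_day Day index on whose night the participant sleeps at
#'   a friend's home instead (docked there), or `NA`.
#' @param questionnaire List `car_owner`, `bike_owner` (logicals), `pt_freq`
#'   (0-4 ordinal public-transport use frequency).
#' @param base_lonlat Geographic anchor of the local frame.
#' @param origin_offset Metres added to all coordinates (distinct cohort
#'   homes).
#' @param tz_offset Minutes from UTC to local clock.
#' @return A `scenario` list.
#' @export
scenario <- function(n_days = 7, seed = 1L,
                     home_xy = c(0, 0), work_xy = c(4000, 2000),
                     commute_modes = c("walk", "cycle", "car", "bus",
                                       "train_metro"),
                     gps_noise_sd = 10, indoor_dropout_p = 0.4,
                     outdoor_dropout_p = 0.02,
                     sat_indoor_mean = 5, sat_outdoor_mean = 9,
                     sleep_window = c("23:30", "07:00"),
                     home_share = NA, sleep_away_day = NA,
                     questionnaire = list(car_owner = TRUE, bike_owner = TRUE,
                                          pt_freq = 3L),
                     base_lonlat = c(-0.12, 51.51),
                     origin_offset = c(0, 0), tz_offset = 0L) {
  stopifnot(indoor_dropout_p >= 0, indoor_dropout_p <= 1,
            all(commute_modes %in% TA_MODES), n_days >= 1)
  sc <- list(n_days = n_days, seed = as.integer(seed), home_xy = home_xy,
             work_xy = work_xy, commute_modes = commute_modes,
             gps_noise_sd = gps_noise_sd, indoor_dropout_p = indoor_dropout_p,
             outdoor_dropout_p = outdoor_dropout_p,
             sat_indoor_mean = sat_indoor_mean,
             sat_outdoor_mean = sat_outdoor_mean,
             sleep_window = sleep_window, home_share = home_share,
             sleep_away_day = sleep_away_day, questionnaire = questionnaire,
             base_lonlat = base_lonlat, origin_offset = origin_offset,
             tz_offset = as.integer(tz_offset),
             start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"))
  sc$sites <- list(home = home_xy, work = work_xy,
                   shop = home_xy + c(-800, 600),
                   park = home_xy + c(500, -900),
                   friend = home_xy + c(9000, -3000))
  sc$routes <- .scenario_routes(sc)
  class(sc) <- "scenario"
  sc
}

# Mode-specific polylines between home and work, plus walk branches to the
# shop, the park and the train stations. Train journeys are composite:
# walk to the station, ride the railway, walk to work.
.scenario_routes <- function(sc) {
  h <- sc$home_xy; w <- sc$work_xy
  seg <- function(...) do.call(rbind, list(...))
  station_a <- h + c(0, 400); station_b <- w + c(-100, 300)
  list(
    walk = seg(h, h + c(1000, 300), h + c(2200, 1100), w),
    cycle = seg(h, h + c(800, 900), h + c(2800, 1700), w),
    car = seg(h, h + c(1500, -200), h + c(3500, 800), w),
    bus = seg(h, h + c(500, 500), h + c(2000, 1500), h + c(3600, 1900), w),
    railway = seg(station_a, h + c(1200, 1600), h + c(2600, 2400),
                  station_b),
    walk_station_home = seg(h, station_a),
    walk_station_work = seg(station_b, w),
    walk_shop = seg(h, sc$sites$shop),
    walk_park = seg(h, sc$sites$park),
    car_friend = seg(h, h + c(4000, -1500), sc$sites$friend))
}

#' GIS network for a scenario
#'
#' Line layers (highway, railway, sidewalk, cycleway, busway) follow the
#' scenario's mode-specific routes so that projecting trips on the network
#' is informative; bus stops sit along the bus route and train stops at the
#' railway ends.
#'
#' @param sc A [scenario()].
#' @return Network list (WGS84 coordinates) writable with [write_network()].
#' @export
scenario_network <- function(sc) {
  to_ll <- function(m) {
    ll <- .local_to_lonlat(m, sc)
    cbind(ll$lon, ll$lat)
  }
  r <- sc$routes
  lines <- list(
    list(kind = "highway", coords = to_ll(r$car)),
    list(kind = "railway", coords = to_ll(r$railway)),
    list(kind = "sidewalk", coords = to_ll(r$walk)),
    list(kind = "sidewalk", coords = to_ll(r$walk_shop)),
    list(kind = "sidewalk", coords = to_ll(r$walk_park)),
    list(kind = "sidewalk", coords = to_ll(r$walk_station_home)),
    list(kind = "sidewalk", coords = to_ll(r$walk_station_work)),
    list(kind = "cycleway", coords = to_ll(r$cycle)),
    list(kind = "busway", coords = to_ll(r$bus)))
  # bus stops every ~1.2 km along the bus route; train stops at railway ends
  bus_stops <- .points_along(r$bus, spacing = 1200)
  stops <- lapply(seq_len(nrow(bus_stops)), function(i)
    list(kind = "bus_stop", coords = to_ll(bus_stops[i, , drop = FALSE])[1, ]))
  stops <- c(stops,
             list(list(kind = "train_stop",
                       coords = to_ll(r$railway[1, , drop = FALSE])[1, ]),
                  list(kind = "train_stop",
                       coords = to_ll(r$railway[nrow(r$railway), ,
                                                drop = FALSE])[1, ])))
  list(lines = lines, stops = stops)
}

.local_to_lonlat <- function(m, sc) {
  x <- m[, 1] + sc$origin_offset[1]
  y <- m[, 2] + sc$origin_offset[2]
  lat0 <- sc$base_lonlat[2]
  list(lon = sc$base_lonlat[1] + x / (111320 * cos(lat0 * pi / 180)),
       lat = lat0 + y / 110540)
}

.polyline_cumlen <- function(p) {
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  c(0, cumsum(d))
}

.point_at <- function(p, cum, d) {
  d <- min(max(d, 0), cum[length(cum)])
  i <- findInterval(d, cum, rightmost.closed = TRUE)
  i <- min(i, nrow(p) - 1)
  f <- if (cum[i + 1] > cum[i]) (d - cum[i]) / (cum[i + 1] - cum[i]) else 0
  p[i, ] + f * (p[i + 1, ] - p[i, ])
}

.points_along <- function(p, spacing) {
  cum <- .polyline_cumlen(p)
  dd <- seq(spacing / 2, cum[length(cum)], by = spacing)
  do.call(rbind, lapply(dd, function(d) .point_at(p, cum, d)))
}

.hhmm <- function(s) {
  z <- as.numeric(strsplit(s, ":")[[1]])
  as.integer(z[1] * 60 + z[2])
}

# --- week builder -----------------------------------------------------------

# Fills per-minute arrays (environment `e`) for one trip; returns the minute
# after arrival. Legs: list of (mode, polyline) ridden in order.
.sim_trip <- function(e, start, legs, journey_id) {
  cur <- start
  for (leg in legs) {
    mode <- leg$mode; route <- leg$route
    cum <- .polyline_cumlen(route)
    total <- cum[length(cum)]
    base <- runif(1, .MODE_SPEED[[mode]][1], .MODE_SPEED[[mode]][2])
    # distances along the route of the forced bus stops
    stops <- if (mode == "bus") seq(600, total, by = 1200) else numeric(0)
    d <- 0; next_stop <- 1
    while (d < total && cur <= length(e$ctx)) {
      v <- base * exp(rnorm(1, 0, 0.12))
      if (mode == "bus" && next_stop <= length(stops) &&
          d + v * 60 >= stops[next_stop]) {
        # forced stop: pull up at the bus stop and crawl
        d <- stops[next_stop]; next_stop <- next_stop + 1
        v <- runif(1, 1, 2)
      } else {
        d <- d + v * 60
      }
      pt <- .point_at(route, cum, min(d, total))
      e$x[cur] <- pt[1]; e$y[cur] <- pt[2]
      e$ctx[cur] <- mode
      e$micro[cur] <- "transit"
      e$mode[cur] <- mode
      e$journey[cur] <- journey_id
      e$speed[cur] <- v
      e$indoor[cur] <- FALSE
      e$dock[cur] <- FALSE
      e$sleep[cur] <- FALSE
      cur <- cur + 1
    }
  }
  cur
}

.sim_static <- function(e, from, to, micro, ctx, site, indoor,
                        dock = FALSE, sleep = FALSE) {
  if (to < from) return(invisible())
  span <- from:min(to, length(e$ctx))
  e$x[span] <- site[1]; e$y[span] <- site[2]
  e$micro[span] <- micro; e$ctx[span] <- ctx
  e$mode[span] <- NA_character_; e$journey[span] <- NA_integer_
  e$speed[span] <- 0
  e$indoor[span] <- indoor; e$dock[span] <- dock; e$sleep[span] <- sleep
  invisible()
}

.commute_legs <- function(sc, mode, outbound) {
  r <- sc$routes
  rev_route <- function(p) p[nrow(p):1, , drop = FALSE]
  if (mode == "train_metro") {
    legs <- list(list(mode = "walk", route = r$walk_station_home),
                 list(mode = "train_metro", route = r$railway),
                 list(mode = "walk", route = r$walk_station_work))
    if (!outbound) legs <- rev(lapply(rev(legs), function(l) {
      l$route <- rev_route(l$route); l
    }))
    return(legs)
  }
  route <- r[[mode]]
  if (!outbound) route <- rev_route(route)
  list(list(mode = mode, route = route))
}

# Build the deterministic weekly schedule into minute arrays; work_adj is a
# per-weekday shift (minutes) of the leave-work time used to hit a target
# home share.
.build_week <- function(sc, work_adj = 0) {
  n <- sc$n_days * 1440
  e <- new.env()
  e$ctx <- rep("home_awake", n); e$micro <- rep("home_in", n)
  e$mode <- rep(NA_character_, n); e$journey <- rep(NA_integer_, n)
  e$x <- rep(sc$sites$home[1], n); e$y <- rep(sc$sites$home[2], n)
  e$speed <- rep(0, n)
  e$indoor <- rep(TRUE, n); e$dock <- rep(FALSE, n); e$sleep <- rep(FALSE, n)
  jid <- 0
  s0 <- .hhmm(sc$sleep_window[1]); s1 <- .hhmm(sc$sleep_window[2])
  for (d in seq_len(sc$n_days)) {
    day0 <- (d - 1) * 1440  # minute before 00:00 of day d
    at <- function(hm) day0 + .hhmm(hm) + 1
    weekday <- ((d - 1) %% 7) < 5
    away <- !is.na(sc$sleep_away_day) && d == sc$sleep_away_day
    if (weekday) {
      mode <- sc$commute_modes[((d - 1) %% length(sc$commute_modes)) + 1]
      jid <- jid + 1
      cur <- .sim_trip(e, at("08:30"), .commute_legs(sc, mode, TRUE), jid)
      work_end <- day0 + .hhmm("17:30") + round(work_adj) + 1
      work_end <- min(max(work_end, day0 + .hhmm("13:30")),
                      day0 + .hhmm("22:30"))
      .sim_static(e, cur, at("12:30") - 1, "work_in", "work",
                  sc$sites$work, TRUE)
      .sim_static(e, at("12:30"), at("12:50") - 1, "work_out", "out_static",
                  sc$sites$work + c(30, 20), FALSE)
      .sim_static(e, at("12:50"), work_end - 1, "work_in", "work",
                  sc$sites$work, TRUE)
      jid <- jid + 1
      cur <- .sim_trip(e, work_end, .commute_legs(sc, mode, FALSE), jid)
      # evening (anchored to arrival home so a late work end shifts it)
      if (d %% 7 %in% c(2, 4)) {  # shop run
        jid <- jid + 1
        cur2 <- .sim_trip(e, max(at("19:30"), cur + 10),
                          list(list(mode = "walk",
                                    route = sc$routes$walk_shop)), jid)
        .sim_static(e, cur2, cur2 + 39, "other_in", "other_in",
                    sc$sites$shop, TRUE)
        jid <- jid + 1
        .sim_trip(e, cur2 + 40,
                  list(list(mode = "walk",
                            route = sc$routes$walk_shop[2:1, , drop = FALSE])),
                  jid)
      } else {                    # garden interlude
        g0 <- max(at("18:45"), cur + 5)
        .sim_static(e, g0, g0 + 19, "home_out",
                    "out_static", sc$sites$home + c(15, -10), FALSE)
      }
    } else if ((d - 1) %% 7 == 5) {  # Saturday: park walk
      jid <- jid + 1
      cur <- .sim_trip(e, at("11:00"),
                       list(list(mode = "walk",
                                 route = sc$routes$walk_park)), jid)
      .sim_static(e, cur, cur + 59, "other_out", "out_static",
                  sc$sites$park, FALSE)
      jid <- jid + 1
      .sim_trip(e, cur + 60,
                list(list(mode = "walk",
                          route = sc$routes$walk_park[2:1, , drop = FALSE])),
                jid)
      .sim_static(e, at("16:00"), at("16:30") - 1, "home_out", "out_static",
                  sc$sites$home + c(12, 18), FALSE)
    } else {                        # Sunday: short shop walk
      jid <- jid + 1
      cur <- .sim_trip(e, at("15:00"),
                       list(list(mode = "walk",
                                 route = sc$routes$walk_shop)), jid)
      .sim_static(e, cur, cur + 29, "other_in", "other_in",
                  sc$sites$shop, TRUE)
      jid <- jid + 1
      .sim_trip(e, cur + 30,
                list(list(mode = "walk",
                          route = sc$routes$walk_shop[2:1, , drop = FALSE])),
                jid)
    }
    if (away) {
      # evening drive to a friend's home; overnight stay there (docked)
      jid <- jid + 1
      cur <- .sim_trip(e, at("20:00"),
                       list(list(mode = "car",
                                 route = sc$routes$car_friend)), jid)
      .sim_static(e, cur, day0 + 1440, "other_in", "other_in",
                  sc$sites$friend, TRUE, dock = TRUE)
    }
    away_prev <- !is.na(sc$sleep_away_day) && d == sc$sleep_away_day + 1
    if (away_prev) {
      .sim_static(e, day0 + 1, at("07:00") - 1, "other_in", "other_in",
                  sc$sites$friend, TRUE, dock = TRUE)
      jid <- jid + 1
      .sim_trip(e, at("07:00"),
                list(list(mode = "car",
                          route = sc$routes$car_friend[
                            nrow(sc$routes$car_friend):1, , drop = FALSE])),
                jid)
    }
    # nightly sleep (skipped at home when sleeping away)
    if (!away) {
      if (s0 > s1) {  # window crosses midnight
        .sim_static(e, day0 + s0 + 1, day0 + 1440, "home_in", "sleep",
                    sc$sites$home, TRUE, dock = TRUE, sleep = TRUE)
        if (!away_prev)
          .sim_static(e, day0 + 1, day0 + s1, "home_in", "sleep",
                      sc$sites$home, TRUE, dock = TRUE, sleep = TRUE)
      } else {
        .sim_static(e, day0 + s0 + 1, day0 + s1, "home_in", "sleep",
                    sc$sites$home, TRUE, dock = TRUE, sleep = TRUE)
      }
    }
    # docked while home around the night window
    morning <- (day0 + s1 + 1):(day0 + .hhmm("08:00"))
    morning <- morning[morning <= n & morning >= 1]
    if (!away_prev)
      e$dock[morning] <- e$micro[morning] == "home_in"
    evening <- (day0 + .hhmm("22:00") + 1):(day0 + 1440)
    if (!away)
      e$dock[evening] <- e$dock[evening] | e$micro[evening] == "home_in"
  }
  e
}

# --- clean trace, corruption, assembly --------------------------------------

.clean_trace <- function(sc, e) {
  n <- length(e$ctx)
  idx <- match(e$ctx, .CTX$ctx)
  accel <- .CTX$accel[idx]
  mic <- .CTX$mic[idx]
  sat <- ifelse(e$indoor, sc$sat_indoor_mean, sc$sat_outdoor_mean)
  # coarse particles: flat while asleep, higher and livelier awake at home,
  # with an evening cooking ramp
  pm10 <- ifelse(e$sleep, 8, 12)
  minute_of_day <- (seq_len(n) - 1) %% 1440
  cook <- minute_of_day >= .hhmm("19:00") & minute_of_day < .hhmm("19:20") &
    e$micro == "home_in" & !e$sleep
  pm10[cook] <- pm10[cook] + 25
  ll <- .local_to_lonlat(cbind(e$x, e$y), sc)
  df <- data.frame(
    t = sc$start + 60 * (seq_len(n) - 1),
    lon = ll$lon, lat = ll$lat, n_sat = sat, accel = accel, mic = mic,
    dock_v = e$dock, pm10 = pm10)
  tr <- .ta_trace(df, participant_id = paste0("sim", sc$seed),
                  tz_offset = sc$tz_offset)
  attr(tr, "truth_indoor") <- e$indoor
  attr(tr, "truth_sleep") <- e$sleep
  tr
}

#' Corrupt a clean simulated trace
#'
#' Adds isotropic Gaussian GPS noise, Bernoulli per-minute indoor (and
#' outdoor) fix dropout, Poisson satellite-count sampling and multiplicative
#' channel jitter. Truth labels are untouched. Uses the current RNG state;
#' [simulate_participant()] seeds it from the scenario.
#'
#' @param trace Clean trace from the generator (carries truth attributes).
#' @param sc The [scenario()].
#' @return The corrupted `ta_trace`.
#' @export
corrupt_sensors <- function(trace, sc) {
  n <- nrow(trace)
  indoor <- attr(trace, "truth_indoor") %||% rep(FALSE, n)
  asleep <- attr(trace, "truth_sleep") %||% rep(FALSE, n)
  lat0 <- sc$base_lonlat[2]
  if (sc$gps_noise_sd > 0) {
    nx <- rnorm(n, 0, sc$gps_noise_sd)
    ny <- rnorm(n, 0, sc$gps_noise_sd)
    trace$lon <- trace$lon + nx / (111320 * cos(lat0 * pi / 180))
    trace$lat <- trace$lat + ny / 110540
  }
  trace$n_sat <- rpois(n, trace$n_sat)
  trace$accel <- trace$accel * exp(rnorm(n, 0, 0.20))
  trace$mic <- trace$mic * exp(rnorm(n, 0, 0.15))
  if (!is.null(trace$pm10))
    trace$pm10 <- trace$pm10 + rnorm(n, 0, ifelse(asleep, 0.05, 1.5))
  drop_p <- ifelse(indoor, sc$indoor_dropout_p, sc$outdoor_dropout_p)
  dropped <- runif(n) < drop_p
  trace$lon[dropped] <- NA_real_
  trace$lat[dropped] <- NA_real_
  trace
}

#' Simulate one participant-week
#'
#' Builds the ground-truth weekly schedule, renders it into a clean
#' minute-cadence trace and corrupts the sensors. Deterministic given the
#' scenario seed.
#'
#' @param sc A [scenario()].
#' @return List with `trace` (`ta_trace`), `truth` (data frame `t`, `label`,
#'   `micro`, `mode`, `journey`, `indoor`, `sleep`, `speed`), `questionnaire`
#'   and `scenario`.
#' @export
simulate_participant <- function(sc) {
  set.seed(sc$seed)
  e <- .build_week(sc)
  if (!is.na(sc$home_share)) {
    # shift the weekday leave-work time until the home share hits the target
    n_weekdays <- sum(((seq_len(sc$n_days) - 1) %% 7) < 5)
    adj <- 0
    for (it in seq_len(6)) {
      h <- mean(e$micro == "home_in")
      if (abs(h - sc$home_share) < 0.005 || n_weekdays == 0) break
      adj <- adj + (h - sc$home_share) * length(e$ctx) / n_weekdays
      set.seed(sc$seed)
      e <- .build_week(sc, work_adj = adj)
    }
  }
  set.seed(sc$seed + 1L)
  clean <- .clean_trace(sc, e)
  trace <- corrupt_sensors(clean, sc)
  label <- ifelse(e$sleep, "sleep",
                  ifelse(e$micro == "transit", e$mode, e$micro))
  truth <- data.frame(t = clean$t, label = label, micro = e$micro,
                      mode = e$mode, journey = e$journey, indoor = e$indoor,
                      sleep = e$sleep, speed = e$speed,
                      stringsAsFactors = FALSE)
  list(trace = trace, truth = truth, questionnaire = sc$questionnaire,
       scenario = sc)
}

#' Simulate a cohort
#'
#' Participants get jittered scenario parameters (distinct home areas,
#' rotated commute-mode phases, questionnaire variation); the second
#' participant (when `n >= 2`) sleeps away from home one night to exercise
#' the home-identification fallback path. Reproducible from
#' `(base_scenario, seed)`.
#'
#' @param n Number of participants.
#' @param base_scenario Template [scenario()].
#' @param seed Integer cohort seed.
#' @return List of [simulate_participant()] results.
#' @export
simulate_cohort <- function(n, base_scenario = scenario(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  offs <- matrix(runif(2 * n, -25000, 25000), ncol = 2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- base_scenario
    sc$seed <- as.integer(seed * 1000 + i)
    sc$origin_offset <- base_scenario$origin_offset + offs[i, ]
    k <- i %% length(base_scenario$commute_modes)
    sc$commute_modes <- if (k > 0)
      c(tail(base_scenario$commute_modes, -k),
        head(base_scenario$commute_modes, k))
    else base_scenario$commute_modes
    sc$sleep_away_day <- if (n >= 2 && i == 2) 3 else NA
    sc$questionnaire <- list(
      car_owner = (i %% 3) != 0,
      bike_owner = (i %% 2) == 0,
      pt_freq = as.integer((i * 2) %% 5))
    sc$routes <- .scenario_routes(sc)
    out[[i]] <- simulate_participant(sc)
  }
  names(out) <- paste0("p", seq_len(n))
  out
}

#' Simulate one standalone trip
#'
#' A single journey of the given mode along the scenario's mode route,
#' rendered and corrupted like any other trace (outdoor throughout). Used to
#' build transport-mode training sets.
#'
#' @param mode One of [ta_modes()].
#' @param sc A [scenario()].
#' @param seed Integer seed.
#' @param start_minute Minute of day the trip starts.
#' @return List `trace`, `truth` as in [simulate_participant()] but limited
#'   to the trip span.
#' @export
simulate_trip <- function(mode, sc = scenario(), seed = 1L,
                          start_minute = 540) {
  stopifnot(mode %in% TA_MODES)
  sc$seed <- as.integer(seed)
  set.seed(seed)
  n <- 1440
  e <- new.env()
  e$ctx <- rep("home_awake", n); e$micro <- rep("home_in", n)
  e$mode <- rep(NA_character_, n); e$journey <- rep(NA_integer_, n)
  e$x <- rep(sc$sites$home[1], n); e$y <- rep(sc$sites$home[2], n)
  e$speed <- rep(0, n)
  e$indoor <- rep(TRUE, n); e$dock <- rep(FALSE, n); e$sleep <- rep(FALSE, n)
  route <- if (mode == "train_metro") sc$routes$railway else sc$routes[[mode]]
  cur <- .sim_trip(e, start_minute,
                   list(list(mode = mode, route = route)), 1L)
  span <- start_minute:(cur - 1)
  clean <- .clean_trace(sc, e)
  trace <- corrupt_sensors(clean, sc)
  trace <- .keep_trace_attrs(trace[span, , drop = FALSE], trace)
  label <- ifelse(e$micro == "transit", e$mode, e$micro)[span]
  truth <- data.frame(t = clean$t[span], label = label,
                      micro = e$micro[span], mode = e$mode[span],
                      journey = e$journey[span], indoor = e$indoor[span],
                      sleep = e$sleep[span], speed = e$speed[span],
                      stringsAsFactors = FALSE)
  list(trace = trace, truth = truth, scenario = sc)
}

#' Simulate a transport-mode training dataset
#'
#' Generates `n_per_mode` standalone trips per mode, each from a
#' participant-like context (questionnaire answers correlated with the
#' habitual mode), extracts the full 60-variable feature set per trip and
#' returns the design matrix with trip-level grouping for grouped
#' cross-validation.
#'
#' @param n_per_mode Trips per mode.
#' @param sc Template [scenario()].
#' @param seed Integer seed.
#' @param cfg Configuration ([ta_config()]).
#' @return List `X` (features), `y` (mode factor), `groups` (trip ids).
#' @export
simulate_mode_dataset <- function(n_per_mode = 30, sc = scenario(),
                                  seed = 1L, cfg = ta_config()) {
  set.seed(seed)
  network_ll <- scenario_network(sc)
  tmp <- tempfile(fileext = ".geojson")
  on.exit(unlink(tmp))
  write_network(network_ll, tmp)
  zone <- utm_zone(sc$base_lonlat[1])
  network <- read_network(tmp, zone = zone, south = sc$base_lonlat[2] < 0)
  rows <- list(); ys <- character(0); groups <- integer(0)
  trip_id <- 0
  for (mode in TA_MODES) {
    for (k in seq_len(n_per_mode)) {
      trip_id <- trip_id + 1
      q <- .mode_questionnaire(mode)
      start <- sample(420:1200, 1)
      tp <- simulate_trip(mode, sc, seed = seed * 10000 + trip_id,
                          start_minute = start)
      tr <- project_utm(tp$trace)
      hm <- tryCatch({
        pars <- space_use_params(tr, cfg)
        nn <- adaptive_neighbors(tr, pars)
        build_hulls(tr, nn, ivg_hours = cfg$ivg_hours)$metrics
      }, error = function(e) NULL)
      fv <- extract_segment_features(tr, seq_len(nrow(tr)), q, network, cfg,
                                     hull_metrics = hm)
      rows[[trip_id]] <- fv
      ys <- c(ys, mode)
      groups <- c(groups, trip_id)
    }
  }
  X <- do.call(rbind, rows)
  list(X = X, y = factor(ys, levels = TA_MODES), groups = groups)
}

.mode_questionnaire <- function(mode) {
  switch(mode,
    car = list(car_owner = runif(1) < 0.9, bike_owner = runif(1) < 0.3,
               pt_freq = sample(0:2, 1)),
    cycle = list(car_owner = runif(1) < 0.4, bike_owner = runif(1) < 0.9,
                 pt_freq = sample(0:2, 1)),
    bus = list(car_owner = runif(1) < 0.3, bike_owner = runif(1) < 0.3,
               pt_freq = sample(3:4, 1)),
    train_metro = list(car_owner = runif(1) < 0.4,
                       bike_owner = runif(1) < 0.3,
                       pt_freq = sample(3:4, 1)),
    list(car_owner = runif(1) < 0.5, bike_owner = runif(1) < 0.5,
         pt_freq = sample(0:4, 1)))
}
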