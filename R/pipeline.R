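# End-to-end six-step classification of one participant trace.

#' Classify a participant trace
#'
#' Runs the full six-step model: (1) home identification from night-time
#' docked fixes and the elliptical buffer zone; (2) time-scaled-distance
#' local hulls separating static clusters from directional movement on the
#' non-home minutes; (3) visit metrics and home/work/other role assignment
#' (home falls back to the most-used cluster when Step 1 is undetermined);
#' (4) GPS gap interpolation and indoor/outdoor separation; (5) sleep
#' detection within the indoor home microenvironment; (6) journey splitting,
#' penalized-contrast segmentation and (when a mode model is supplied)
#' transport-mode prediction per segment.
#'
#' @param trace A `ta_trace` (any cadence <= 60 s; resampled internally).
#' @param questionnaire List `car_owner`, `bike_owner`, `pt_freq` (or `NULL`).
#' @param network Projected network from [read_network()] (or `NULL`).
#' @param cfg Configuration ([ta_config()]).
#' @param mode_model Optional `mode_model`; without it transit minutes keep
#'   the generic `transit` label.
#' @return List with `labels` (data frame `t`, `label`, `provenance`),
#'   `trace` (projected, gap-filled), `home_zone`, `hulls`, `motion`,
#'   `clusters`, `roles`, `thresholds`, `journeys`, `segments` (with
#'   features), and `params`.
#' @export
classify_trace <- function(trace, questionnaire = NULL, network = NULL,
                           cfg = ta_config(), mode_model = NULL) {
  tr <- resample_minutely(trace)
  tr <- project_utm(tr)
  n <- nrow(tr)
  labels <- rep(NA_character_, n)
  prov <- rep(NA_character_, n)

  # Step 1: home from night-time docked fixes
  nd <- night_dock_subset(tr, cfg$night_window)
  zone <- fit_home_zone(tr$x[nd], tr$y[nd], cfg)
  home_determined <- !is.null(zone)
  if (home_determined) {
    hl <- label_home(tr, zone)
    labels[!is.na(hl)] <- "home"
    prov[!is.na(hl)] <- "step1"
  }

  # Step 2: space use on the remaining valid-fix minutes
  sub_rows <- which(valid_fix(tr) & is.na(labels))
  hulls <- NULL; motion <- NULL; params <- NULL
  mv_rows <- integer(0); st_rows <- integer(0)
  if (length(sub_rows) >= 5) {
    sub <- .keep_trace_attrs(tr[sub_rows, , drop = FALSE], tr)
    params <- space_use_params(sub, cfg)
    nn <- adaptive_neighbors(sub, params)
    hulls <- build_hulls(sub, nn, ivg_hours = cfg$ivg_hours)
    motion <- classify_motion(hulls, cfg$ecc_quantile, cfg$density_quantile)
    mv_rows <- sub_rows[motion$row[motion$motion == "movement"]]
    st_rows <- sub_rows[motion$row[motion$motion == "static"]]
  }

  # Step 3: static clusters, visit metrics, roles
  clusters <- NULL; roles <- NULL
  if (length(st_rows)) {
    cl <- cluster_static_points(tr$x[st_rows], tr$y[st_rows],
                                eps = cfg$eps_m, min_pts = cfg$min_pts)
    ids <- sort(unique(cl[cl > 0]))
    if (length(ids)) {
      met <- do.call(rbind, lapply(ids, function(id) {
        rows <- st_rows[cl == id]
        vm <- visit_metrics(tr$t[rows], ivg_hours = cfg$ivg_hours)
        data.frame(cluster_id = id, total_minutes = vm$total_minutes,
                   nsv = vm$nsv, mnlv = vm$mnlv)
      }))
      # clusters with very short mean visits are directional movement
      move_cl <- met$cluster_id[met$mnlv < cfg$mnlv_static_min]
      met <- met[!met$cluster_id %in% move_cl, , drop = FALSE]
      if (length(move_cl))
        mv_rows <- sort(c(mv_rows, st_rows[cl %in% move_cl]))
      if (nrow(met)) {
        roles <- assign_roles(met, home_determined,
                              work_min_visits = cfg$work_min_visits,
                              work_min_duration_min =
                                cfg$work_min_duration_min)
        if (!home_determined && "home" %in% roles$role) {
          hid <- roles$cluster_id[roles$role == "home"]
          hrows <- st_rows[cl == hid]
          zone <- home_zone_from_points(tr$x[hrows], tr$y[hrows], cfg,
                                        determined_in_step1 = FALSE)
          hl <- label_home(tr, zone)
          labels[!is.na(hl)] <- "home"
          prov[!is.na(hl)] <- "step3"
        }
        for (i in seq_len(nrow(roles))) {
          rows <- st_rows[cl == roles$cluster_id[i]]
          rows <- rows[is.na(labels[rows])]
          lab <- switch(roles$role[i], home = "home", work = "work",
                        roles$unique_tag[i])
          labels[rows] <- lab
          prov[rows] <- "step3"
        }
      }
      clusters <- list(rows = st_rows, cluster = cl, metrics = met)
    }
  }
  labels[mv_rows[is.na(labels[mv_rows])]] <- "transit"
  prov[mv_rows] <- ifelse(is.na(prov[mv_rows]), "step2", prov[mv_rows])

  # Step 4: gap interpolation, then indoor/outdoor separation
  thr <- derive_thresholds(tr, cfg)
  gi <- interpolate_gaps(tr, labels, cfg)
  tr <- gi$trace
  newly <- is.na(labels) & !is.na(gi$labels)
  labels <- gi$labels
  prov[newly] <- "step4_fill"
  labels[gi$transit_candidate & is.na(labels)] <- "transit"
  prov[gi$transit_candidate] <- ifelse(is.na(prov[gi$transit_candidate]),
                                       "step4_gap", prov[gi$transit_candidate])
  labels <- classify_indoor_outdoor(tr, labels, thr, cfg)

  # Step 5: sleep inside home_in
  labels <- classify_sleep(tr, labels, thr, cfg)
  prov[labels == "sleep" & !is.na(labels)] <- "step5"

  # Step 6: journeys, segmentation, mode prediction
  transit_flag <- !is.na(labels) & labels == "transit"
  journeys <- split_journeys(transit_flag, cfg$stop_max_min)
  segments <- NULL
  if (nrow(journeys)) {
    seg_list <- list()
    for (j in seq_len(nrow(journeys))) {
      span <- journeys$start[j]:journeys$end[j]
      sp <- .minute_speed(tr, span)
      lv <- lavielle_segments(sp, cfg$lavielle_lmin, cfg$lavielle_kmax,
                              cfg$lavielle_threshold)
      for (s in seq_len(nrow(lv$segments))) {
        rows <- span[lv$segments$start[s]:lv$segments$end[s]]
        hm <- NULL
        if (!is.null(hulls)) {
          sub_idx <- na.omit(match(rows, sub_rows))
          hm <- hulls$metrics[hulls$metrics$parent %in% sub_idx, ,
                              drop = FALSE]
        }
        fv <- extract_segment_features(tr, rows, questionnaire, network,
                                       cfg, hm)
        seg_list[[length(seg_list) + 1]] <-
          cbind(data.frame(journey = j, segment = s,
                           start = rows[1], end = rows[length(rows)]), fv)
      }
    }
    segments <- do.call(rbind, seg_list)
    if (!is.null(mode_model)) {
      pr <- predict(mode_model, segments[, feature_names(), drop = FALSE])
      for (s in seq_len(nrow(segments))) {
        rows <- segments$start[s]:segments$end[s]
        sel <- rows[transit_flag[rows]]
        labels[sel] <- as.character(pr[s])
        prov[sel] <- "step6"
      }
      segments$mode_pred <- as.character(pr)
    }
  }

  labels[is.na(labels)] <- "unclassified"
  prov[is.na(prov)] <- ifelse(labels[is.na(prov)] == "unclassified",
                              "none", "step4")
  list(labels = data.frame(t = tr$t, label = labels, provenance = prov,
                           stringsAsFactors = FALSE),
       trace = tr, home_zone = zone, hulls = hulls, motion = motion,
       clusters = clusters, roles = roles, thresholds = thr,
       journeys = journeys, segments = segments, params = params,
       fill = gi$fill)
}

# Per-minute speed (m/s) over a span, from consecutive available positions.
.minute_speed <- function(tr, span) {
  x <- tr$x[span]; y <- tr$y[span]
  tt <- as.numeric(tr$t[span])
  n <- length(span)
  sp <- rep(NA_real_, n)
  if (n >= 2) {
    d <- sqrt(diff(x)^2 + diff(y)^2) / diff(tt)
    sp[1] <- d[1]
    sp[2:n] <- d
  }
  sp
}

#' Align predictions with truth on the minute grid
#'
#' @param labels Prediction data frame (`t`, `label`).
#' @param truth Truth data frame (`t`, `label`).
#' @return Data frame with `t`, `pred`, `truth` on the intersection grid.
#' @export
align_labels <- function(labels, truth) {
  m <- merge(data.frame(t = labels$t, pred = labels$label),
             data.frame(t = truth$t, truth = truth$label), by = "t")
  m[order(m$t), ]
}
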