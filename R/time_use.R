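# Step 3: time-use metrics (visits) and role assignment of static clusters.

#' Visit metrics for a set of member timestamps
#'
#' Visits are maximal runs of member timestamps whose consecutive gaps are
#' smaller than the inter-visit gap; a 12 h gap captures diurnal revisitation
#' patterns.
#'
#' @param times Sorted POSIXct (or numeric seconds) member timestamps.
#' @param ivg_hours Inter-visit gap in hours (a gap >= this starts a new
#'   visit).
#' @return List with `nsv` (number of separate visits), `mnlv` (mean member
#'   minutes per visit) and `total_minutes`.
#' @export
visit_metrics <- function(times, ivg_hours = 12) {
  tt <- as.numeric(times)
  stopifnot(length(tt) > 0)
  if (is.unsorted(tt)) tt <- sort(tt)
  gaps <- diff(tt)
  new_visit <- c(TRUE, gaps >= ivg_hours * 3600)
  run_sizes <- as.integer(table(cumsum(new_visit)))
  list(nsv = length(run_sizes), mnlv = mean(run_sizes),
       total_minutes = length(tt))
}

#' Density-based clustering of static minutes
#'
#' Groups the projected positions of static minutes into spatial clusters;
#' points in no dense region are noise (cluster id 0).
#'
#' @param x,y Projected coordinates (metres) of static minutes.
#' @param eps Neighbourhood radius in metres.
#' @param min_pts Minimum neighbourhood size (minutes) for a core point.
#' @return Integer cluster ids (0 = noise), one per point.
#' @export
cluster_static_points <- function(x, y, eps = 150, min_pts = 10) {
  stopifnot(length(x) == length(y))
  if (!length(x)) return(integer(0))
  cpp_dbscan(as.numeric(x), as.numeric(y), eps, as.integer(min_pts))
}

#' Assign home/work/other roles to static clusters
#'
#' If home was not determined in Step 1, the cluster where the participant
#' spent most time becomes home. Work is the remaining cluster maximising
#' `nsv * mnlv` (visited frequently and for extended periods) subject to
#' minimum visit count and duration; if none qualifies there is no work.
#' All remaining clusters are `other` with unique tags.
#'
#' @param metrics Data frame with one row per cluster: `cluster_id`,
#'   `total_minutes`, `nsv`, `mnlv`.
#' @param home_determined Logical: was home identified in Step 1?
#' @param work_min_visits Minimum separate visits for work.
#' @param work_min_duration_min Minimum mean visit duration (minutes).
#' @return Data frame `cluster_id`, `role` (home/work/other), `unique_tag`.
#' @export
assign_roles <- function(metrics, home_determined,
                         work_min_visits = 3, work_min_duration_min = 60) {
  stopifnot(nrow(metrics) >= 1)
  m <- metrics[order(metrics$cluster_id), , drop = FALSE]
  role <- rep("other", nrow(m))
  if (!home_determined) {
    role[which.max(m$total_minutes)] <- "home"
  }
  cand <- which(role != "home" &
                m$nsv >= work_min_visits &
                m$mnlv >= work_min_duration_min)
  if (length(cand)) {
    score <- m$nsv[cand] * m$mnlv[cand]
    role[cand[which.max(score)]] <- "work"
  }
  tag <- character(nrow(m))
  tag[role == "home"] <- "home"
  tag[role == "work"] <- "work"
  oth <- which(role == "other")
  tag[oth] <- paste0("other_", seq_along(oth))
  data.frame(cluster_id = m$cluster_id, role = role, unique_tag = tag,
             stringsAsFactors = FALSE)
}
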