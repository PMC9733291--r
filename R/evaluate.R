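# Confusion-matrix evaluation against truth/diary labels and time budgets.

#' One-vs-rest confusion counts
#'
#' Minutes with missing truth are excluded and counted. Minutes the model
#' left unclassified score as negatives for every positive class
#' (pessimistic).
#'
#' @param pred,truth Aligned label vectors (same length).
#' @param positive The positive class label.
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`, `n_excluded`.
#' @export
confusion <- function(pred, truth, positive) {
  stopifnot(length(pred) == length(truth))
  keep <- !is.na(truth)
  if (!any(keep)) stop("no overlapping minutes with truth labels")
  p <- pred[keep]; tr <- truth[keep]
  pp <- !is.na(p) & p == positive
  tp_ <- tr == positive
  structure(list(tp = sum(pp & tp_), fp = sum(pp & !tp_),
                 fn = sum(!pp & tp_), tn = sum(!pp & !tp_),
                 n_excluded = sum(!keep)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Undefined ratios (zero denominators) are reported as `NA`, never as 0.
#'
#' @param c A `confusion_counts` list.
#' @return List `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
classification_metrics <- function(c) {
  n <- c$tp + c$fp + c$fn + c$tn
  stopifnot(n > 0)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(c$tp, c$tp + c$fn)
  prec <- rat(c$tp, c$tp + c$fp)
  f1 <- if (!is.na(sens) && !is.na(prec) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(accuracy = (c$tp + c$tn) / n, sensitivity = sens,
       specificity = rat(c$tn, c$tn + c$fp), precision = prec, f1 = f1)
}

#' Time budgets from a label series
#'
#' Mean minutes per day and percentage shares of classified minutes per
#' class, plus the diurnal profile of per-hour class shares.
#'
#' @param labels Data frame with `t` (POSIXct) and `label`.
#' @param tz_offset Minutes from UTC to local clock (for the diurnal
#'   profile).
#' @return List with `budget` (data frame `label`, `minutes_per_day`,
#'   `share_pct`) and `diurnal` (class-share matrix, hours x classes).
#' @export
time_budget <- function(labels, tz_offset = 0L) {
  n_days <- nrow(labels) / 1440
  classified <- !is.na(labels$label) & labels$label != "unclassified"
  tab <- table(labels$label[classified])
  budget <- data.frame(label = names(tab),
                       minutes_per_day = as.numeric(tab) / n_days,
                       share_pct = 100 * as.numeric(tab) / sum(tab),
                       stringsAsFactors = FALSE)
  budget <- budget[order(-budget$minutes_per_day), ]
  rownames(budget) <- NULL
  local <- labels$t + tz_offset * 60
  hr <- as.integer(format(local, "%H", tz = "UTC"))
  diurnal <- prop.table(table(hr[classified], labels$label[classified]),
                        margin = 1)
  list(budget = budget, diurnal = diurnal)
}

# Collapse fine labels into the evaluation classes used for scoring
# against simulator truth: home includes sleep (indoors at home).
.eval_class <- function(lab, class) {
  switch(class,
    home = lab %in% c("home_in", "home_out", "sleep"),
    home_in = lab %in% c("home_in", "sleep"),
    work = lab %in% c("work_in", "work_out"),
    other_in = lab == "other_in",
    other_out = lab == "other_out",
    sleep = lab == "sleep",
    travel = lab %in% c(TA_MODES, "transit"),
    lab == class)
}

#' Score a prediction against truth for one evaluation class
#'
#' @param pred,truth Label vectors on the same minute grid.
#' @param class One of home, home_in, work, other_in, other_out, sleep,
#'   travel, or a raw label.
#' @return List with the confusion counts and metrics.
#' @export
score_class <- function(pred, truth, class) {
  p <- ifelse(.eval_class(pred, class), class, paste0("not_", class))
  tr <- ifelse(.eval_class(truth, class), class, paste0("not_", class))
  cc <- confusion(p, tr, positive = class)
  c(list(counts = cc), classification_metrics(cc))
}

#' Indoor/outdoor balanced accuracy
#'
#' Scored over minutes where both prediction and truth carry a static
#' indoor/outdoor label.
#'
#' @param pred,truth Label vectors.
#' @return Balanced accuracy (mean of indoor and outdoor sensitivity).
#' @export
io_balanced_accuracy <- function(pred, truth) {
  is_in <- function(l) l %in% c("home_in", "work_in", "other_in", "sleep")
  is_out <- function(l) l %in% c("home_out", "work_out", "other_out")
  static <- (is_in(pred) | is_out(pred)) & (is_in(truth) | is_out(truth))
  if (!any(static)) return(NA_real_)
  pin <- is_in(pred)[static]; tin <- is_in(truth)[static]
  sens_in <- if (any(tin)) mean(pin[tin]) else NA_real_
  sens_out <- if (any(!tin)) mean(!pin[!tin]) else NA_real_
  mean(c(sens_in, sens_out), na.rm = TRUE)
}
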