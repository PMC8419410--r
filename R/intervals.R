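#' Counting-process risk intervals for recurrent relapses (total time)
#'
#' Builds the total-time PWP interval table for one subject.  The clock
#' starts at stool collection (day 0) and is never reset: stratum 1 runs
#' from 0 to the first relapse (or last visit if censored); stratum k >= 2
#' is entered only after relapse k-1, starting 30 days after it (the
#' refractory period is discounted from the time at risk), and ends at
#' relapse k or the last visit.  Relapses are truncated after the first
#' `max_events`; follow-up ends at the earlier of the last visit and the
#' `max_events`-th relapse.  Zero-length intervals (stop <= start) are
#' dropped.
#'
#' @param timeline a [subject_timeline()].
#' @param max_events truncation cap on the number of relapses (default 3).
#' @return data.frame with columns `subject`, `stratum`, `start`, `stop`,
#'   `event`, `cal_stop` (calendar day of the interval end, equal to `stop`
#'   on the total-time clock); attribute `outcome_type = "relapse"`.
#' @export
build_relapse_intervals <- function(timeline, max_events = 3) {
  stopifnot(inherits(timeline, "subject_timeline"))
  if (max_events < 1) stop_invalid("max_events must be >= 1")
  L <- timeline$last_visit_day
  rel <- timeline$relapse_days
  rel <- rel[seq_len(min(length(rel), max_events))]
  end_day <- if (length(rel) == max_events) rel[max_events] else L

  rows <- list()
  # stratum 1
  stop1 <- if (length(rel) >= 1) rel[1] else end_day
  if (stop1 > 0)
    rows[[1]] <- c(1, 0, stop1, as.integer(length(rel) >= 1))
  # subsequent strata
  k <- 1L
  while (k <= length(rel) && k < max_events) {
    start_k <- rel[k] + 30
    stop_k <- if (length(rel) >= k + 1) rel[k + 1] else end_day
    ev <- as.integer(length(rel) >= k + 1)
    if (stop_k > start_k)
      rows[[length(rows) + 1L]] <- c(k + 1, start_k, stop_k, ev)
    k <- k + 1L
  }
  mat <- do.call(rbind, rows)
  out <- if (is.null(mat)) {
    data.frame(subject = character(0), stratum = integer(0),
               start = numeric(0), stop = numeric(0), event = integer(0),
               cal_stop = numeric(0))
  } else {
    data.frame(subject = timeline$subject_id, stratum = as.integer(mat[, 1]),
               start = mat[, 2], stop = mat[, 3],
               event = as.integer(mat[, 4]), cal_stop = mat[, 3])
  }
  attr(out, "outcome_type") <- "relapse"
  out
}

#' Gap-time risk intervals for MRI lesion outcomes
#'
#' Builds the gap-time PWP interval table for one subject and one lesion
#' type.  Because lesion onset is only known to lie between two scans, an
#' event is timed at the midpoint of the event-flagged scan and the prior
#' scan.  Stratum 1 runs from stool collection (day 0) to the first event
#' midpoint, or to the last scan if censored.  Stratum k >= 2 starts on the
#' date of the previous event's scan and ends at the current event midpoint
#' (or last scan); each stratum's clock is reset, so rows are recorded as
#' `(0, gap]`.  A first event whose baseline-to-scan midpoint falls before
#' stool collection is excluded from the likelihood but still advances the
#' event ordering and counts toward the truncation cap.  Events are
#' truncated after the first `max_events`.
#'
#' @param timeline a [subject_timeline()]; must contain a baseline MRI
#'   (day <= 0).
#' @param lesion_type `"gad"` or `"t2"`.
#' @param max_events truncation cap on lesion events (default 2).
#' @return data.frame with columns `subject`, `stratum`, `start` (always
#'   0), `stop` (gap length, possibly half-integer), `event`, `cal_stop`
#'   (calendar day of the interval end), `prev_scan_day`, `term_scan_day`
#'   (the scans bracketing the interval end, used for the DMT rule);
#'   attribute `outcome_type = "mri"`.  Zero rows, with a warning, when no
#'   post-stool scans exist.
#' @export
build_mri_intervals <- function(timeline, lesion_type = c("gad", "t2"),
                                max_events = 2) {
  stopifnot(inherits(timeline, "subject_timeline"))
  lesion_type <- match.arg(lesion_type)
  scans <- timeline$mri_scans
  base <- scans[scans$is_baseline == 1, , drop = FALSE]
  if (nrow(base) != 1 || base$day > 0)
    stop_invalid("subject ", timeline$subject_id,
                 " has no baseline MRI (exactly one scan with day <= 0 required)")
  post <- scans[scans$day > 0, , drop = FALSE]
  empty <- data.frame(subject = character(0), stratum = integer(0),
                      start = numeric(0), stop = numeric(0),
                      event = integer(0), cal_stop = numeric(0),
                      prev_scan_day = numeric(0), term_scan_day = numeric(0))
  attr(empty, "outcome_type") <- "mri"
  if (!nrow(post)) {
    warning("subject ", timeline$subject_id, ": no post-stool MRI scans")
    return(empty)
  }
  flag <- if (lesion_type == "gad") post$gad_event else post$t2_event
  days <- post$day
  prev_day <- c(base$day, days[-length(days)])  # scan preceding each scan
  last_scan <- days[length(days)]

  rows <- list()
  stratum <- 1L
  risk_start_cal <- 0      # calendar day at-risk begins for current stratum
  n_events <- 0L
  for (i in seq_along(days)) {
    if (n_events >= max_events) break
    if (flag[i] == 1) {
      mid <- (days[i] + prev_day[i]) / 2
      n_events <- n_events + 1L
      excluded <- (stratum == 1L && mid < 0)
      if (!excluded) {
        gap <- mid - risk_start_cal
        if (gap > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = stratum, start = 0, stop = gap, event = 1L,
            cal_stop = mid, prev_scan_day = prev_day[i],
            term_scan_day = days[i])
      }
      stratum <- stratum + 1L
      risk_start_cal <- days[i]   # next stratum starts on the event's scan date
    }
  }
  # censored tail: only if follow-up was not closed by the max_events-th event
  if (n_events < max_events && last_scan > risk_start_cal) {
    i_last <- length(days)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = stratum, start = 0, stop = last_scan - risk_start_cal,
      event = 0L, cal_stop = last_scan, prev_scan_day = prev_day[i_last],
      term_scan_day = last_scan)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- cbind(subject = timeline$subject_id, out)
  rownames(out) <- NULL
  attr(out, "outcome_type") <- "mri"
  out
}

#' Attach model covariates to a risk-interval table
#'
#' Adds the adjustment covariates and the feature of interest.  Sex is
#' fixed; age is time-varying ("age at event"), evaluated at each
#' interval's terminal calendar day as `age_at_stool + cal_stop/365.25`.
#' DMT exposure follows the outcome-specific rule: for relapse intervals,
#' exposure in the 90 days before the interval's terminal time; for MRI
#' intervals, exposure at any point between the terminal scan and the scan
#' before it.  Censored intervals use the same rule evaluated at the
#' censoring time.  The feature is constant within subject (measured at
#' stool collection).
#'
#' @param intervals output of [build_relapse_intervals()] or
#'   [build_mri_intervals()] (possibly row-bound over subjects, keeping the
#'   `outcome_type` attribute).
#' @param timelines a single [subject_timeline()] or a list of them named
#'   or identifiable by `subject_id`.
#' @param feature optional per-subject feature: a [dichotomized feature]
#'   (values named by subject), or a named numeric vector.  Added as column
#'   `feature`.
#' @return the interval table with columns `sex`, `age`, `dmt` (and
#'   `feature` when supplied) appended.
#' @export
attach_covariates <- function(intervals, timelines, feature = NULL) {
  type <- attr(intervals, "outcome_type")
  if (is.null(type)) stop_invalid("interval table lacks its outcome_type attribute")
  if (inherits(timelines, "subject_timeline")) timelines <- list(timelines)
  tl_ids <- vapply(timelines, function(t) t$subject_id, character(1))
  names(timelines) <- tl_ids
  miss <- setdiff(unique(intervals$subject), tl_ids)
  if (length(miss))
    stop_invalid("no timeline for subject(s): ", paste(miss, collapse = ", "))

  fvals <- NULL
  if (!is.null(feature)) {
    if (inherits(feature, "dichotomized_feature")) fvals <- feature$values
    else fvals <- feature
    if (is.null(names(fvals)))
      stop_invalid("feature values must be named by subject id")
    fmiss <- setdiff(unique(intervals$subject), names(fvals))
    if (length(fmiss))
      stop_invalid("feature missing for subject(s): ", paste(fmiss, collapse = ", "))
  }

  n <- nrow(intervals)
  sex <- age <- dmt <- numeric(n)
  for (i in seq_len(n)) {
    tl <- timelines[[intervals$subject[i]]]
    sex[i] <- tl$sex
    age[i] <- tl$age_at_stool + intervals$cal_stop[i] / 365.25
    dmt[i] <- if (type == "relapse") {
      dmt_overlap(tl$dmt_intervals, intervals$cal_stop[i] - 90,
                  intervals$cal_stop[i])
    } else {
      dmt_overlap(tl$dmt_intervals, intervals$prev_scan_day[i],
                  intervals$term_scan_day[i])
    }
  }
  intervals$sex <- sex
  intervals$age <- age
  intervals$dmt <- dmt
  if (!is.null(fvals)) intervals$feature <- as.numeric(fvals[intervals$subject])
  intervals
}

# 1 if any exposure interval overlaps [lo, hi]
dmt_overlap <- function(dmt, lo, hi) {
  if (!nrow(dmt)) return(0)
  as.numeric(any(dmt$start_day <= hi & dmt$end_day >= lo))
}

#' Row-bind per-subject interval tables, preserving the outcome type
#'
#' @param tables list of interval tables of the same outcome type.
#' @return single interval table.
#' @export
bind_intervals <- function(tables) {
  tables <- Filter(function(t) nrow(t) > 0, tables)
  if (!length(tables))
    stop_invalid("no non-empty interval tables to bind")
  types <- unique(vapply(tables, function(t) attr(t, "outcome_type"), character(1)))
  if (length(types) != 1) stop_invalid("mixed outcome types")
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  attr(out, "outcome_type") <- types
  out
}
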