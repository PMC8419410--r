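#' Construct a subject timeline
#'
#' A subject's event history on the study clock: integer days relative to
#' stool collection (day 0).  Relapses must be strictly post-baseline and
#' separated by the 30-day refractory period (by definition a new relapse
#' is at least 30 days after the previous one).  MRI scans carry binary
#' new-lesion flags relative to the prior scan; the baseline MRI is the
#' scan closest to, but before, stool collection.
#'
#' @param subject_id character id.
#' @param sex 1 = female, 0 = male.
#' @param age_at_stool age in years at stool collection.
#' @param relapse_days ascending integer days (> 0) of relapses.
#' @param last_visit_day final clinic visit day (> 0) closing clinical
#'   follow-up.
#' @param mri_scans data.frame with columns `day`, `gad_event`, `t2_event`,
#'   `is_baseline`; may have zero rows.
#' @param dmt_intervals data.frame with columns `start_day`, `end_day`
#'   (half-open on neither side; overlapping intervals are merged).
#' @return object of class `subject_timeline`.
#' @export
subject_timeline <- function(subject_id, sex, age_at_stool,
                             relapse_days = integer(0),
                             last_visit_day,
                             mri_scans = empty_mri(),
                             dmt_intervals = empty_dmt()) {
  relapse_days <- as.numeric(sort(relapse_days))
  if (length(relapse_days)) {
    if (any(relapse_days <= 0))
      stop_invalid("relapse days must be > 0 (post stool collection)")
    if (length(relapse_days) > 1 && any(diff(relapse_days) < 30))
      stop_invalid("relapse gaps must be >= 30 days (refractory period)")
    if (any(relapse_days > last_visit_day))
      stop_invalid("relapse after the last clinic visit")
  }
  if (!is.numeric(last_visit_day) || last_visit_day <= 0)
    stop_invalid("last_visit_day must be > 0")
  mri_scans <- as.data.frame(mri_scans)
  if (nrow(mri_scans)) {
    need <- c("day", "gad_event", "t2_event", "is_baseline")
    if (!all(need %in% names(mri_scans)))
      stop_invalid("mri_scans must have columns ", paste(need, collapse = ", "))
    mri_scans <- mri_scans[order(mri_scans$day), , drop = FALSE]
    if (any(mri_scans$day[mri_scans$is_baseline == 1] > 0))
      stop_invalid("baseline MRI must be on or before day 0")
  }
  dmt_intervals <- normalize_dmt(as.data.frame(dmt_intervals))
  structure(list(
    subject_id = as.character(subject_id),
    sex = as.numeric(sex),
    age_at_stool = as.numeric(age_at_stool),
    relapse_days = relapse_days,
    last_visit_day = as.numeric(last_visit_day),
    mri_scans = mri_scans,
    dmt_intervals = dmt_intervals
  ), class = "subject_timeline")
}

empty_mri <- function() {
  data.frame(day = numeric(0), gad_event = integer(0), t2_event = integer(0),
             is_baseline = integer(0))
}

empty_dmt <- function() {
  data.frame(start_day = numeric(0), end_day = numeric(0))
}

# merge overlapping DMT exposure intervals
normalize_dmt <- function(dmt) {
  if (!nrow(dmt)) return(empty_dmt())
  if (!all(c("start_day", "end_day") %in% names(dmt)))
    stop_invalid("dmt_intervals must have columns start_day, end_day")
  dmt <- dmt[order(dmt$start_day), , drop = FALSE]
  out_s <- dmt$start_day[1]; out_e <- dmt$end_day[1]
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(nrow(dmt))[-1]) {
    if (dmt$start_day[i] <= out_e) {
      out_e <- max(out_e, dmt$end_day[i])
    } else {
      starts <- c(starts, out_s); ends <- c(ends, out_e)
      out_s <- dmt$start_day[i]; out_e <- dmt$end_day[i]
    }
  }
  data.frame(start_day = c(starts, out_s), end_day = c(ends, out_e))
}

#' @export
print.subject_timeline <- function(x, ...) {
  cat("Subject", x$subject_id, "- sex:", x$sex,
      "age:", round(x$age_at_stool, 1), "\n")
  cat("  relapses:", if (length(x$relapse_days)) paste(x$relapse_days, collapse = ", ") else "none",
      "| last visit day:", x$last_visit_day, "\n")
  cat("  MRI scans:", nrow(x$mri_scans),
      "| DMT intervals:", nrow(x$dmt_intervals), "\n")
  invisible(x)
}

#' Binary disease-activity summaries for one subject
#'
#' Computes the over-follow-up outcome flags used by the community-level
#' (PERMANOVA) analyses: a clinically meaningful annualized relapse rate
#' (>= 0.5 relapses/year, i.e. more than one relapse over two years), any
#' new gadolinium-enhancing lesion, and any new or enlarging T2 lesion.
#'
#' @param timeline a [subject_timeline()].
#' @return named logical vector `(relapse_rate, any_gad, any_t2)`.
#' @export
activity_flags <- function(timeline) {
  stopifnot(inherits(timeline, "subject_timeline"))
  if (timeline$last_visit_day <= 0)
    stop_invalid("zero follow-up: last_visit_day must be > 0")
  years <- timeline$last_visit_day / 365.25
  post <- timeline$mri_scans[timeline$mri_scans$day > 0, , drop = FALSE]
  c(relapse_rate = length(timeline$relapse_days) / years >= 0.5,
    any_gad = nrow(post) > 0 && any(post$gad_event == 1),
    any_t2 = nrow(post) > 0 && any(post$t2_event == 1))
}
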