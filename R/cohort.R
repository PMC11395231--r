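# Longitudinal cohort analysis: baseline comparison, treatment-course
# classification, rebound (interval-increase) detection, and
# responsive/resistant phase labeling of detected CHCs.
#
# "Undetectable" always means a normalized CHC count of exactly zero: raw
# counts are integers scaled by a positive constant, so no epsilon is needed.

#' Compare baseline CHC counts between patients and healthy subjects
#'
#' The baseline for a patient is the last sample collected at or before
#' treatment start; healthy subjects contribute their first sample. The
#' comparison uses [mann_whitney()] on normalized CHC counts.
#'
#' @param patients,healthy Lists of `subject_timeline` objects.
#' @return An `mw_test` object.
#' @export
compare_baseline <- function(patients, healthy) {
  px <- vapply(patients, baseline_chc, numeric(1))
  hy <- vapply(healthy, function(tl) tl$samples$chc_per_50k[1], numeric(1))
  mann_whitney(px, hy)
}

baseline_chc <- function(tl) {
  stopifnot(inherits(tl, "subject_timeline"))
  if (tl$cohort != "patient" || is.na(tl$treatment_start)) {
    stop_input("subject %s is not a patient timeline with a treatment start", tl$subject_id)
  }
  pre <- which(tl$samples$days_from_treatment_start <= tl$treatment_start)
  if (length(pre) == 0) {
    stop_input("subject %s has no baseline sample at or before treatment start", tl$subject_id)
  }
  tl$samples$chc_per_50k[max(pre)]
}

#' Classify a patient's treatment course
#'
#' Reproduces the clinical course taxonomy: whether the on-trial nadir was
#' undetectable (some post-treatment on-trial sample at zero), whether counts
#' were increased again by the end of trial (last on-trial sample positive
#' after a zero nadir), the post-trial surveillance status (evaluated on
#' samples after `trial_end`; `not_available` if there are none), and the
#' first rebound: its magnitude (`interval_increase`, the first post-nadir
#' positive normalized count, measured from the zero nadir) and its time.
#'
#' @param timeline A patient `subject_timeline` with `trial_end` set.
#' @return A list of class `course_summary`: `subject_id`, `nadir_status`,
#'   `end_of_trial_status`, `post_trial_status`, `interval_increase`
#'   (`NA` if no rebound), `time_of_first_rebound` (`NA` if none).
#' @export
classify_course <- function(timeline) {
  stopifnot(inherits(timeline, "subject_timeline"))
  if (timeline$cohort != "patient") {
    stop_input("classify_course expects a patient timeline, got cohort '%s'",
               timeline$cohort)
  }
  if (is.na(timeline$trial_end)) {
    stop_input("subject %s has no trial_end", timeline$subject_id)
  }
  s <- timeline$samples
  days <- s$days_from_treatment_start
  chc <- s$chc_per_50k
  post_tx <- days > timeline$treatment_start
  on_trial <- post_tx & days <= timeline$trial_end
  post_trial <- days > timeline$trial_end

  nadir_status <- if (any(on_trial & chc == 0)) "undetectable" else "detectable"

  last_on <- which(on_trial)
  end_status <- "undetectable"
  if (length(last_on) > 0) {
    li <- max(last_on)
    zero_before <- any(on_trial & chc == 0 & seq_along(chc) < li)
    if (chc[li] > 0 && zero_before) end_status <- "increased"
  }

  post_status <- if (!any(post_trial)) {
    "not_available"
  } else if (any(post_trial & chc > 0)) {
    "increased"
  } else {
    "undetectable"
  }

  interval_increase <- NA_real_
  rebound_time <- NA_real_
  zeros <- which(post_tx & chc == 0)
  if (length(zeros) > 0) {
    reb <- which(seq_along(chc) > min(zeros) & chc > 0)
    if (length(reb) > 0) {
      interval_increase <- chc[min(reb)]
      rebound_time <- days[min(reb)]
    }
  }

  structure(list(subject_id = timeline$subject_id,
                 nadir_status = nadir_status,
                 end_of_trial_status = end_status,
                 post_trial_status = post_status,
                 interval_increase = interval_increase,
                 time_of_first_rebound = rebound_time),
            class = "course_summary")
}

#' @export
print.course_summary <- function(x, ...) {
  cat(sprintf("<course_summary> %s: nadir %s, end of trial %s, post-trial %s",
              x$subject_id, x$nadir_status, x$end_of_trial_status,
              x$post_trial_status))
  if (!is.na(x$interval_increase)) {
    cat(sprintf(", rebound +%.2f/50k at day %g", x$interval_increase,
                x$time_of_first_rebound))
  }
  cat("\n")
  invisible(x)
}

#' Label each sample's detected CHCs as treatment-responsive or -resistant
#'
#' Treatment-responsive CHCs are cells detected from the onset of treatment
#' until counts first become undetectable; treatment-resistant CHCs are
#' recurrent cells identified after a period of undetectable counts. Samples
#' with zero CHCs are labeled `none`. The label of a sample propagates to
#' every CHC crop drawn from it.
#'
#' @param timeline A patient `subject_timeline`.
#' @return Data frame over samples at or after treatment start: `sample_id`,
#'   `days_from_treatment_start`, `chc_per_50k`, `phase` (responsive /
#'   resistant / none).
#' @export
label_chc_phases <- function(timeline) {
  stopifnot(inherits(timeline, "subject_timeline"))
  if (timeline$cohort != "patient") {
    stop_input("phase labels are defined for patient timelines only")
  }
  s <- timeline$samples
  keep <- s$days_from_treatment_start >= timeline$treatment_start
  if (!any(keep)) {
    stop_input("subject %s has no samples at or after treatment start",
               timeline$subject_id)
  }
  s <- s[keep, , drop = FALSE]
  chc <- s$chc_per_50k
  first_zero <- match(TRUE, chc == 0)
  phase <- rep("none", length(chc))
  if (is.na(first_zero)) {
    phase[chc > 0] <- "responsive"
  } else {
    idx <- seq_along(chc)
    phase[chc > 0 & idx < first_zero] <- "responsive"
    phase[chc > 0 & idx > first_zero] <- "resistant"
  }
  data.frame(sample_id = s$sample_id,
             days_from_treatment_start = s$days_from_treatment_start,
             chc_per_50k = chc, phase = phase, stringsAsFactors = FALSE)
}

#' Summarize a cohort of timelines
#'
#' Medians and ranges of baseline counts, samples per subject, and interval
#' increases, plus counts of course categories, reported the way clinical
#' descriptive tables are (continuous variables as median (range), categorical
#' as counts).
#'
#' @param timelines List of `subject_timeline` objects (patients and/or
#'   healthy subjects).
#' @return A list of class `cohort_summary` with elements `n_patients`,
#'   `n_healthy`, `baseline`, `samples_per_subject`, `interval_increase`
#'   (each `c(median, min, max)`), `courses` (data frame of per-patient course
#'   summaries), and `course_counts`.
#' @export
summarize_cohort <- function(timelines) {
  if (length(timelines) == 0) stop_input("empty cohort")
  is_pat <- vapply(timelines, function(t) t$cohort == "patient", logical(1))
  pats <- timelines[is_pat]
  nspls <- vapply(timelines, function(t) nrow(t$samples), numeric(1))
  med_range <- function(v) {
    if (length(v) == 0) c(median = NA_real_, min = NA_real_, max = NA_real_)
    else c(median = stats::median(v), min = min(v), max = max(v))
  }
  baselines <- if (length(pats)) vapply(pats, baseline_chc, numeric(1)) else numeric(0)
  courses <- NULL
  increases <- numeric(0)
  if (length(pats)) {
    cs <- lapply(pats, classify_course)
    courses <- do.call(rbind, lapply(cs, function(x) {
      data.frame(subject_id = x$subject_id, nadir_status = x$nadir_status,
                 end_of_trial_status = x$end_of_trial_status,
                 post_trial_status = x$post_trial_status,
                 interval_increase = x$interval_increase,
                 time_of_first_rebound = x$time_of_first_rebound,
                 stringsAsFactors = FALSE)
    }))
    increases <- courses$interval_increase[!is.na(courses$interval_increase)]
  }
  structure(list(
    n_patients = sum(is_pat), n_healthy = sum(!is_pat),
    baseline = med_range(baselines),
    samples_per_subject = med_range(nspls),
    interval_increase = med_range(increases),
    courses = courses,
    course_counts = if (!is.null(courses)) {
      table(nadir = courses$nadir_status, end_of_trial = courses$end_of_trial_status)
    } else NULL
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f (%.2f-%.2f)", v[1], v[2], v[3])
  cat(sprintf("<cohort_summary> %d patients, %d healthy\n", x$n_patients, x$n_healthy))
  cat("  baseline CHC/50k, median (range):      ", fmt(x$baseline), "\n")
  cat("  samples per subject, median (range):   ", fmt(x$samples_per_subject), "\n")
  if (!all(is.na(x$interval_increase))) {
    cat("  interval increase/50k, median (range): ", fmt(x$interval_increase), "\n")
  }
  invisible(x)
}
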