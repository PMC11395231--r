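# Marker gating against unstained control cells, and per-sample enumeration
# normalized to 50,000 PBMCs.
#
# Positivity thresholds for CK and CD45 are taken as a high percentile
# (default 99.5) of the per-cell mean intensities of the unstained control
# cells imaged on the same slide. A cell is positive on a channel only if its
# mean intensity STRICTLY exceeds the threshold; boundary values are called
# negative. Classes: CK+/CD45+ -> CHC, CK+/CD45- -> CTC, CK-/CD45+ ->
# leukocyte, CK-/CD45- -> negative.

GATE_LABELS <- c("CHC", "CTC", "leukocyte", "negative")

#' Establish gating thresholds from unstained control cells
#'
#' The threshold on each marker channel is the given percentile (linear
#' interpolation of the empirical CDF) of the control cells' per-cell mean
#' intensities on that channel.
#'
#' @param control_records A `cell_records` data frame in which every row has
#'   `is_control = TRUE`.
#' @param percentile Percentile in (50, 100); default 99.5 bounds the
#'   per-channel false-positive rate at roughly 0.5%.
#' @param min_control Minimum number of control cells required.
#' @return A list of class `gating_thresholds` with elements `threshold`
#'   (named numeric, CK and CD45), `percentile_used`, `n_control_cells`.
#' @export
establish_thresholds <- function(control_records, percentile = 99.5,
                                 min_control = 30) {
  check_scalar_num(percentile, "percentile")
  if (percentile <= 50 || percentile >= 100) {
    stop_input("`percentile` must lie strictly between 50 and 100")
  }
  if (!all(c("mean_CK", "mean_CD45", "is_control") %in% names(control_records))) {
    stop_input("`control_records` must be a cell_records data frame")
  }
  if (nrow(control_records) > 0 && !all(control_records$is_control)) {
    stop_input("non-control cell present in `control_records`")
  }
  if (nrow(control_records) < min_control) {
    stop_input("need at least %d control cells to establish thresholds, got %d",
               min_control, nrow(control_records))
  }
  thr <- c(
    CK = percentile_lin(control_records$mean_CK, percentile),
    CD45 = percentile_lin(control_records$mean_CD45, percentile)
  )
  structure(list(threshold = thr, percentile_used = percentile,
                 n_control_cells = nrow(control_records)),
            class = "gating_thresholds")
}

#' @export
print.gating_thresholds <- function(x, ...) {
  cat(sprintf("<gating_thresholds> CK > %.4g, CD45 > %.4g (%.4g th percentile of %d control cells)\n",
              x$threshold["CK"], x$threshold["CD45"], x$percentile_used,
              x$n_control_cells))
  invisible(x)
}

#' Classify segmented cells by marker positivity
#'
#' Control cells are excluded from calls. Positivity is strict (`mean
#' intensity > threshold`); ties are negative.
#'
#' @param records A `cell_records` data frame.
#' @param thresholds A [establish_thresholds()] result.
#' @return Data frame with one row per non-control cell: `cell_id`, `label`
#'   (factor with levels CHC, CTC, leukocyte, negative).
#' @export
classify_cells <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "gating_thresholds"))
  rec <- records[!records$is_control, , drop = FALSE]
  ck_pos <- rec$mean_CK > thresholds$threshold["CK"]
  cd45_pos <- rec$mean_CD45 > thresholds$threshold["CD45"]
  label <- ifelse(ck_pos & cd45_pos, "CHC",
           ifelse(ck_pos, "CTC",
           ifelse(cd45_pos, "leukocyte", "negative")))
  data.frame(cell_id = rec$cell_id,
             label = factor(label, levels = GATE_LABELS),
             stringsAsFactors = FALSE)
}

#' Normalize a raw cell count to 50,000 PBMCs
#'
#' Returns `raw_count * 50000 / total_pbmcs` at full precision; rounding to
#' two decimals happens only at I/O boundaries.
#'
#' @param raw_count Non-negative integer count(s).
#' @param total_pbmcs Positive total PBMCs scanned for the sample.
#' @return Numeric normalized count(s) per 50,000 PBMCs.
#' @export
normalize_per_50k <- function(raw_count, total_pbmcs) {
  if (any(!is.finite(total_pbmcs)) || any(total_pbmcs <= 0)) {
    stop_input("`total_pbmcs` must be positive")
  }
  if (any(!is.finite(raw_count)) || any(raw_count < 0)) {
    stop_input("`raw_count` must be non-negative")
  }
  raw_count * 50000 / total_pbmcs
}

#' Enumerate one sample from its cell calls
#'
#' Tallies raw counts per label and normalizes them per 50,000 PBMCs. By
#' default the PBMC denominator is the number of segmented non-control cells
#' in the sample (i.e. the number of calls).
#'
#' @param calls Data frame from [classify_cells()].
#' @param metadata List with `sample_id`, `subject_id`,
#'   `days_from_treatment_start`, and optional `event`.
#' @param total_pbmcs Positive denominator; `NULL` uses `nrow(calls)`.
#' @return One-row data frame in the shared enumeration dialect: identifiers,
#'   `raw_chc`, `raw_ctc`, `raw_leukocyte`, `raw_negative`, `total_pbmcs`,
#'   `chc_per_50k`, `ctc_per_50k`, `event`.
#' @export
enumerate_sample <- function(calls, metadata = list(), total_pbmcs = NULL) {
  if (anyDuplicated(calls$cell_id)) {
    stop_input("duplicate cell_id in calls")
  }
  if (is.null(total_pbmcs)) total_pbmcs <- nrow(calls)
  if (nrow(calls) > 0) check_scalar_num(total_pbmcs, "total_pbmcs", 1)
  raw <- table(factor(calls$label, levels = GATE_LABELS))
  norm_chc <- if (nrow(calls) == 0) 0 else normalize_per_50k(raw[["CHC"]], total_pbmcs)
  norm_ctc <- if (nrow(calls) == 0) 0 else normalize_per_50k(raw[["CTC"]], total_pbmcs)
  data.frame(
    sample_id = metadata$sample_id %||% "sample",
    subject_id = metadata$subject_id %||% "subject",
    days_from_treatment_start = metadata$days_from_treatment_start %||% NA_real_,
    raw_chc = as.integer(raw[["CHC"]]),
    raw_ctc = as.integer(raw[["CTC"]]),
    raw_leukocyte = as.integer(raw[["leukocyte"]]),
    raw_negative = as.integer(raw[["negative"]]),
    total_pbmcs = as.integer(if (nrow(calls) == 0) 0 else total_pbmcs),
    chc_per_50k = norm_chc,
    ctc_per_50k = norm_ctc,
    event = metadata$event %||% "",
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gate a segmented field end to end
#'
#' Thresholds from the field's control cells, calls for the non-control
#' cells, and a one-row enumeration.
#'
#' @param records A `cell_records` data frame containing control cells.
#' @param metadata Passed to [enumerate_sample()].
#' @param percentile,min_control See [establish_thresholds()].
#' @return List with `thresholds`, `calls`, and `enumeration`.
#' @export
gate_sample <- function(records, metadata = list(), percentile = 99.5,
                        min_control = 30) {
  thresholds <- establish_thresholds(records[records$is_control, , drop = FALSE],
                                     percentile = percentile,
                                     min_control = min_control)
  calls <- classify_cells(records, thresholds)
  list(thresholds = thresholds, calls = calls,
       enumeration = enumerate_sample(calls, metadata))
}
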