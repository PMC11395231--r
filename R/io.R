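# File dialects shared across stages.
#
# Image fields travel as multi-page 32-bit float TIFFs (one page per channel,
# intensities scaled to [0, 1] by a factor recorded in the sidecar) plus a
# JSON sidecar carrying the channel order, the control-region bounding box,
# the scale factor, and any planted ground truth. Cohorts travel as a flat
# CSV, one row per sample, with treatment events as free-text markers.

#' Write an image field (TIFF + JSON sidecar)
#'
#' @param field An `image_field`.
#' @param path Path of the TIFF to write; the sidecar is `<path>.json`.
#' @param ground_truth Optional planted ground-truth data frame.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, ground_truth = NULL) {
  stopifnot(inherits(field, "image_field"))
  scale <- max(field$pixels, 1e-12)
  pages <- lapply(1:3, function(ch) field$pixels[, , ch] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cm <- field$control_mask
  rows <- which(apply(cm, 1, any))
  cols <- which(apply(cm, 2, any))
  bbox <- if (length(rows)) {
    c(min(rows) - 1L, min(cols) - 1L, max(rows), max(cols))  # 0-based half-open
  } else {
    c(0L, 0L, 0L, 0L)
  }
  sidecar <- list(
    sample_id = field$sample_id,
    channel_order = field$channel_names,
    intensity_scale = scale,
    control_bbox = as.integer(bbox),
    ground_truth = ground_truth
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image field written by [write_field()]
#'
#' @param path Path of the TIFF (sidecar expected at `<path>.json`).
#' @return A list with `field` (an `image_field`) and `ground_truth` (data
#'   frame or `NULL`).
#' @export
read_field <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop_input("expected a 3-page TIFF, got %d pages", length(pages))
  H <- nrow(pages[[1]])
  W <- ncol(pages[[1]])
  pix <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) pix[, , ch] <- pages[[ch]] * side$intensity_scale
  cm <- matrix(FALSE, H, W)
  bb <- side$control_bbox
  if (bb[3] > bb[1] && bb[4] > bb[2]) {
    cm[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] <- TRUE
  }
  gt <- side$ground_truth
  if (!is.null(gt) && length(gt) == 0) gt <- NULL
  list(field = new_image_field(pix, cm, side$sample_id), ground_truth = gt)
}

#' Write a cohort of timelines as the shared enumeration CSV
#'
#' Columns: `subject_id`, `cohort`, `sample_index`,
#' `days_from_treatment_start`, `raw_chc`, `raw_ctc`, `total_pbmcs`, `event`.
#' Treatment start and trial end are encoded as `treatment_start` /
#' `trial_end:<day>` markers in `event`. Normalized counts are derived on
#' read (and rounded only for display).
#'
#' @param timelines List of `subject_timeline` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(timelines, path) {
  rows <- lapply(timelines, function(tl) {
    s <- tl$samples
    ev <- s$event
    if (tl$cohort == "patient" && !is.na(tl$trial_end)) {
      ev[1] <- paste0(ev[1], ifelse(nzchar(ev[1]), ";", ""),
                      "trial_end:", tl$trial_end)
    }
    data.frame(subject_id = tl$subject_id, cohort = tl$cohort,
               sample_index = seq_len(nrow(s)),
               days_from_treatment_start = s$days_from_treatment_start,
               raw_chc = s$raw_chc, raw_ctc = s$raw_ctc,
               total_pbmcs = s$total_pbmcs, event = ev,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV back into timelines
#'
#' @param path CSV path written by [write_cohort_csv()].
#' @return List of `subject_timeline` objects.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort", "sample_index",
            "days_from_treatment_start", "raw_chc", "raw_ctc",
            "total_pbmcs", "event")
  if (!all(need %in% names(df))) {
    stop_input("cohort CSV missing columns: %s",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$sample_index), , drop = FALSE]
    cohort <- d$cohort[1]
    treatment_start <- NA_real_
    trial_end <- NA_real_
    if (cohort == "patient") {
      treatment_start <- 0
      m <- regmatches(d$event, regexpr("trial_end:[0-9.]+", d$event))
      m <- unlist(m)
      if (length(m)) trial_end <- as.numeric(sub("trial_end:", "", m[1]))
    }
    samples <- data.frame(
      sample_id = sprintf("%s_S%02d", d$subject_id, d$sample_index),
      subject_id = d$subject_id,
      days_from_treatment_start = d$days_from_treatment_start,
      raw_chc = d$raw_chc, raw_ctc = d$raw_ctc,
      total_pbmcs = d$total_pbmcs,
      chc_per_50k = normalize_per_50k(d$raw_chc, d$total_pbmcs),
      ctc_per_50k = normalize_per_50k(d$raw_ctc, d$total_pbmcs),
      event = sub(";?trial_end:[0-9.]+", "", d$event),
      stringsAsFactors = FALSE
    )
    subject_timeline(d$subject_id[1], cohort, samples,
                     treatment_start = treatment_start, trial_end = trial_end)
  })
}

#' Write per-cell records to CSV
#' @param records A `cell_records` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Write an embedding set (matrix + labels + features, optional UMAP) to CSV
#' @param embedding_set An `embedding_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings_csv <- function(embedding_set, path) {
  m <- embedding_set$matrix
  colnames(m) <- sprintf("z%02d", seq_len(ncol(m)))
  df <- data.frame(phase = embedding_set$phase, m, embedding_set$features,
                   stringsAsFactors = FALSE)
  if (!is.null(embedding_set$umap)) {
    df$UMAP1 <- embedding_set$umap[, 1]
    df$UMAP2 <- embedding_set$umap[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
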