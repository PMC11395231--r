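# Crop extraction, padding, and per-sample median normalization for the
# latent model.

#' Crop a 64 x 64 x 3 window around a segmented cell
#'
#' The crop is centered on the cell's centroid; area outside the field is
#' zero-padded, and cells larger than the window are center-cropped to 64.
#'
#' @param field An `image_field`.
#' @param record One row of a `cell_records` data frame (0-based centroid).
#' @return A list of class `chc_crop`: `tensor` (64 x 64 x 3), `sample_id`,
#'   `cell_id`, `phase` (initially "unknown").
#' @export
crop_and_pad <- function(field, record) {
  stopifnot(inherits(field, "image_field"))
  d <- dim(field$pixels)
  r0 <- record$centroid_row
  c0 <- record$centroid_col
  if (is.na(r0) || is.na(c0) || r0 < 0 || c0 < 0 || r0 > d[1] - 1 || c0 > d[2] - 1) {
    stop_input("cell centroid (%s, %s) lies outside the field", r0, c0)
  }
  cr <- round(r0) + 1   # to 1-based
  cc <- round(c0) + 1
  rows <- (cr - 31):(cr + 32)
  cols <- (cc - 31):(cc + 32)
  tensor <- array(0, dim = c(64L, 64L, 3L))
  rin <- rows >= 1 & rows <= d[1]
  cin <- cols >= 1 & cols <= d[2]
  tensor[rin, cin, ] <- field$pixels[rows[rin], cols[cin], , drop = FALSE]
  structure(list(tensor = tensor, sample_id = field$sample_id,
                 cell_id = record$cell_id, phase = "unknown"),
            class = "chc_crop")
}

#' Per-sample median normalization of crops
#'
#' Each channel of each crop is divided by its source sample's median
#' per-cell mean intensity on that channel (the median over all segmented
#' non-control cells), making crops comparable across samples with different
#' illumination or staining efficiency. Divisors are floored at `eps`.
#'
#' @param crops A `crop_set`, or a list of `chc_crop` objects.
#' @param sample_cell_records A `cell_records` data frame covering the crops'
#'   source sample(s), or a named list of them (by sample id). `NULL`
#'   self-normalizes a `crop_set` by the median of its own per-crop channel
#'   means (the whole set treated as one sample).
#' @param eps Floor for the per-channel divisor.
#' @return The same container with normalized tensors.
#' @export
normalize_crops <- function(crops, sample_cell_records = NULL, eps = 1e-6) {
  if (inherits(crops, "crop_set")) {
    n <- length(crops$phase)
    if (n == 0) stop_input("no crops to normalize")
    if (is.null(sample_cell_records)) {
      ch_means <- apply(crops$tensors, c(3, 4), mean)   # 3 x n
      med <- pmax(apply(ch_means, 1, stats::median), eps)
    } else {
      med <- sample_channel_medians(sample_cell_records, eps)
    }
    for (ch in 1:3) crops$tensors[, , ch, ] <- crops$tensors[, , ch, ] / med[ch]
    return(crops)
  }
  if (inherits(crops, "chc_crop")) crops <- list(crops)
  if (length(crops) == 0) stop_input("no crops to normalize")
  if (is.null(sample_cell_records)) {
    stop_input("`sample_cell_records` is required for field-derived crops")
  }
  recs_by_sample <- if (is.data.frame(sample_cell_records)) {
    sid <- attr(sample_cell_records, "sample_id") %||% crops[[1]]$sample_id
    stats::setNames(list(sample_cell_records), sid)
  } else {
    sample_cell_records
  }
  meds <- lapply(recs_by_sample, sample_channel_medians, eps = eps)
  lapply(crops, function(cr) {
    med <- meds[[cr$sample_id]]
    if (is.null(med)) {
      stop_input("no cell records for sample '%s'", cr$sample_id)
    }
    for (ch in 1:3) cr$tensor[, , ch] <- cr$tensor[, , ch] / med[ch]
    cr
  })
}

sample_channel_medians <- function(records, eps) {
  rec <- records[!records$is_control, , drop = FALSE]
  if (nrow(rec) == 0) stop_input("sample has no non-control cells to normalize against")
  pmax(c(stats::median(rec$mean_CK), stats::median(rec$mean_CD45),
         stats::median(rec$mean_DAPI)), eps)
}

# Stack crops into the (64, 64, 3, n) array the trainer consumes.
crops_to_array <- function(crops) {
  if (inherits(crops, "crop_set")) return(crops$tensors)
  if (inherits(crops, "chc_crop")) crops <- list(crops)
  if (is.array(crops) && length(dim(crops)) == 4L) return(crops)
  arr <- array(0, dim = c(64L, 64L, 3L, length(crops)))
  for (i in seq_along(crops)) arr[, , , i] <- crops[[i]]$tensor
  arr
}

crop_phases <- function(crops) {
  if (inherits(crops, "crop_set")) return(crops$phase)
  if (is.list(crops) && length(crops) && inherits(crops[[1]], "chc_crop")) {
    return(vapply(crops, function(x) x$phase, character(1)))
  }
  rep("unknown", dim(crops_to_array(crops))[4])
}

#' Per-crop morphology features
#'
#' Features in the style of per-cell feature maps: mean normalized CK, CD45,
#' and DAPI over the cell footprint (pixels with DAPI above 10% of the crop
#' maximum) and the footprint area in pixels.
#'
#' @param crops A `crop_set` or list of `chc_crop` objects.
#' @return Data frame with `mean_CK`, `mean_CD45`, `mean_DAPI`, `area_px`.
#' @export
crop_features <- function(crops) {
  arr <- crops_to_array(crops)
  n <- dim(arr)[4]
  out <- data.frame(mean_CK = numeric(n), mean_CD45 = numeric(n),
                    mean_DAPI = numeric(n), area_px = integer(n))
  for (i in seq_len(n)) {
    dapi <- arr[, , 3, i]
    fg <- dapi > 0.1 * max(dapi, 1e-12)
    if (!any(fg)) fg <- dapi >= 0
    out$mean_CK[i] <- mean(arr[, , 1, i][fg])
    out$mean_CD45[i] <- mean(arr[, , 2, i][fg])
    out$mean_DAPI[i] <- mean(dapi[fg])
    out$area_px[i] <- sum(fg)
  }
  out
}
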