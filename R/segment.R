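# Nuclear segmentation and membrane-guided cell expansion.
#
# DAPI nuclei are detected with a classical pipeline (Gaussian smoothing,
# Otsu threshold, hole filling, distance transform, watershed) and expanded
# into whole-cell masks along the CK/CD45 maximum projection. The stage is
# pluggable: any function mapping a field to an integer label image can stand
# in for `segment_field()`'s default, so a deep segmenter can be substituted
# without touching downstream gating.

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, Otsu thresholding, hole filling, then a distance
#' -transform watershed to split touching nuclei. Components smaller than
#' `min_area` are discarded as debris and labels are relabeled contiguously
#' `1..K`.
#'
#' @param dapi Numeric H x W matrix of non-negative DAPI intensities.
#' @param min_area Minimum component area in pixels.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param tolerance Watershed tolerance (intensity units of the distance map).
#' @return Integer H x W label matrix; background is 0, labels `1..K` are
#'   contiguous.
#' @export
segment_nuclei <- function(dapi, min_area = 20, smoothing_sigma = 1.5,
                           tolerance = 1) {
  dapi <- as.matrix(dapi)
  if (any(is.na(dapi)) || any(!is.finite(dapi))) {
    stop_input("DAPI image contains NA or non-finite pixels")
  }
  if (any(dapi < 0)) stop_input("DAPI intensities must be non-negative")
  mx <- max(dapi)
  if (mx == 0) {
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  img <- EBImage::Image(dapi / mx)
  sm <- EBImage::gblur(img, sigma = smoothing_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- EBImage::fillHull(sm > thr)
  if (sum(mask) == 0) {
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  relabel_min_area(as.matrix(EBImage::imageData(labels)), min_area)
}

# Drop components below min_area and relabel contiguously.
relabel_min_area <- function(labels, min_area) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_area)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

#' Expand nuclear labels into whole-cell labels
#'
#' Grows each nucleus along the membrane projection (the pixelwise maximum of
#' the CK and CD45 channels) using seeded Voronoi-style propagation. Growth is
#' confined to pixels above the membrane background level and within
#' `max_expand_px` of a nucleus, so cells remain disjoint and each nucleus
#' maps to exactly one cell covering it.
#'
#' @param nuclei_labels Integer label matrix from [segment_nuclei()].
#' @param membrane_projection Numeric matrix, pixelwise `max(CK, CD45)`.
#' @param max_expand_px Maximum expansion beyond the nucleus, in pixels.
#' @param background Membrane background level; pixels at or below it are
#'   never annexed. `NULL` estimates the noise floor robustly as
#'   `median + 5 * mad` of the projection (background pixels dominate a
#'   PBMC field, so the median and MAD are noise statistics).
#' @return Integer cell label matrix with the same labels as
#'   `nuclei_labels`.
#' @export
expand_to_cells <- function(nuclei_labels, membrane_projection,
                            max_expand_px = 8, background = NULL) {
  nuclei_labels <- matrix(as.integer(nuclei_labels),
                          nrow(nuclei_labels), ncol(nuclei_labels))
  membrane_projection <- as.matrix(membrane_projection)
  if (!all(dim(nuclei_labels) == dim(membrane_projection))) {
    stop_input("membrane projection shape does not match nuclei labels")
  }
  if (any(!is.finite(membrane_projection))) {
    stop_input("membrane projection contains non-finite pixels")
  }
  mx <- max(membrane_projection)
  if (max(nuclei_labels) == 0L || mx == 0) {
    return(nuclei_labels)
  }
  # Expansion decisions are taken on a lightly smoothed projection so that
  # single bright noise pixels are never annexed (raw-pixel thresholding
  # would select noise pixels biased high on the marker channels and corrupt
  # downstream per-cell means).
  smooth <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(membrane_projection / mx), sigma = 1.5))) * mx
  if (is.null(background)) {
    background <- stats::median(smooth) + 5 * stats::mad(smooth)
  }
  nuc_mask <- nuclei_labels > 0L
  # Distance of every non-nucleus pixel to the nearest nucleus pixel.
  dist_to_nuc <- as.matrix(EBImage::imageData(
    EBImage::distmap(EBImage::Image(1 - nuc_mask))))
  mask <- nuc_mask | (smooth > background & dist_to_nuc <= max_expand_px)
  cells <- EBImage::propagate(EBImage::Image(smooth / max(smooth)),
                              seeds = EBImage::Image(nuclei_labels),
                              mask = EBImage::Image(mask), lambda = 1e-4)
  matrix(as.integer(EBImage::imageData(cells)),
         nrow(nuclei_labels), ncol(nuclei_labels))
}

#' Extract per-cell records from a labeled field
#'
#' Computes, for every cell label, the centroid (0-based pixel coordinates),
#' half-open bounding box, area, and per-channel mean intensity over the cell
#' mask, and flags cells whose centroid lies inside the unstained control
#' region or whose mask touches the field border.
#'
#' @param field An `image_field`.
#' @param cell_labels Integer label matrix derived from this field.
#' @return Data frame of class `cell_records`, one row per cell: `cell_id`,
#'   `centroid_row`, `centroid_col`, `bbox_r0`, `bbox_c0`, `bbox_r1`,
#'   `bbox_c1` (half-open, 0-based), `area_px`, `mean_CK`, `mean_CD45`,
#'   `mean_DAPI`, `is_control`, `on_border`.
#' @export
extract_cell_records <- function(field, cell_labels) {
  stopifnot(inherits(field, "image_field"))
  cell_labels <- matrix(as.integer(cell_labels),
                        nrow(cell_labels), ncol(cell_labels))
  d <- dim(field$pixels)
  if (!all(dim(cell_labels) == d[1:2])) {
    stop_input("cell labels shape does not match field")
  }
  K <- max(cell_labels)
  empty <- data.frame(
    cell_id = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
    bbox_r0 = integer(0), bbox_c0 = integer(0), bbox_r1 = integer(0),
    bbox_c1 = integer(0), area_px = integer(0), mean_CK = numeric(0),
    mean_CD45 = numeric(0), mean_DAPI = numeric(0), is_control = logical(0),
    on_border = logical(0), stringsAsFactors = FALSE
  )
  if (K == 0L) {
    return(structure(empty, class = c("cell_records", "data.frame"),
                     sample_id = field$sample_id))
  }
  in_mask <- cell_labels > 0L
  lab <- cell_labels[in_mask]
  rows <- row(cell_labels)[in_mask]
  cols <- col(cell_labels)[in_mask]
  area <- tabulate(lab, nbins = K)
  present <- which(area > 0L)
  cr <- rowsum(rows, lab)[, 1] / area[present]
  cc <- rowsum(cols, lab)[, 1] / area[present]
  r0 <- tapply(rows, lab, min)
  r1 <- tapply(rows, lab, max)
  c0 <- tapply(cols, lab, min)
  c1 <- tapply(cols, lab, max)
  means <- vapply(1:3, function(ch) {
    v <- field$pixels[, , ch][in_mask]
    rowsum(v, lab)[, 1] / area[present]
  }, numeric(length(present)))
  means <- matrix(means, ncol = 3L)
  ctr_r <- pmin(pmax(round(cr), 1), d[1])
  ctr_c <- pmin(pmax(round(cc), 1), d[2])
  is_ctrl <- field$control_mask[cbind(ctr_r, ctr_c)]
  on_border <- (r0 == 1) | (c0 == 1) | (r1 == d[1]) | (c1 == d[2])
  rec <- data.frame(
    cell_id = present,
    centroid_row = unname(cr) - 1,
    centroid_col = unname(cc) - 1,
    bbox_r0 = as.integer(r0) - 1L,
    bbox_c0 = as.integer(c0) - 1L,
    bbox_r1 = as.integer(r1),
    bbox_c1 = as.integer(c1),
    area_px = area[present],
    mean_CK = unname(means[, 1]),
    mean_CD45 = unname(means[, 2]),
    mean_DAPI = unname(means[, 3]),
    is_control = unname(is_ctrl),
    on_border = unname(on_border),
    stringsAsFactors = FALSE
  )
  structure(rec, class = c("cell_records", "data.frame"),
            sample_id = field$sample_id)
}

#' Segment a field end to end
#'
#' Convenience wrapper: nuclei from DAPI, expansion along the CK/CD45
#' projection, then record extraction. The `segmenter` argument accepts any
#' replacement function `function(field, ...) -> label matrix`, so an
#' external deep segmenter can be plugged in.
#'
#' @param field An `image_field`.
#' @param min_area,smoothing_sigma,max_expand_px See [segment_nuclei()] and
#'   [expand_to_cells()].
#' @param segmenter Optional replacement segmentation function.
#' @return A list with `cell_labels` (integer matrix) and `records`
#'   (a `cell_records` data frame).
#' @export
segment_field <- function(field, min_area = 20, smoothing_sigma = 1.5,
                          max_expand_px = 8, segmenter = NULL) {
  stopifnot(inherits(field, "image_field"))
  if (is.null(segmenter)) {
    nuc <- segment_nuclei(field$pixels[, , 3], min_area = min_area,
                          smoothing_sigma = smoothing_sigma)
    memb <- pmax(field$pixels[, , 1], field$pixels[, , 2])
    cells <- expand_to_cells(nuc, memb, max_expand_px = max_expand_px)
  } else {
    cells <- segmenter(field)
  }
  list(cell_labels = cells, records = extract_cell_records(field, cells))
}
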