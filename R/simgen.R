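# Synthetic immunofluorescence fields, cell crops, and longitudinal cohorts.
#
# The generator emulates the statistical structure of stained PBMC slides:
# three channels (CK, CD45, DAPI), an unstained control region on the same
# slide, rare CK+/CD45+ hybrid cells among abundant CD45+ leukocytes, and
# longitudinal per-50,000-PBMC count trajectories (treatment-naive baseline,
# post-treatment nadir at zero, rebound under resistance). Every output is a
# deterministic function of its config, including the seed.

#' Configuration for one synthetic immunofluorescence field
#'
#' Cells are rendered as isotropic Gaussian disks: a nucleus on the DAPI
#' channel and a cytoplasm (radius 1.6x nuclear) on the marker channels the
#' cell's class expresses. Classes follow the gating chemistry: leukocytes are
#' CD45-only, CTCs CK-only, CHCs express both. Control cells are unstained
#' (DAPI only) and are confined to a reserved control strip on the left of the
#' field, mirroring the on-slide unstained control region used to set gating
#' thresholds.
#'
#' @param height_px,width_px Field size in pixels (>= 64).
#' @param n_leukocytes,n_chc,n_ctc,n_control_cells Planted cell counts.
#' @param cell_radius_px Length-2 numeric, min/max nuclear radius in pixels.
#' @param amplitude_means 4x3 numeric matrix of per-class (rows: leukocyte,
#'   CHC, CTC, control) per-channel (columns: CK, CD45, DAPI) peak amplitudes.
#'   Positive-marker amplitudes must exceed `5 * noise_sd` so that gating is
#'   exercised on separable data, not fought.
#' @param noise_sd Standard deviation of additive Gaussian camera noise
#'   (clipped at zero).
#' @param punctate_fraction Fraction of CK-positive cells whose CK stain is
#'   rendered as 3-6 discrete puncta instead of a diffuse disk.
#' @param control_frac Fraction of the field width reserved as the unstained
#'   control strip.
#' @param seed Integer seed; identical configs give bit-identical fields.
#' @return A list of class `field_config`.
#' @export
field_config <- function(height_px = 448, width_px = 480,
                         n_leukocytes = 80, n_chc = 3, n_ctc = 0,
                         n_control_cells = 100,
                         cell_radius_px = c(3.5, 5.5),
                         amplitude_means = NULL,
                         noise_sd = 2,
                         punctate_fraction = 0.2,
                         control_frac = 0.45,
                         seed = 1L) {
  check_scalar_num(height_px, "height_px", 64)
  check_scalar_num(width_px, "width_px", 64)
  for (nm in c("n_leukocytes", "n_chc", "n_ctc", "n_control_cells")) {
    check_scalar_num(get(nm), nm, 0)
  }
  if (length(cell_radius_px) != 2L || any(cell_radius_px <= 0) ||
      cell_radius_px[1] > cell_radius_px[2]) {
    stop_input("`cell_radius_px` must be a positive (min, max) pair")
  }
  check_scalar_num(noise_sd, "noise_sd", 0)
  check_scalar_num(punctate_fraction, "punctate_fraction", 0, 1)
  check_scalar_num(control_frac, "control_frac", 0.05, 0.9)
  if (is.null(amplitude_means)) {
    amplitude_means <- default_amplitudes()
  }
  amplitude_means <- as.matrix(amplitude_means)
  if (!all(dim(amplitude_means) == c(4L, 3L))) {
    stop_input("`amplitude_means` must be a 4 x 3 matrix (classes x channels)")
  }
  rownames(amplitude_means) <- c("leukocyte", "CHC", "CTC", "control")
  colnames(amplitude_means) <- chc_channels()
  pos <- amplitude_means[amplitude_means > 0]
  if (length(pos) && any(pos <= 5 * noise_sd)) {
    stop_input("positive marker amplitudes must exceed 5 * noise_sd for separability")
  }
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    n_leukocytes = as.integer(n_leukocytes), n_chc = as.integer(n_chc),
    n_ctc = as.integer(n_ctc), n_control_cells = as.integer(n_control_cells),
    cell_radius_px = as.numeric(cell_radius_px),
    amplitude_means = amplitude_means,
    noise_sd = as.numeric(noise_sd),
    punctate_fraction = as.numeric(punctate_fraction),
    control_frac = as.numeric(control_frac),
    seed = as.integer(seed)
  ), class = "field_config")
}

default_amplitudes <- function() {
  m <- rbind(
    leukocyte = c(0, 40, 60),
    CHC       = c(40, 40, 60),
    CTC       = c(40, 0, 60),
    control   = c(0, 0, 60)
  )
  colnames(m) <- chc_channels()
  m
}

#' Generate a synthetic multi-channel immunofluorescence field
#'
#' Places non-overlapping cells by rejection sampling (100 retries per cell,
#' then an error), renders them as Gaussian disks onto the three channels,
#' adds clipped Gaussian noise, and returns both the field and the planted
#' ground truth. Control cells are placed inside the control strip; all other
#' cells outside it.
#'
#' @param config A [field_config()].
#' @return A list with elements `field` (an `image_field`: `pixels` H x W x 3
#'   array, `channel_names`, `control_mask`, `sample_id`) and `ground_truth`
#'   (a data frame with one row per planted cell: `cell_id`, `class`,
#'   `centroid_row`/`centroid_col` in 0-based pixel coordinates, `radius_px`,
#'   per-channel amplitudes, `punctate`).
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  with_seed(config$seed, generate_field_impl(config))
}

generate_field_impl <- function(config) {
  H <- config$height_px
  W <- config$width_px
  ctrl_w <- max(1L, as.integer(round(W * config$control_frac)))
  control_mask <- matrix(FALSE, H, W)
  control_mask[, seq_len(ctrl_w)] <- TRUE

  classes <- c(
    rep("leukocyte", config$n_leukocytes),
    rep("CHC", config$n_chc),
    rep("CTC", config$n_ctc),
    rep("control", config$n_control_cells)
  )
  n <- length(classes)
  gt <- data.frame(
    cell_id = integer(0), class = character(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    radius_px = numeric(0), amp_ck = numeric(0), amp_cd45 = numeric(0),
    amp_dapi = numeric(0), punctate = logical(0),
    stringsAsFactors = FALSE
  )

  pix <- array(0, dim = c(H, W, 3L))
  if (n > 0L) {
    radii <- stats::runif(n, config$cell_radius_px[1], config$cell_radius_px[2])
    cyto <- 1.6 * radii
    placed_r <- numeric(0)
    placed_c <- numeric(0)
    placed_rad <- numeric(0)
    rows <- numeric(n)
    cols <- numeric(n)
    margin <- 2
    for (i in seq_len(n)) {
      in_ctrl <- classes[i] == "control"
      lo_c <- if (in_ctrl) cyto[i] + margin else ctrl_w + cyto[i] + margin
      hi_c <- if (in_ctrl) ctrl_w - cyto[i] - margin else W - cyto[i] - margin
      lo_r <- cyto[i] + margin
      hi_r <- H - cyto[i] - margin
      if (lo_c >= hi_c || lo_r >= hi_r) {
        stop_input("field too small to place cell %d (class %s)", i, classes[i])
      }
      ok <- FALSE
      for (try in 1:100) {
        r <- stats::runif(1, lo_r, hi_r)
        cc <- stats::runif(1, lo_c, hi_c)
        if (length(placed_r) == 0L ||
            all((placed_r - r)^2 + (placed_c - cc)^2 >
                (1.2 * (placed_rad + cyto[i]) + 2)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop_input("could not place cell %d without overlap after 100 retries; enlarge the field or reduce counts", i)
      }
      placed_r <- c(placed_r, r)
      placed_c <- c(placed_c, cc)
      placed_rad <- c(placed_rad, cyto[i])
      rows[i] <- r
      cols[i] <- cc
    }

    punct <- rep(FALSE, n)
    ck_pos <- config$amplitude_means[classes, "CK"] > 0
    punct[ck_pos] <- stats::runif(sum(ck_pos)) < config$punctate_fraction

    for (i in seq_len(n)) {
      amps <- config$amplitude_means[classes[i], ]
      pix[, , 3L] <- add_gaussian_disk(pix[, , 3L], rows[i], cols[i],
                                       sigma = radii[i] / 2, amp = amps["DAPI"])
      for (ch in 1:2) {
        if (amps[ch] > 0) {
          if (ch == 1L && punct[i]) {
            pix[, , ch] <- add_puncta(pix[, , ch], rows[i], cols[i],
                                      cyto_radius = cyto[i], amp = amps[ch])
          } else {
            pix[, , ch] <- add_gaussian_disk(pix[, , ch], rows[i], cols[i],
                                             sigma = cyto[i] / 2, amp = amps[ch])
          }
        }
      }
    }

    gt <- data.frame(
      cell_id = seq_len(n), class = classes,
      centroid_row = rows - 1, centroid_col = cols - 1,
      radius_px = radii,
      amp_ck = unname(config$amplitude_means[classes, "CK"]),
      amp_cd45 = unname(config$amplitude_means[classes, "CD45"]),
      amp_dapi = unname(config$amplitude_means[classes, "DAPI"]),
      punctate = punct,
      stringsAsFactors = FALSE
    )
  }

  if (config$noise_sd > 0) {
    pix <- pix + stats::rnorm(length(pix), 0, config$noise_sd)
    pix[pix < 0] <- 0
  }

  field <- new_image_field(pix, control_mask,
                           sample_id = sprintf("sim%08d", config$seed))
  list(field = field, ground_truth = gt)
}

new_image_field <- function(pixels, control_mask, sample_id = "field") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!all(dim(control_mask) == dim(pixels)[1:2])) {
    stop_input("`control_mask` must match the field's spatial shape")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop_input("field intensities must be finite and non-negative")
  }
  structure(list(pixels = pixels, channel_names = chc_channels(),
                 control_mask = control_mask, sample_id = sample_id),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_field> %s: %d x %d px, channels %s, control region %d px\n",
              x$sample_id, d[1], d[2], paste(x$channel_names, collapse = "/"),
              sum(x$control_mask)))
  invisible(x)
}

# Add an isotropic 2-D Gaussian of peak `amp` at (r0, c0), truncated to
# compact support at 2.5 sigma (edge value subtracted so the profile reaches
# zero smoothly). Compact support keeps marker signal from bleeding into
# neighboring cell masks, which would corrupt their gating means.
add_gaussian_disk <- function(img, r0, c0, sigma, amp) {
  if (amp <= 0) return(img)
  H <- nrow(img); W <- ncol(img)
  w <- ceiling(2.5 * sigma)
  rr <- max(1L, floor(r0 - w)):min(H, ceiling(r0 + w))
  cc <- max(1L, floor(c0 - w)):min(W, ceiling(c0 + w))
  g <- amp * (exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma^2)) -
                exp(-2.5^2 / 2))
  g[g < 0] <- 0
  img[rr, cc] <- img[rr, cc] + g
  img
}

# Punctate CK: 3-6 tight Gaussians inside the cytoplasm disk, mutually
# separated so they resolve as distinct connected components above half-max.
# The punctum amplitude is chosen so the integrated CK signal matches the
# diffuse disk it replaces (`amp` at sigma = cyto_radius / 2), keeping the
# cell's mean CK intensity comparable across the two staining patterns.
add_puncta <- function(img, r0, c0, cyto_radius, amp) {
  k <- sample(3:6, 1)
  sigma_p <- 1.1
  a <- amp * (cyto_radius / 2)^2 / (k * sigma_p^2)
  ang <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(k) / k
  rad <- cyto_radius * stats::runif(k, 0.45, 0.8)
  pr <- r0 + rad * sin(ang)
  pc <- c0 + rad * cos(ang)
  for (j in seq_len(k)) {
    img <- add_gaussian_disk(img, pr[j], pc[j], sigma = sigma_p, amp = a)
  }
  img
}

#' Generate labeled 64 x 64 x 3 cell crops for the two CHC phenotypes
#'
#' Renders single-cell crops matching the two morphology classes the latent
#' model is asked to separate: treatment-responsive CHCs (elevated CD45,
#' decreased CK) and treatment-resistant CHCs (elevated CK, decreased CD45),
#' with a configurable fraction of resistant cells showing a punctate CK
#' staining pattern (>= 3 discrete puncta) instead of a diffuse disk.
#'
#' @param n_responsive,n_resistant Number of crops per class.
#' @param punctate_fraction Fraction of resistant crops rendered punctate.
#' @param seed Integer seed.
#' @param noise_sd Additive noise standard deviation.
#' @return A list of class `crop_set`: `tensors` (64 x 64 x 3 x n array),
#'   `phase` (character, "responsive"/"resistant"), `punctate` (logical).
#' @export
generate_crop_set <- function(n_responsive, n_resistant,
                              punctate_fraction = 0.25, seed = 1L,
                              noise_sd = 1.5) {
  check_scalar_num(n_responsive, "n_responsive", 0)
  check_scalar_num(n_resistant, "n_resistant", 0)
  check_scalar_num(punctate_fraction, "punctate_fraction", 0, 1)
  n <- as.integer(n_responsive + n_resistant)
  phase <- c(rep("responsive", n_responsive), rep("resistant", n_resistant))
  tensors <- array(0, dim = c(64L, 64L, 3L, n))
  punct <- rep(FALSE, n)
  if (n > 0L) {
    with_seed(seed, {
      punct[phase == "resistant"] <-
        stats::runif(sum(phase == "resistant")) < punctate_fraction
      for (i in seq_len(n)) {
        tensors[, , , i] <- render_crop(phase[i], punct[i], noise_sd)
      }
    })
  }
  structure(list(tensors = tensors, phase = phase, punctate = punct),
            class = "crop_set")
}

#' @export
print.crop_set <- function(x, ...) {
  cat(sprintf("<crop_set> %d crops (%s)\n", length(x$phase),
              paste(sprintf("%s: %d", names(table(x$phase)), table(x$phase)),
                    collapse = ", ")))
  invisible(x)
}

render_crop <- function(phase, punctate, noise_sd) {
  img <- array(0, dim = c(64L, 64L, 3L))
  r0 <- 32.5 + stats::runif(1, -4, 4)
  c0 <- 32.5 + stats::runif(1, -4, 4)
  nuc <- stats::runif(1, 6, 9)
  cyto <- 1.6 * nuc
  amp_hi <- 50
  amp_lo <- 10
  amp_ck <- if (phase == "resistant") amp_hi else amp_lo
  amp_cd45 <- if (phase == "resistant") amp_lo else amp_hi
  img[, , 3] <- add_gaussian_disk(img[, , 3], r0, c0, nuc / 2, 60)
  if (punctate) {
    img[, , 1] <- add_puncta(img[, , 1], r0, c0, cyto, amp_ck)
  } else {
    img[, , 1] <- add_gaussian_disk(img[, , 1], r0, c0, cyto / 2, amp_ck)
  }
  img[, , 2] <- add_gaussian_disk(img[, , 2], r0, c0, cyto / 2, amp_cd45)
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
  }
  img
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Trajectory regimes map onto the course categories seen clinically:
#' `sustained_response` (counts fall to zero and stay there; no post-trial
#' samples), `long_term_stable` (zero through trial and post-trial
#' surveillance), `on_trial_resistance` (rebound while still on trial), and
#' `post_trial_progression` (zero through trial, rebound during surveillance).
#'
#' @param n_patients,n_healthy Cohort sizes.
#' @param samples_per_patient Length-2 integer range of on-trial samples per
#'   patient (must allow >= 3 so a regime can be expressed).
#' @param baseline_range Patient baseline CHC counts per 50,000 PBMCs.
#' @param healthy_range Healthy-subject CHC counts per 50,000 PBMCs.
#' @param healthy_zero_prob Probability a healthy sample has zero CHCs.
#' @param regimes Character vector of per-patient regimes (recycled); `NULL`
#'   uses a clinically motivated default mix.
#' @param interval_increase_range Rebound magnitudes per 50,000 PBMCs.
#' @param pbmcs_per_sample PBMCs scanned per patient sample.
#' @param samples_per_healthy Length-2 integer range of samples per healthy
#'   subject.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 5, n_healthy = 15,
                          samples_per_patient = c(6, 7),
                          baseline_range = c(7.6, 15.5),
                          healthy_range = c(0, 1.67),
                          healthy_zero_prob = 0.8,
                          regimes = NULL,
                          interval_increase_range = c(2.0, 49.6),
                          pbmcs_per_sample = 50000,
                          samples_per_healthy = c(1, 3),
                          seed = 1L) {
  check_scalar_num(n_patients, "n_patients", 0)
  check_scalar_num(n_healthy, "n_healthy", 0)
  check_scalar_num(healthy_zero_prob, "healthy_zero_prob", 0, 1)
  check_scalar_num(pbmcs_per_sample, "pbmcs_per_sample", 1)
  for (nm in c("samples_per_patient", "baseline_range", "healthy_range",
               "interval_increase_range", "samples_per_healthy")) {
    v <- get(nm)
    if (length(v) != 2L || any(v < 0) || v[1] > v[2]) {
      stop_input("`%s` must be a non-negative (min, max) pair", nm)
    }
  }
  if (samples_per_patient[1] < 3) {
    stop_input("`samples_per_patient` must allow at least 3 samples to express a regime")
  }
  valid <- c("sustained_response", "on_trial_resistance",
             "post_trial_progression", "long_term_stable")
  if (is.null(regimes)) {
    # Default mix mirrors the observed clinical courses: two post-trial
    # progressors, one long-term stable, two on-trial resistant.
    regimes <- c("post_trial_progression", "long_term_stable",
                 "post_trial_progression", "on_trial_resistance",
                 "on_trial_resistance")
  }
  if (!all(regimes %in% valid)) {
    stop_input("regimes must be drawn from: %s", paste(valid, collapse = ", "))
  }
  if (n_patients > 0) {
    regimes <- rep_len(regimes, n_patients)
  } else {
    regimes <- character(0)
  }
  structure(list(
    n_patients = as.integer(n_patients), n_healthy = as.integer(n_healthy),
    samples_per_patient = as.integer(samples_per_patient),
    baseline_range = as.numeric(baseline_range),
    healthy_range = as.numeric(healthy_range),
    healthy_zero_prob = as.numeric(healthy_zero_prob),
    regimes = regimes,
    interval_increase_range = as.numeric(interval_increase_range),
    pbmcs_per_sample = as.integer(pbmcs_per_sample),
    samples_per_healthy = as.integer(samples_per_healthy),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic longitudinal cohort of CHC enumerations
#'
#' Counts are generated as integer raw cell counts and normalized per 50,000
#' PBMCs, so the enumeration invariant `normalized = raw * 50000 /
#' total_pbmcs` holds exactly. Patient baselines land inside
#' `baseline_range`, counts drop to exactly zero within two post-treatment
#' samples, resistant/progressing regimes rebound by a magnitude drawn from
#' `interval_increase_range`, healthy subjects stay inside `healthy_range`
#' (realized as a single detected cell over 30,000-150,000 scanned PBMCs),
#' and CTC counts are zero everywhere.
#'
#' @param config A [cohort_config()].
#' @return A list of `subject_timeline` objects (see [subject_timeline()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    out <- vector("list", config$n_patients + config$n_healthy)
    idx <- 1L
    for (i in seq_len(config$n_patients)) {
      out[[idx]] <- simulate_patient(sprintf("P%02d", i), config$regimes[i], config)
      idx <- idx + 1L
    }
    for (i in seq_len(config$n_healthy)) {
      out[[idx]] <- simulate_healthy(sprintf("H%02d", i), config)
      idx <- idx + 1L
    }
    out
  })
}

# Clamp-and-round a target normalized count into an integer raw count whose
# normalized value stays inside [lo, hi].
raw_in_range <- function(target_norm, pbmcs, lo, hi) {
  raw <- round(target_norm * pbmcs / 50000)
  raw_lo <- ceiling(lo * pbmcs / 50000)
  raw_hi <- floor(hi * pbmcs / 50000)
  if (raw_lo > raw_hi) {
    stop_input("pbmcs_per_sample = %d cannot realize an integer count in [%g, %g] per 50,000", pbmcs, lo, hi)
  }
  as.integer(min(max(raw, raw_lo), raw_hi))
}

simulate_patient <- function(subject_id, regime, config) {
  pb <- config$pbmcs_per_sample
  n_on <- sample(seq(config$samples_per_patient[1],
                     config$samples_per_patient[2]), 1)
  base_raw <- raw_in_range(stats::runif(1, config$baseline_range[1],
                                        config$baseline_range[2]),
                           pb, config$baseline_range[1], config$baseline_range[2])
  raw <- integer(n_on)
  raw[1] <- base_raw
  # Decline: optionally one intermediate responsive detection, then zero
  # within two post-treatment samples.
  if (stats::runif(1) < 0.5 && n_on >= 4) {
    raw[2] <- max(1L, as.integer(round(base_raw * stats::runif(1, 0.2, 0.6))))
  }
  rebound_raw <- raw_in_range(stats::runif(1, config$interval_increase_range[1],
                                           config$interval_increase_range[2]),
                              pb, config$interval_increase_range[1],
                              config$interval_increase_range[2])
  n_post <- switch(regime,
    sustained_response = 0L,
    long_term_stable = sample(1:3, 1),
    on_trial_resistance = 0L,
    post_trial_progression = sample(1:3, 1)
  )
  if (regime == "on_trial_resistance") {
    raw[n_on] <- rebound_raw
  }
  post_raw <- integer(n_post)
  if (regime == "post_trial_progression") {
    post_raw[n_post] <- rebound_raw
  }
  days_on <- 28 * (seq_len(n_on) - 1)
  trial_end <- days_on[n_on] + 14
  days_post <- if (n_post > 0) trial_end + 56 * seq_len(n_post) else numeric(0)
  days <- c(days_on, days_post)
  raw_all <- c(raw, post_raw)
  event <- rep("", length(days))
  event[1] <- "treatment_start"
  samples <- data.frame(
    sample_id = sprintf("%s_S%02d", subject_id, seq_along(days)),
    subject_id = subject_id,
    days_from_treatment_start = days,
    raw_chc = raw_all,
    raw_ctc = 0L,
    total_pbmcs = pb,
    chc_per_50k = raw_all * 50000 / pb,
    ctc_per_50k = 0,
    event = event,
    stringsAsFactors = FALSE
  )
  subject_timeline(subject_id, "patient", samples,
                   treatment_start = 0, trial_end = trial_end,
                   regime = regime)
}

simulate_healthy <- function(subject_id, config) {
  n <- sample(seq(config$samples_per_healthy[1], config$samples_per_healthy[2]), 1)
  raw <- integer(n)
  pb <- integer(n)
  for (j in seq_len(n)) {
    if (stats::runif(1) < config$healthy_zero_prob) {
      raw[j] <- 0L
      pb[j] <- config$pbmcs_per_sample
    } else {
      # One detected CHC over a deep scan: normalized value in (0.33, 1.67],
      # consistent with the healthy-range upper endpoint 1.67 = 50000/30000.
      raw[j] <- 1L
      lo_pb <- max(30000, ceiling(50000 / max(config$healthy_range[2], 1e-9)))
      pb[j] <- as.integer(round(stats::runif(1, lo_pb, 150000)))
    }
  }
  days <- 90 * (seq_len(n) - 1)
  samples <- data.frame(
    sample_id = sprintf("%s_S%02d", subject_id, seq_len(n)),
    subject_id = subject_id,
    days_from_treatment_start = days,
    raw_chc = raw,
    raw_ctc = 0L,
    total_pbmcs = pb,
    chc_per_50k = raw * 50000 / pb,
    ctc_per_50k = 0,
    event = "",
    stringsAsFactors = FALSE
  )
  subject_timeline(subject_id, "healthy", samples)
}

#' Construct a subject timeline
#'
#' A timeline holds the time-ordered per-sample enumerations for one subject
#' plus treatment metadata (for patients: treatment start and trial end).
#'
#' @param subject_id Subject identifier.
#' @param cohort `"patient"` or `"healthy"`.
#' @param samples Data frame with columns `sample_id`, `subject_id`,
#'   `days_from_treatment_start`, `raw_chc`, `raw_ctc`, `total_pbmcs`,
#'   `chc_per_50k`, `ctc_per_50k`, `event`; rows must be strictly
#'   time-ordered.
#' @param treatment_start,trial_end Days from treatment start (`NA` for
#'   healthy subjects).
#' @param regime Optional generating regime tag (synthetic cohorts only).
#' @return A list of class `subject_timeline`.
#' @export
subject_timeline <- function(subject_id, cohort, samples,
                             treatment_start = NA_real_, trial_end = NA_real_,
                             regime = NULL) {
  cohort <- match.arg(cohort, c("patient", "healthy"))
  need <- c("sample_id", "subject_id", "days_from_treatment_start",
            "raw_chc", "raw_ctc", "total_pbmcs", "chc_per_50k",
            "ctc_per_50k", "event")
  if (!all(need %in% names(samples))) {
    stop_input("timeline samples missing columns: %s",
               paste(setdiff(need, names(samples)), collapse = ", "))
  }
  d <- samples$days_from_treatment_start
  if (nrow(samples) > 1 && any(diff(d) <= 0)) {
    stop_input("sample times must be strictly increasing for subject %s", subject_id)
  }
  structure(list(subject_id = subject_id, cohort = cohort, samples = samples,
                 treatment_start = treatment_start, trial_end = trial_end,
                 regime = regime),
            class = "subject_timeline")
}

#' @export
print.subject_timeline <- function(x, ...) {
  cat(sprintf("<subject_timeline> %s (%s): %d samples, CHC/50k: %s\n",
              x$subject_id, x$cohort, nrow(x$samples),
              paste(round(x$samples$chc_per_50k, 2), collapse = ", ")))
  invisible(x)
}
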