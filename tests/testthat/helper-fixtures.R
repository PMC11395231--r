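# Shared fixtures and independent oracles.

# A compact field that exercises placement, segmentation and gating quickly.
small_field_config <- function(seed = 1L, n_chc = 3, n_ctc = 1,
                               n_leukocytes = 40) {
  field_config(height_px = 360, width_px = 380, n_leukocytes = n_leukocytes,
               n_chc = n_chc, n_ctc = n_ctc, n_control_cells = 40,
               cell_radius_px = c(3.5, 5.5), control_frac = 0.4, seed = seed)
}

# Brute-force Mann-Whitney oracle: enumerates every C(n1+n2, n1) group
# assignment of the pooled values, computes the rank-sum U for each, and
# returns the two-sided p as 2 * min(tail masses) capped at 1. Independent of
# the shift-algorithm implementation.
mw_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Hand-built cell records table for gating tests (bypasses imaging).
make_records <- function(ck, cd45, is_control = rep(FALSE, length(ck)),
                         dapi = rep(10, length(ck))) {
  n <- length(ck)
  structure(data.frame(
    cell_id = seq_len(n),
    centroid_row = rep(10, n), centroid_col = rep(10, n),
    bbox_r0 = rep(0L, n), bbox_c0 = rep(0L, n),
    bbox_r1 = rep(20L, n), bbox_c1 = rep(20L, n),
    area_px = rep(50L, n),
    mean_CK = ck, mean_CD45 = cd45, mean_DAPI = dapi,
    is_control = is_control, on_border = rep(FALSE, n),
    stringsAsFactors = FALSE
  ), class = c("cell_records", "data.frame"), sample_id = "fixture")
}

# Patient timeline from a vector of normalized CHC counts (28-day spacing,
# treatment start at day 0, trial end after the last on-trial sample).
make_patient_timeline <- function(chc, n_post_trial = 0,
                                  subject_id = "PT") {
  n <- length(chc)
  days <- 28 * (seq_len(n) - 1)
  n_on <- n - n_post_trial
  trial_end <- days[n_on] + 14
  samples <- data.frame(
    sample_id = sprintf("%s_S%02d", subject_id, seq_len(n)),
    subject_id = subject_id,
    days_from_treatment_start = days,
    raw_chc = as.integer(round(chc)), raw_ctc = 0L,
    total_pbmcs = 50000L,
    chc_per_50k = chc, ctc_per_50k = 0,
    event = c("treatment_start", rep("", n - 1)),
    stringsAsFactors = FALSE
  )
  subject_timeline(subject_id, "patient", samples,
                   treatment_start = 0, trial_end = trial_end)
}

make_healthy_timeline <- function(chc, subject_id = "HL") {
  n <- length(chc)
  samples <- data.frame(
    sample_id = sprintf("%s_S%02d", subject_id, seq_len(n)),
    subject_id = subject_id,
    days_from_treatment_start = 90 * (seq_len(n) - 1),
    raw_chc = as.integer(round(chc)), raw_ctc = 0L,
    total_pbmcs = 50000L,
    chc_per_50k = chc, ctc_per_50k = 0,
    event = "",
    stringsAsFactors = FALSE
  )
  subject_timeline(subject_id, "healthy", samples)
}

# Tiny VAE settings shared by the latent-module tests.
tiny_vae_config <- function(seed = 1L, max_epochs = 4) {
  vae_config(encoder_filters = c(8, 8, 16), latent_dim = 8, batch_size = 16,
             max_epochs = max_epochs, seed = seed)
}
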