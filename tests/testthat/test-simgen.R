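# Synthetic field, crop-set, and cohort generators.

test_that("empty configurations give empty outputs", {
  cfg <- small_field_config(seed = 3, n_chc = 0, n_ctc = 0, n_leukocytes = 0)
  cfg$n_control_cells <- 0L
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$ground_truth), 0)
  expect_equal(dim(sim$field$pixels), c(360L, 380L, 3L))

  expect_length(generate_crop_set(0, 0, 0, seed = 1)$phase, 0)
})

test_that("planted class counts are conserved and recorded in ground truth", {
  cfg <- small_field_config(seed = 7, n_chc = 3, n_ctc = 1, n_leukocytes = 50)
  sim <- generate_field(cfg)
  tab <- table(sim$ground_truth$class)
  expect_equal(unname(tab[["leukocyte"]]), 50)
  expect_equal(unname(tab[["CHC"]]), 3)
  expect_equal(unname(tab[["CTC"]]), 1)
  expect_equal(nrow(sim$ground_truth), 54 + cfg$n_control_cells)

  # centroids inside bounds; class/amplitude consistency
  gt <- sim$ground_truth
  expect_true(all(gt$centroid_row >= 0 & gt$centroid_row <= cfg$height_px - 1))
  expect_true(all(gt$centroid_col >= 0 & gt$centroid_col <= cfg$width_px - 1))
  expect_true(all(gt$amp_ck[gt$class == "CHC"] > 0))
  expect_true(all(gt$amp_cd45[gt$class == "CHC"] > 0))
  expect_true(all(gt$amp_cd45[gt$class == "CTC"] == 0))
  expect_true(all(gt$amp_ck[gt$class == "leukocyte"] == 0))
})

test_that("identical config and seed give bit-identical fields", {
  cfg <- small_field_config(seed = 11)
  a <- generate_field(cfg)
  b <- generate_field(cfg)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$ground_truth, b$ground_truth)

  c2 <- generate_field(small_field_config(seed = 12))
  expect_false(identical(a$field$pixels, c2$field$pixels))
})

test_that("control region holds only unstained cells and all cells have nuclei", {
  sim <- generate_field(small_field_config(seed = 5))
  gt <- sim$ground_truth
  cm <- sim$field$control_mask
  in_ctrl <- cm[cbind(round(gt$centroid_row) + 1, round(gt$centroid_col) + 1)]
  expect_true(all(gt$class[in_ctrl] == "control"))
  expect_true(all(gt$class[!in_ctrl] != "control"))
  expect_true(all(gt$amp_ck[in_ctrl] == 0 & gt$amp_cd45[in_ctrl] == 0))
  expect_true(all(gt$amp_dapi > 0))
})

test_that("placement fails loudly when the field cannot hold the request", {
  cfg <- small_field_config(seed = 1)
  cfg$height_px <- 64L
  cfg$width_px <- 64L
  expect_error(generate_field(cfg), "place")
})

test_that("responsive crops are CD45-dominant and resistant crops CK-dominant", {
  cs <- generate_crop_set(100, 100, punctate_fraction = 0.5, seed = 1)
  expect_length(cs$phase, 200)
  ck <- apply(cs$tensors[, , 1, ], 3, mean)
  cd45 <- apply(cs$tensors[, , 2, ], 3, mean)
  expect_true(all(cd45[cs$phase == "responsive"] > ck[cs$phase == "responsive"]))
  expect_true(all(ck[cs$phase == "resistant"] > cd45[cs$phase == "resistant"]))
  expect_true(all(dim(cs$tensors)[1:3] == c(64, 64, 3)))
})

test_that("punctate resistant crops render >= 3 discrete CK puncta", {
  cs <- generate_crop_set(0, 10, punctate_fraction = 1, seed = 2)
  expect_true(all(cs$punctate))
  for (i in 1:10) {
    ck <- cs$tensors[, , 1, i]
    comps <- EBImage::bwlabel(ck > max(ck) / 2)
    expect_gte(max(comps), 3)
  }
})

test_that("healthy cohorts stay inside the healthy range with zero CTCs", {
  co <- cohort_config(n_patients = 0, n_healthy = 3, seed = 4)
  tls <- generate_cohort(co)
  expect_length(tls, 3)
  for (tl in tls) {
    expect_identical(tl$cohort, "healthy")
    expect_true(all(tl$samples$chc_per_50k <= 1.67))
    expect_true(all(tl$samples$ctc_per_50k == 0))
  }
})

test_that("sustained response declines to zero within two samples and stays there", {
  co <- cohort_config(n_patients = 1, n_healthy = 0, samples_per_patient = c(7, 7),
                      regimes = "sustained_response", seed = 8)
  tl <- generate_cohort(co)[[1]]
  chc <- tl$samples$chc_per_50k
  expect_gte(chc[1], 7.6)
  expect_lte(chc[1], 15.5)
  expect_equal(chc[3], 0)                  # zero within two post-treatment samples
  first_zero <- match(0, chc)
  expect_true(all(chc[first_zero:length(chc)] == 0))
  expect_true(all(tl$samples$ctc_per_50k == 0))
})

test_that("on-trial resistance ends the trial with a rebound of at least 2 per 50k", {
  co <- cohort_config(n_patients = 1, n_healthy = 0,
                      regimes = "on_trial_resistance", seed = 9)
  tl <- generate_cohort(co)[[1]]
  s <- tl$samples
  on_trial <- s$days_from_treatment_start <= tl$trial_end
  last_chc <- tail(s$chc_per_50k[on_trial], 1)
  expect_gt(last_chc, 0)
  expect_gte(last_chc, 2.0)
  expect_lte(last_chc, 49.6)
})

test_that("baseline marginals match the configured range over many patients", {
  co <- cohort_config(n_patients = 200, n_healthy = 0, seed = 10)
  tls <- generate_cohort(co)
  baselines <- vapply(tls, function(tl) tl$samples$chc_per_50k[1], numeric(1))
  expect_true(all(baselines >= 7.6 & baselines <= 15.5))
  expect_gte(median(baselines), 7.6)
  expect_lte(median(baselines), 15.5)
})

test_that("cohort generation is deterministic and validates its config", {
  co <- cohort_config(seed = 12)
  expect_identical(generate_cohort(co), generate_cohort(co))
  expect_error(cohort_config(samples_per_patient = c(2, 2)), "at least 3")
  expect_error(cohort_config(regimes = "miracle_cure"), "regimes")
})

test_that("fields round-trip through the TIFF + JSON dialect", {
  sim <- generate_field(small_field_config(seed = 21, n_leukocytes = 10))
  path <- file.path(tempdir(), "field_roundtrip.tiff")
  write_field(sim$field, path, ground_truth = sim$ground_truth)
  back <- read_field(path)
  expect_equal(back$field$pixels, sim$field$pixels, tolerance = 1e-6)
  expect_identical(back$field$control_mask, sim$field$control_mask)
  expect_equal(nrow(back$ground_truth), nrow(sim$ground_truth))
  unlink(c(path, paste0(path, ".json")))
})

test_that("cohorts round-trip through the enumeration CSV dialect", {
  tls <- generate_cohort(cohort_config(seed = 13))
  path <- file.path(tempdir(), "cohort_roundtrip.csv")
  write_cohort_csv(tls, path)
  back <- read_cohort_csv(path)
  expect_length(back, length(tls))
  orig <- tls[[1]]
  got <- back[[orig$subject_id]]
  expect_equal(got$samples$chc_per_50k, orig$samples$chc_per_50k)
  expect_equal(got$trial_end, orig$trial_end)
  expect_identical(got$cohort, orig$cohort)
  unlink(path)
})
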