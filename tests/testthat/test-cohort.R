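# Longitudinal course classification, phase labeling, baseline comparison.

test_that("course classification reproduces the printed clinical patterns", {
  # sustained undetectable: nadir and end-of-trial undetectable, no post-trial
  c1 <- classify_course(make_patient_timeline(c(13.5, 0, 0, 0)))
  expect_identical(c1$nadir_status, "undetectable")
  expect_identical(c1$end_of_trial_status, "undetectable")
  expect_identical(c1$post_trial_status, "not_available")
  expect_true(is.na(c1$interval_increase))

  # on-trial rebound after a zero nadir
  c2 <- classify_course(make_patient_timeline(c(9, 0, 0, 6)))
  expect_identical(c2$nadir_status, "undetectable")
  expect_identical(c2$end_of_trial_status, "increased")
  expect_equal(c2$interval_increase, 6)

  # post-trial rebound
  c3 <- classify_course(make_patient_timeline(c(8, 0, 0, 0, 49.6),
                                              n_post_trial = 2))
  expect_identical(c3$end_of_trial_status, "undetectable")
  expect_identical(c3$post_trial_status, "increased")
  expect_equal(c3$interval_increase, 49.6)
  expect_equal(c3$time_of_first_rebound, 28 * 4)
})

test_that("classification rejects healthy timelines and needs a trial end", {
  expect_error(classify_course(make_healthy_timeline(c(0, 0))), "patient")
  tl <- make_patient_timeline(c(10, 0, 0))
  tl$trial_end <- NA_real_
  expect_error(classify_course(tl), "trial_end")
})

test_that("inserting extra zero samples after an existing zero changes nothing", {
  base <- make_patient_timeline(c(12, 0, 7))
  ext <- make_patient_timeline(c(12, 0, 0, 0, 7))
  a <- classify_course(base)
  b <- classify_course(ext)
  expect_identical(a$nadir_status, b$nadir_status)
  expect_identical(a$end_of_trial_status, b$end_of_trial_status)
  expect_identical(a$post_trial_status, b$post_trial_status)
  expect_equal(a$interval_increase, b$interval_increase)
})

test_that("phase labels split detections at the first undetectable sample", {
  ph <- label_chc_phases(make_patient_timeline(c(12, 4, 0, 0, 7)))
  expect_equal(ph$phase, c("responsive", "responsive", "none", "none", "resistant"))

  ph2 <- label_chc_phases(make_patient_timeline(c(10, 0)))
  expect_equal(ph2$phase, c("responsive", "none"))

  ph3 <- label_chc_phases(make_patient_timeline(c(0, 0, 0)))
  expect_true(all(ph3$phase == "none"))

  # partition property: every positive sample labeled exactly once, and no
  # resistant label before the first zero
  set.seed(3)
  for (i in 1:20) {
    chc <- c(sample(5:15, 1), sample(c(0, 0, 3, 7), 5, replace = TRUE))
    ph <- label_chc_phases(make_patient_timeline(chc))
    expect_true(all(ph$phase[ph$chc_per_50k > 0] %in% c("responsive", "resistant")))
    expect_true(all(ph$phase[ph$chc_per_50k == 0] == "none"))
    fz <- match(0, ph$chc_per_50k)
    if (!is.na(fz)) {
      expect_false(any(ph$phase[seq_len(fz - 1)] == "resistant"))
    }
  }
})

test_that("baseline comparison applies the exact test to per-subject baselines", {
  pats <- lapply(1:5, function(i) make_patient_timeline(c(8 + i, 0, 0),
                                                        subject_id = paste0("P", i)))
  heal <- lapply(1:15, function(i) make_healthy_timeline(c(0, 0),
                                                         subject_id = paste0("H", i)))
  r <- compare_baseline(pats, heal)
  expect_identical(r$method, "exact")
  expect_equal(r$p_two_sided, 2 / choose(20, 5))   # complete separation

  # identical constant counts in both groups: p = 1
  pats2 <- lapply(1:3, function(i) make_patient_timeline(c(5, 0, 0),
                                                         subject_id = paste0("Q", i)))
  heal2 <- lapply(1:3, function(i) make_healthy_timeline(5,
                                                         subject_id = paste0("G", i)))
  expect_equal(compare_baseline(pats2, heal2)$p_two_sided, 1)

  # missing baseline names the subject
  nob <- make_patient_timeline(c(9, 0, 0))
  nob$samples$days_from_treatment_start <- nob$samples$days_from_treatment_start + 5
  expect_error(compare_baseline(list(nob), heal), "PT")
})

test_that("cohort summaries report medians and ranges correctly", {
  pats <- list(
    make_patient_timeline(c(10, 0, 0, 2.0), subject_id = "A"),
    make_patient_timeline(c(12, 0, 0, 7.6), subject_id = "B"),
    make_patient_timeline(c(14, 0, 0, 49.6), subject_id = "C")
  )
  s <- summarize_cohort(pats)
  expect_equal(unname(s$interval_increase), c(7.6, 2.0, 49.6))
  expect_equal(unname(s$baseline["median"]), 12)

  # degenerate single subject
  s1 <- summarize_cohort(pats[1])
  expect_equal(unname(s1$baseline), c(10, 10, 10))

  # min <= median <= max on random cohorts
  set.seed(5)
  for (i in 1:10) {
    tls <- generate_cohort(cohort_config(n_patients = 4, n_healthy = 2, seed = i))
    ss <- summarize_cohort(tls)
    expect_lte(ss$baseline["min"], ss$baseline["median"])
    expect_lte(ss$baseline["median"], ss$baseline["max"])
  }
})

test_that("course classification recovers the generating regimes", {
  co <- cohort_config(n_patients = 40, n_healthy = 0, seed = 17)
  tls <- generate_cohort(co)
  hits <- 0
  for (tl in tls) {
    cs <- classify_course(tl)
    ok <- switch(tl$regime,
      sustained_response = cs$nadir_status == "undetectable" &&
        cs$end_of_trial_status == "undetectable",
      long_term_stable = cs$nadir_status == "undetectable" &&
        cs$end_of_trial_status == "undetectable" &&
        cs$post_trial_status == "undetectable",
      on_trial_resistance = cs$nadir_status == "undetectable" &&
        cs$end_of_trial_status == "increased",
      post_trial_progression = cs$nadir_status == "undetectable" &&
        cs$end_of_trial_status == "undetectable" &&
        cs$post_trial_status == "increased")
    hits <- hits + ok
  }
  expect_equal(hits, length(tls))
})
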