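# Control-region gating, classification, and per-50k enumeration.

test_that("thresholds equal the stated percentile of control intensities", {
  # constant distribution: any percentile is the constant
  rec <- make_records(ck = rep(5, 100), cd45 = rep(2, 100),
                      is_control = rep(TRUE, 100))
  thr <- establish_thresholds(rec, percentile = 99.5)
  expect_equal(unname(thr$threshold["CK"]), 5)
  expect_equal(unname(thr$threshold["CD45"]), 2)
  expect_equal(thr$n_control_cells, 100)

  # arithmetic sequence 1..100 at percentile 99.5 under empirical-CDF linear
  # interpolation: the 99.5th order statistic, i.e. 99.5
  rec2 <- make_records(ck = 1:100, cd45 = 1:100, is_control = rep(TRUE, 100))
  thr2 <- establish_thresholds(rec2, percentile = 99.5)
  expect_equal(unname(thr2$threshold["CK"]), 99.5)
})

test_that("threshold preconditions are enforced", {
  few <- make_records(ck = rep(1, 10), cd45 = rep(1, 10),
                      is_control = rep(TRUE, 10))
  expect_error(establish_thresholds(few, min_control = 30), "30")
  mixed <- make_records(ck = rep(1, 40), cd45 = rep(1, 40),
                        is_control = c(rep(TRUE, 39), FALSE))
  expect_error(establish_thresholds(mixed), "non-control")
  ok <- make_records(ck = rep(1, 40), cd45 = rep(1, 40),
                     is_control = rep(TRUE, 40))
  expect_error(establish_thresholds(ok, percentile = 50), "between 50 and 100")
})

test_that("cells map to CHC/CTC/leukocyte/negative with a strict tie rule", {
  ctrl <- make_records(ck = rep(0, 40), cd45 = rep(0, 40),
                       is_control = rep(TRUE, 40))
  thr <- establish_thresholds(ctrl)
  thr$threshold <- c(CK = 5, CD45 = 5)
  rec <- make_records(ck = c(10, 10, 2, 2, 5), cd45 = c(10, 2, 10, 2, 5))
  calls <- classify_cells(rec, thr)
  expect_equal(as.character(calls$label),
               c("CHC", "CTC", "leukocyte", "negative", "negative"))
})

test_that("control cells are excluded from calls", {
  thr <- structure(list(threshold = c(CK = 5, CD45 = 5), percentile_used = 99.5,
                        n_control_cells = 40), class = "gating_thresholds")
  rec <- make_records(ck = c(10, 10), cd45 = c(10, 10),
                      is_control = c(FALSE, TRUE))
  calls <- classify_cells(rec, thr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cell_id, 1L)
})

test_that("per-50k normalization matches closed forms and is linear", {
  expect_equal(normalize_per_50k(0, 50000), 0)
  expect_equal(round(normalize_per_50k(1, 30000), 2), 1.67)
  expect_equal(normalize_per_50k(14, 50000), 14)
  expect_error(normalize_per_50k(1, 0), "positive")
  # linearity: f(k, N) = k * f(1, N)
  for (k in c(2, 5, 17)) {
    expect_equal(normalize_per_50k(k, 36000), k * normalize_per_50k(1, 36000))
  }
})

test_that("enumeration tallies calls, normalizes, and conserves cells", {
  thr <- structure(list(threshold = c(CK = 5, CD45 = 5), percentile_used = 99.5,
                        n_control_cells = 40), class = "gating_thresholds")
  rec <- make_records(ck = c(rep(10, 3), rep(0, 47)),
                      cd45 = c(rep(10, 3), rep(10, 47)))
  calls <- classify_cells(rec, thr)
  en <- enumerate_sample(calls, total_pbmcs = 25000)
  expect_equal(en$raw_chc, 3L)
  expect_equal(en$raw_leukocyte, 47L)
  expect_equal(en$chc_per_50k, 6)
  expect_equal(en$raw_chc + en$raw_ctc + en$raw_leukocyte + en$raw_negative,
               nrow(calls))

  # empty calls -> all-zero enumeration
  en0 <- enumerate_sample(calls[0, , drop = FALSE])
  expect_equal(en0$raw_chc + en0$raw_ctc + en0$raw_leukocyte + en0$raw_negative, 0L)
  expect_equal(en0$chc_per_50k, 0)

  # duplicate ids are rejected
  dup <- calls
  dup$cell_id[2] <- dup$cell_id[1]
  expect_error(enumerate_sample(dup), "duplicate")
})

test_that("raising a threshold never increases the positive-cell count", {
  set.seed(77)
  rec <- make_records(ck = runif(200, 0, 10), cd45 = runif(200, 0, 10))
  thr <- structure(list(threshold = c(CK = 0, CD45 = 5), percentile_used = 99.5,
                        n_control_cells = 40), class = "gating_thresholds")
  n_ck_pos <- function(t) {
    thr$threshold["CK"] <- t
    calls <- classify_cells(rec, thr)
    sum(calls$label %in% c("CHC", "CTC"))
  }
  counts <- vapply(seq(0, 10, by = 0.5), n_ck_pos, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gating recovers planted counts on a separable field", {
  sim <- generate_field(small_field_config(seed = 55, n_chc = 3, n_ctc = 1))
  seg <- segment_field(sim$field)
  g <- gate_sample(seg$records)
  expect_equal(g$enumeration$raw_chc, 3L)
  expect_equal(g$enumeration$raw_ctc, 1L)
  # every non-control cell got exactly one call
  expect_equal(nrow(g$calls), sum(!seg$records$is_control))
  expect_false(anyNA(g$calls$label))
})
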