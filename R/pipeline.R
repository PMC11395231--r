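# End-to-end orchestration: config validation and the synthetic-data demo
# that regenerates a course-classification table, a baseline group
# comparison, and a phenotype-separation report from scratch.

#' Default demo configuration
#'
#' A nested configuration covering every stage. The cohort and field settings
#' are the generator's study conditions; the latent stage is scaled to a
#' desk-size run (small filter stack, few epochs) so the demo finishes in
#' minutes on one CPU - pass `vae = vae_config()` for the full-scale
#' architecture.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    cohort = cohort_config(seed = child_seed(seed, 1)),
    field = field_config(seed = child_seed(seed, 2)),
    n_fields = 2L,
    gating_percentile = 99.5,
    crops = list(n_responsive = 60L, n_resistant = 60L,
                 punctate_fraction = 0.25, seed = child_seed(seed, 3)),
    vae = vae_config(encoder_filters = c(8, 16, 32), latent_dim = 16,
                     max_epochs = 8, seed = child_seed(seed, 4)),
    beta = beta_schedule(),
    umap = list(n_neighbors = 15, min_dist = 0.1, seed = child_seed(seed, 5)),
    run_umap = FALSE
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain list with the same fields).
#' @return Character vector of human-readable issues; empty iff valid.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  chk <- function(expr, msg) if (!isTRUE(expr)) add(msg)

  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed: must be a single integer")
  co <- config$cohort
  if (is.null(co)) add("cohort: missing") else {
    chk(co$n_patients >= 0 && co$n_healthy >= 0, "cohort: counts must be >= 0")
    chk(co$samples_per_patient[1] >= 3,
        "cohort: samples_per_patient must allow >= 3 samples per regime")
    chk(all(co$baseline_range >= 0) && co$baseline_range[1] <= co$baseline_range[2],
        "cohort: baseline_range must be a non-negative (min, max) pair")
  }
  fc <- config$field
  if (is.null(fc)) add("field: missing") else {
    chk(fc$height_px >= 64 && fc$width_px >= 64,
        "field: dimensions must be >= 64 px")
    pos <- fc$amplitude_means[fc$amplitude_means > 0]
    chk(length(pos) == 0 || all(pos > 5 * fc$noise_sd),
        "field: positive amplitudes must exceed 5 * noise_sd (separability)")
  }
  chk(is.numeric(config$gating_percentile) &&
        config$gating_percentile > 50 && config$gating_percentile < 100,
      "gating_percentile: must lie strictly between 50 and 100")
  b <- config$beta
  if (is.null(b)) add("beta: missing") else {
    chk(b$beta_step > 0, "beta: BetaSchedule invariant violated (beta_step must be > 0)")
    chk(b$beta_start > 0 && b$beta_start <= b$beta_max,
        "beta: BetaSchedule invariant violated (0 < beta_start <= beta_max)")
  }
  v <- config$vae
  if (is.null(v)) add("vae: missing") else {
    chk(v$latent_dim >= 1, "vae: VAEConfig invariant violated (latent_dim >= 1)")
    chk(v$validation_fraction > 0 && v$validation_fraction < 0.5,
        "vae: validation_fraction must lie in (0, 0.5)")
  }
  issues
}

#' Run the synthetic-data demo pipeline
#'
#' From synthetic data only: generates a cohort and enumeration CSV, runs
#' image fields through segmentation and gating (verifying planted counts),
#' classifies each patient's course into a summary table, compares baselines
#' between patients and healthy subjects, trains the (scaled) beta-VAE on a
#' two-phenotype crop set, and writes the embedding and phenotype reports
#' plus a manifest recording every seed.
#'
#' @param config A [demo_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log per-stage progress and counts.
#' @return Invisibly, a list with the main in-memory results (`timelines`,
#'   `courses`, `baseline_test`, `field_check`, `model`, `report`, `paths`).
#' @export
run_demo <- function(config = demo_config(), out_dir = tempfile("chc_demo_"),
                     verbose = TRUE) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop_input("invalid config:\n  %s", paste(issues, collapse = "\n  "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list()

  # --- cohort simulation ---------------------------------------------------
  if (config$cohort$n_patients == 0) {
    stop_input("cohort stage: config has no patients (n_patients = 0)")
  }
  timelines <- generate_cohort(config$cohort)
  paths$cohort_csv <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(timelines, paths$cohort_csv)
  is_pat <- vapply(timelines, function(t) t$cohort == "patient", logical(1))
  say("cohort: %d patients, %d healthy subjects", sum(is_pat), sum(!is_pat))

  # --- image fields: segment + gate ---------------------------------------
  field_rows <- list()
  for (i in seq_len(config$n_fields)) {
    fc <- config$field
    fc$seed <- child_seed(config$seed, 100 + i)
    sim <- generate_field(fc)
    seg <- segment_field(sim$field)
    gated <- gate_sample(seg$records,
                         metadata = list(sample_id = sim$field$sample_id,
                                         subject_id = sprintf("F%02d", i),
                                         days_from_treatment_start = 0),
                         percentile = config$gating_percentile)
    planted <- table(factor(sim$ground_truth$class,
                            levels = c("leukocyte", "CHC", "CTC", "control")))
    say("field %d: %d cells segmented (%d control), calls CHC=%d CTC=%d (planted CHC=%d CTC=%d)",
        i, nrow(seg$records), sum(seg$records$is_control),
        gated$enumeration$raw_chc, gated$enumeration$raw_ctc,
        planted[["CHC"]], planted[["CTC"]])
    field_rows[[i]] <- cbind(gated$enumeration,
                             planted_chc = planted[["CHC"]],
                             planted_ctc = planted[["CTC"]])
  }
  field_check <- do.call(rbind, field_rows)
  paths$field_csv <- file.path(out_dir, "field_enumerations.csv")
  utils::write.csv(field_check, paths$field_csv, row.names = FALSE)

  # --- course classification + baseline comparison ------------------------
  summary <- summarize_cohort(timelines)
  paths$course_csv <- file.path(out_dir, "course_summary.csv")
  utils::write.csv(summary$courses, paths$course_csv, row.names = FALSE)
  baseline_test <- compare_baseline(timelines[is_pat], timelines[!is_pat])
  say("baseline comparison: U = %g, two-sided p = %.3g (%s)",
      baseline_test$U, baseline_test$p_two_sided, baseline_test$method)
  stats_report <- list(
    baseline = as.list(summary$baseline),
    interval_increase = as.list(summary$interval_increase),
    mann_whitney = list(U = baseline_test$U,
                        p_two_sided = baseline_test$p_two_sided,
                        method = baseline_test$method)
  )
  paths$stats_json <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats_report, paths$stats_json, auto_unbox = TRUE,
                       digits = NA)

  # --- latent phenotyping --------------------------------------------------
  cs <- generate_crop_set(config$crops$n_responsive, config$crops$n_resistant,
                          config$crops$punctate_fraction, config$crops$seed)
  cs <- normalize_crops(cs)
  model <- vae_fit(cs, config$vae, config$beta, verbose = FALSE)
  es <- encode(model, cs)
  if (isTRUE(config$run_umap)) {
    es <- embed_umap(es, config$umap$n_neighbors, config$umap$min_dist,
                     config$umap$seed)
  }
  report <- phenotype_report(es)
  say("phenotype: silhouette %.3f, CK resistant-responsive %+.3f, CD45 responsive-resistant %+.3f",
      report$silhouette, report$ck_resistant_minus_responsive,
      report$cd45_responsive_minus_resistant)
  paths$embeddings_csv <- file.path(out_dir, "embeddings.csv")
  write_embeddings_csv(es, paths$embeddings_csv)
  paths$history_json <- file.path(out_dir, "training_history.json")
  jsonlite::write_json(model$history, paths$history_json, digits = NA,
                       dataframe = "columns")
  paths$report_json <- file.path(out_dir, "phenotype_report.json")
  jsonlite::write_json(list(
    silhouette = report$silhouette,
    ck_resistant_minus_responsive = report$ck_resistant_minus_responsive,
    cd45_responsive_minus_resistant = report$cd45_responsive_minus_resistant,
    class_means = report$class_means
  ), paths$report_json, auto_unbox = TRUE, digits = NA)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridscope")),
    global_seed = config$seed,
    stage_seeds = list(cohort = config$cohort$seed,
                       fields = vapply(seq_len(config$n_fields), function(i)
                         child_seed(config$seed, 100 + i), numeric(1)),
                       crops = config$crops$seed, vae = config$vae$seed,
                       umap = config$umap$seed),
    outputs = lapply(paths, basename)
  )
  paths$manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = NA)
  say("demo outputs written to %s", out_dir)

  invisible(list(timelines = timelines, courses = summary$courses,
                 summary = summary, baseline_test = baseline_test,
                 field_check = field_check, model = model,
                 embeddings = es, report = report, paths = paths,
                 out_dir = out_dir))
}
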