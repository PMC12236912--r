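#' Configuration of an end-to-end pipeline run
#'
#' Collects every stage's configuration: cohort and phantom specifications,
#' model architecture and training regime, ensemble size, analysis options
#' and the global seed from which all stage seeds are derived. Two preset
#' scales are provided: \code{\link{demo_config}} (minutes-scale smoke run)
#' and \code{\link{replica_config}} (the desk-scale study replica: 600
#' subjects at 24 x 28 x 24 voxels, a 2-block CNN, a k = 3 ensemble).
#'
#' @param seed global seed.
#' @param n_train_hc healthy controls in the training cohort.
#' @param n_test_hc,n_test_gad test-cohort group sizes.
#' @param n_sites_train,n_sites_test sites per cohort.
#' @param age_range,age_distribution,variance_inflation,site_offset_sd
#'   cohort parameters (see \code{\link{cohort_spec}}).
#' @param control_noise_sd control-group morphological noise SD (voxels).
#' @param phantom a \code{phantom_params}.
#' @param target_dims crop target consumed by the CNN.
#' @param arch an \code{arch_config} matching \code{target_dims}.
#' @param train_cfg a \code{train_config}.
#' @param k,val_fraction ensemble parameters.
#' @param age_cutoff,levene_center,model_ids,n_perm analysis options.
#' @param out_dir optional directory for report CSVs.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       n_train_hc = 60L, n_test_hc = 30L, n_test_gad = 30L,
                       n_sites_train = 3L, n_sites_test = 4L,
                       age_range = c(8, 80),
                       age_distribution = "bimodal-youth-heavy",
                       variance_inflation = 1.7,
                       site_offset_sd = 0.05,
                       control_noise_sd = 0.25,
                       phantom = phantom_params(),
                       target_dims = c(24L, 28L, 24L),
                       arch = NULL,
                       train_cfg = NULL,
                       k = 2L, val_fraction = 0.10,
                       age_cutoff = 25, levene_center = "mean",
                       model_ids = 1:3, n_perm = 200L,
                       out_dir = NULL) {
  if (is.null(arch))
    arch <- arch_config(input_dims = target_dims, block_filters = c(4L, 8L),
                        fc_widths = 16L)
  if (is.null(train_cfg))
    train_cfg <- train_config(learning_rate = 2e-3, batch_size = 16L,
                              max_epochs = 10L)
  if (!all(arch$input_dims == target_dims))
    stop_config("arch", "input_dims must equal target_dims")
  structure(list(seed = as.integer(seed),
                 n_train_hc = as.integer(n_train_hc),
                 n_test_hc = as.integer(n_test_hc),
                 n_test_gad = as.integer(n_test_gad),
                 n_sites_train = as.integer(n_sites_train),
                 n_sites_test = as.integer(n_sites_test),
                 age_range = age_range,
                 age_distribution = age_distribution,
                 variance_inflation = variance_inflation,
                 site_offset_sd = site_offset_sd,
                 control_noise_sd = control_noise_sd,
                 phantom = phantom, target_dims = as.integer(target_dims),
                 arch = arch, train_cfg = train_cfg,
                 k = as.integer(k), val_fraction = val_fraction,
                 age_cutoff = age_cutoff, levene_center = levene_center,
                 model_ids = model_ids, n_perm = as.integer(n_perm),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  run_config(seed = seed, n_train_hc = 120L, n_test_hc = 25L,
             n_test_gad = 25L, k = 2L, n_perm = 499L,
             train_cfg = train_config(learning_rate = 2e-3, batch_size = 16L,
                                      max_epochs = 10L,
                                      early_stop_patience = 4L),
             out_dir = out_dir)
}

#' @rdname run_config
#' @export
replica_config <- function(seed = 1L, out_dir = NULL) {
  run_config(seed = seed, n_train_hc = 360L, n_test_hc = 120L,
             n_test_gad = 120L, k = 3L, n_perm = 500L,
             train_cfg = train_config(learning_rate = 2e-3, batch_size = 24L,
                                      max_epochs = 10L,
                                      early_stop_patience = 4L),
             out_dir = out_dir)
}

simulate_stage <- function(cfg, which = c("train", "test")) {
  which <- match.arg(which)
  if (which == "train") {
    spec <- cohort_spec(n_control = cfg$n_train_hc, n_clinical = 0L,
                        n_sites = cfg$n_sites_train,
                        age_range = cfg$age_range,
                        age_distribution = cfg$age_distribution,
                        variance_inflation = cfg$variance_inflation,
                        site_offset_sd = cfg$site_offset_sd,
                        seed = mix_seed(cfg$seed, 11L), site_prefix = "tr")
  } else {
    spec <- cohort_spec(n_control = cfg$n_test_hc,
                        n_clinical = cfg$n_test_gad,
                        n_sites = cfg$n_sites_test,
                        age_range = cfg$age_range,
                        age_distribution = cfg$age_distribution,
                        variance_inflation = cfg$variance_inflation,
                        site_offset_sd = cfg$site_offset_sd,
                        seed = mix_seed(cfg$seed, 12L), site_prefix = "ts")
  }
  sample_cohort(spec)
}

#' Run the full study pipeline
#'
#' Executes simulate -> prep -> ensemble-train -> predict -> analyze at the
#' configured scale and returns a report bundle: (a) an architecture audit
#' of the full-size model (parameter count by closed form and enumeration,
#' per-stage shapes - always at full size, whatever the training scale),
#' (b) per-group PAD summaries, (c) Levene variance analyses across
#' diagnosis and the age partition, (d) permutation GLM results with FWER
#' correction, and (e) the ensemble reliability ICC(2,k). All stage seeds
#' derive from the single global seed, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param cfg a \code{run_config}.
#' @return a named list (the report bundle).
#' @export
run_pipeline <- function(cfg = demo_config()) {
  stopifnot(inherits(cfg, "run_config"))
  full <- arch_config()
  full_model <- build_model(full, seed = 1L)
  audit <- list(param_count_closed_form = count_parameters(full),
                param_count_enumerated = count_realized_parameters(full_model),
                flatten_length = forward_shapes(full)$flatten_length,
                stage_dims = forward_shapes(full)$stage_dims)
  train_cohort <- simulate_stage(cfg, "train")
  test_cohort <- simulate_stage(cfg, "test")
  prep_train <- prepare_cohort(train_cohort, cfg$phantom, cfg$target_dims,
                               cfg$control_noise_sd)
  prep_test <- prepare_cohort(test_cohort, cfg$phantom, cfg$target_dims,
                              cfg$control_noise_sd)
  espec <- ensemble_spec(k = cfg$k, val_fraction = cfg$val_fraction,
                         base_seed = mix_seed(cfg$seed, 13L),
                         arch = cfg$arch, train_cfg = cfg$train_cfg)
  ens <- train_ensemble(list(x = prep_train$batch,
                             ages = prep_train$cohort$age), espec)
  ep <- ensemble_predict(ens$models, prep_test$batch)
  icc <- icc_2k(ep$matrix)
  true_ages <- stats::setNames(prep_test$cohort$age,
                               prep_test$cohort$subject_id)
  preds <- predictions_table(ep, true_ages)
  pad <- compute_pad(ep, prep_test$cohort, age_cutoff = cfg$age_cutoff)
  baseline_mae <- mean(abs(median(prep_train$cohort$age) - pad$true_age))
  glms <- run_pad_glms(pad, perm_config(n_perm = cfg$n_perm,
                                        seed = mix_seed(cfg$seed, 14L)),
                       model_ids = cfg$model_ids)
  report <- list(
    audit = audit,
    seeds = c(global = cfg$seed,
              train_cohort = mix_seed(cfg$seed, 11L),
              test_cohort = mix_seed(cfg$seed, 12L),
              ensemble = mix_seed(cfg$seed, 13L),
              permutation = mix_seed(cfg$seed, 14L)),
    train_cohort = prep_train$cohort,
    test_cohort = prep_test$cohort,
    models = ens$models,
    splits = ens$splits,
    training_logs = ens$logs,
    predictions = preds,
    pad_table = pad,
    ensemble_mae = mean(abs(pad$pad)),
    baseline_mae = baseline_mae,
    icc = icc,
    metrics_by_diagnosis = group_metrics(pad, "diagnosis"),
    metrics_by_cell = group_metrics(
      pad, interaction(pad$diagnosis, pad$age_partition, sep = " ")),
    correlations = correlations(pad),
    levene_tests = pairwise_variance_tests(pad, center = cfg$levene_center),
    site_age_matching = site_age_matching(prep_test$cohort),
    glm_table = glms$table,
    glm_results = glms$results)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write the tabular sections of a report bundle as CSVs
#'
#' @param report a report bundle from \code{\link{run_pipeline}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[length(paths) + 1L] <<- p
  }
  put(data.frame(quantity = c("param_count_closed_form",
                              "param_count_enumerated", "flatten_length"),
                 value = c(report$audit$param_count_closed_form,
                           report$audit$param_count_enumerated,
                           report$audit$flatten_length)),
      "architecture_audit.csv")
  put(report$predictions, "predictions.csv")
  put(report$pad_table, "pad_table.csv")
  put(report$metrics_by_diagnosis, "metrics_by_diagnosis.csv")
  put(report$metrics_by_cell, "metrics_by_group.csv")
  put(report$correlations, "correlations.csv")
  put(report$levene_tests, "levene_tests.csv")
  put(report$site_age_matching, "site_age_matching.csv")
  put(report$glm_table, "glm_results.csv")
  put(data.frame(quantity = c("ensemble_mae", "baseline_mae", "icc_2k"),
                 value = c(report$ensemble_mae, report$baseline_mae,
                           report$icc$icc)),
      "summary.csv")
  prov <- list(seeds = as.list(report$seeds),
               glm = lapply(report$glm_results, function(r)
                 list(n_perm = r$n_perm, enumerated = r$enumerated,
                      seed = r$seed)),
               contrasts = report$glm_table$contrast)
  jp <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, jp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, jp))
}

#' Re-test a trained ensemble on a fresh synthetic test cohort
#'
#' Draws a new test cohort (new subjects, sites and noise realizations, same
#' generating conditions), pushes it through an already-trained ensemble,
#' and reruns the variance and permutation analyses. Used to assess the
#' sampling stability of the study's qualitative finding - inflated PAD
#' variance in the clinical group without a mean shift - without retraining.
#'
#' @param models list of trained \code{cnn_model}s.
#' @param cfg the \code{run_config} the ensemble was trained under.
#' @param replicate_seed seed for the fresh test cohort (and its
#'   permutation schedule).
#' @return list with \code{pad_table}, \code{levene_gad_vs_hc} (the overall
#'   variance test), \code{glm_table}, and \code{icc}.
#' @export
replicate_test_analysis <- function(models, cfg, replicate_seed) {
  stopifnot(inherits(cfg, "run_config"))
  rcfg <- cfg
  rcfg$seed <- as.integer(replicate_seed)
  test_cohort <- simulate_stage(rcfg, "test")
  prep <- prepare_cohort(test_cohort, cfg$phantom, cfg$target_dims,
                         cfg$control_noise_sd)
  ep <- ensemble_predict(models, prep$batch)
  pad <- compute_pad(ep, prep$cohort, age_cutoff = cfg$age_cutoff)
  lev <- levene_test(split(pad$pad, pad$diagnosis),
                     center = cfg$levene_center)
  glms <- run_pad_glms(pad, perm_config(n_perm = cfg$n_perm,
                                        seed = mix_seed(replicate_seed, 14L)),
                       model_ids = cfg$model_ids)
  list(pad_table = pad, levene_gad_vs_hc = lev, glm_table = glms$table,
       icc = icc_2k(ep$matrix))
}
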