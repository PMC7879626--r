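#' End-to-end run configuration
#'
#' Bundles every stage's parameters with a master seed from which the
#' stage seeds are derived by fixed offsets (+1 simulation, +2 cohort,
#' +3 model, +4 bootstrap), so one integer reproduces the whole run.
#'
#' @param sim a [sim_config()].
#' @param ratio control:case ratio for [build_cohort()].
#' @param top_k relative-risk screening cut (default 500).
#' @param nrounds,max_depth,eta,cv passed to [phenotype_model()].
#' @param n_reps,level bootstrap settings for [evaluate_definitions()].
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), ratio = 233, top_k = 500,
                       nrounds = 500, max_depth = 4, eta = 0.05, cv = TRUE,
                       n_reps = 1000, level = 0.95, seed = 1L) {
  structure(list(sim = sim, ratio = ratio, top_k = top_k, nrounds = nrounds,
                 max_depth = max_depth, eta = eta, cv = cv,
                 n_reps = n_reps, level = level, seed = as.integer(seed)),
            class = "run_config")
}

named_to_map <- function(x) as.list(x)
map_to_named <- function(x) unlist(x)

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips: `read_run_config(write_run_config(cfg,
#' path))` reproduces an equivalent `run_config`.
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(cfg, path) {
  sim <- cfg$sim
  lst <- list(
    seed = cfg$seed, ratio = cfg$ratio, top_k = cfg$top_k,
    nrounds = cfg$nrounds, max_depth = cfg$max_depth, eta = cfg$eta,
    cv = cfg$cv, n_reps = cfg$n_reps, level = cfg$level,
    sim = list(
      n_patients = sim$n_patients,
      t1d_prevalence = sim$t1d_prevalence,
      hemophilia_prevalence = sim$hemophilia_prevalence,
      coding_sensitivity_e10 = sim$coding_sensitivity_e10,
      chart_review_error = sim$chart_review_error,
      visit_probs = named_to_map(sim$visit_probs),
      emissions = lapply(as.list(sim$emissions), function(col)
        if (is.numeric(col)) ifelse(is.na(col), -1, col) else col),
      n_noise_codes = sim$n_noise_codes,
      noise_rate_range = sim$noise_rate_range,
      labs = lapply(sim$labs, function(l) lapply(l, named_to_map)),
      referral_prob = named_to_map(sim$referral_prob),
      male_prob = sim$male_prob,
      age_range = sim$age_range,
      basal_insulin_codes = sim$basal_insulin_codes,
      training_window = format(sim$training_window),
      test_window = format(sim$test_window),
      seed = sim$seed))
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  s <- lst$sim
  em <- as.data.frame(lapply(s$emissions, function(col)
    if (is.numeric(col)) ifelse(col < 0, NA_real_, col) else unlist(col)))
  sim <- sim_config(
    n_patients = s$n_patients, t1d_prevalence = s$t1d_prevalence,
    hemophilia_prevalence = s$hemophilia_prevalence,
    coding_sensitivity_e10 = s$coding_sensitivity_e10,
    chart_review_error = s$chart_review_error,
    visit_probs = map_to_named(s$visit_probs),
    emissions = em, n_noise_codes = s$n_noise_codes,
    noise_rate_range = unlist(s$noise_rate_range),
    labs = lapply(s$labs, function(l) lapply(l, map_to_named)),
    referral_prob = map_to_named(s$referral_prob),
    male_prob = s$male_prob,
    age_range = lapply(s$age_range, unlist),
    basal_insulin_codes = unlist(s$basal_insulin_codes),
    training_window = as.Date(unlist(s$training_window)),
    test_window = as.Date(unlist(s$test_window)),
    seed = s$seed)
  run_config(sim = sim, ratio = lst$ratio, top_k = lst$top_k,
             nrounds = lst$nrounds, max_depth = lst$max_depth, eta = lst$eta,
             cv = lst$cv, n_reps = lst$n_reps, level = lst$level,
             seed = lst$seed)
}

#' Run the whole validation pipeline
#'
#' simulate -> gold-standard cohort -> feature matrix + relative-risk
#' screening -> gradient-boosted phenotype model -> score the unseen test
#' population -> evaluate the built-in case definitions with bootstrap
#' CIs.  Re-running with the same configuration reproduces identical
#' results; stage timings are logged to stderr.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all stage outputs
#'   (datasets, `cohort.csv`, `importance.tsv`, `scores.csv`,
#'   `results.tsv`, `manifest.json`) are written there.
#' @param quiet suppress stage logging.
#' @return list of class `phenoval_run`: `sim`, `cohort`, `model`,
#'   `scores`, `results`, `calibration`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf("[phenoval %s] ", format(Sys.time(), "%H:%M:%S")),
                        sprintf(fmt, ...))
  }
  seeds <- c(sim = config$seed + 1L, cohort = config$seed + 2L,
             model = config$seed + 3L, bootstrap = config$seed + 4L)

  log_stage("simulate: n=%d", config$sim$n_patients)
  sim <- simulate_claims(config$sim, seed = seeds[["sim"]])

  log_stage("cohort: screening + adjudication + sampling")
  cohort <- build_cohort(sim$train, sim$truth, ratio = config$ratio,
                         error_rate = config$sim$chart_review_error,
                         seed = seeds[["cohort"]])
  keep <- cohort$status %in% c("case", "control")
  cohort_ids <- cohort$patient_id[keep]
  labels <- as.numeric(cohort$status[keep] == "case")

  log_stage("features: building + top-%d relative-risk screening", config$top_k)
  X <- build_features(sim$train)
  Xc <- screen_features(X[cohort_ids, , drop = FALSE], labels, k = config$top_k)

  log_stage("model: gradient boosting (%d cases / %d controls)",
            sum(labels), sum(1 - labels))
  model <- phenotype_model(Xc, labels, seed = seeds[["model"]],
                           nrounds = config$nrounds,
                           max_depth = config$max_depth, eta = config$eta,
                           cv = config$cv)

  log_stage("score: %d test patients", nrow(sim$test$patients))
  Xt <- build_features(sim$test)
  scores <- suppressWarnings(score_patients(model, Xt))
  truth_test <- sim$truth$latent_t1d[match(scores$patient_id,
                                           sim$truth$patient_id)]
  cal <- calibration_check(scores$p_case, truth_test)

  log_stage("evaluate: %d definitions, %d bootstrap reps",
            11L, config$n_reps)
  defs <- builtin_definitions(config$sim$basal_insulin_codes)
  results <- evaluate_definitions(scores, defs, sim$test,
                                  n_reps = config$n_reps,
                                  level = config$level,
                                  seed = seeds[["bootstrap"]],
                                  calibration = cal)

  cfg_file <- tempfile(fileext = ".yaml")
  write_run_config(config, cfg_file)
  manifest <- list(package = "phenoval",
                   version = as.character(utils::packageVersion("phenoval")),
                   r_version = as.character(getRversion()),
                   master_seed = config$seed,
                   stage_seeds = as.list(seeds),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   n_cases = sum(labels), n_controls = sum(1 - labels),
                   mean_cv_auc = if (length(model$cv_auc)) mean(model$cv_auc) else NA,
                   calibration_slope = cal$slope)
  unlink(cfg_file)

  run <- structure(list(sim = sim, cohort = cohort, model = model,
                        scores = scores, results = results,
                        calibration = cal, manifest = manifest,
                        config = config),
                   class = "phenoval_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, file.path(out_dir, "data"))
    utils::write.csv(as.data.frame(cohort), file.path(out_dir, "cohort.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(model$importance, file.path(out_dir, "importance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(scores), file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    write_performance(results, file.path(out_dir, "results.tsv"))
    write_run_config(config, file.path(out_dir, "run.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.phenoval_run <- function(x, ...) {
  cat("phenoval pipeline run (master seed ", x$config$seed, ")\n", sep = "")
  print(x$sim)
  print(x$cohort)
  print(x$model)
  print(x$results)
  invisible(x)
}
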