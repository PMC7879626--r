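small_cfg <- function(...) sim_config(n_patients = 1000, n_noise_codes = 50, ...)

test_that("latent prevalence behaves binomially", {
  # zero prevalence -> no latent cases
  sim0 <- simulate_claims(small_cfg(t1d_prevalence = 0), seed = 3)
  expect_equal(sum(sim0$truth$latent_t1d), 0)

  # default prevalence at n=20000: count within 3 binomial SDs of 100
  sim <- mid_sim()
  expect_equal(nrow(sim$truth), 20000)
  expected <- 20000 * 0.005
  sd3 <- 3 * sqrt(20000 * 0.005 * 0.995)
  expect_lt(abs(sum(sim$truth$latent_t1d) - expected), sd3)
})

test_that("perfect E10 coding marks every latent case", {
  sim <- simulate_claims(
    sim_config(n_patients = 2000, n_noise_codes = 0,
               coding_sensitivity_e10 = 1, t1d_prevalence = 0.05), seed = 5)
  ev <- rbind(sim$train$events, sim$test$events)
  e10_ids <- unique(ev$patient_id[ev$system == "icd10_confirmed" &
                                    ev$code == "E10"])
  t1d_ids <- sim$truth$patient_id[sim$truth$latent_t1d]
  expect_true(all(t1d_ids %in% e10_ids))
})

test_that("identical seed and config give identical output files", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_claims(cfg, seed = 42), d1)
  write_simulation(simulate_claims(cfg, seed = 42), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
  # different seed changes the draw
  d3 <- withr::local_tempdir()
  write_simulation(simulate_claims(cfg, seed = 43), d3)
  expect_false(identical(readLines(file.path(d3, "truth.csv")),
                         readLines(file.path(d1, "truth.csv"))))
})

test_that("empirical emission frequencies converge to the table", {
  sim <- big_sim()
  cfg <- sim$config
  truth <- sim$truth
  check_freq <- function(ds, code, system, class) {
    ids <- ds$patients$patient_id
    t1d <- truth$latent_t1d[match(ids, truth$patient_id)]
    hemo <- truth$latent_hemophilia[match(ids, truth$patient_id)]
    grp <- switch(class,
                  background = ids[!t1d & !hemo],
                  t1d = ids[t1d],
                  hemophilia = ids[hemo & !t1d])
    carriers <- unique(ds$events$patient_id[ds$events$system == system &
                                              ds$events$code == code])
    p_hat <- mean(grp %in% carriers)
    row <- cfg$emissions[cfg$emissions$code == code &
                           cfg$emissions$system == system, ]
    p <- switch(class, background = row$p_background, t1d = row$p_t1d,
                hemophilia = row$p_hemophilia)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / length(grp)) + 1e-12,
              label = paste(class, code, "freq", signif(p_hat, 3), "vs", p))
  }
  check_freq(sim$test, "160010010", "procedure", "background")  # HbA1c
  check_freq(sim$test, "E10", "icd10_confirmed", "t1d")
  check_freq(sim$test, "114010970", "procedure", "t1d")
  check_freq(sim$train, "114010970", "procedure", "hemophilia")
  check_freq(sim$train, "insulin_glargine", "medication", "t1d")
})

test_that("configuration errors are caught", {
  expect_error(sim_config(t1d_prevalence = 1.5), "probabilities")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(visit_probs = c(0.5, 0.2, 0.2)), "visit_probs")
  em <- default_emissions()
  expect_error(sim_config(emissions = em[em$code != "E10", ]),
               "configuration error.*E10")
  expect_error(sim_config(basal_insulin_codes = character(0)),
               "configuration error")
})

test_that("true_definition_performance computes the classical 2x2", {
  sim <- simulate_claims(small_cfg(t1d_prevalence = 0.02), seed = 9)
  defs <- builtin_definitions()

  # a definition matching nobody: sensitivity 0, PPV undefined but flagged
  nothing <- case_definition("nothing",
                             code_predicate("procedure", "no_such_code"))
  perf <- true_definition_performance(nothing, sim$test, sim$truth)
  expect_equal(perf$sensitivity, 0)
  expect_true(is.na(perf$ppv))
  expect_true("ppv" %in% perf$undefined)

  # truth leaked as a code: perfect sensitivity and PPV
  leak <- sim$test
  t1d_ids <- sim$truth$patient_id[sim$truth$latent_t1d]
  t1d_ids <- intersect(t1d_ids, leak$patients$patient_id)
  leak$events <- rbind(leak$events,
                       data.frame(patient_id = t1d_ids,
                                  date = as.Date("2016-01-01"),
                                  system = "procedure", code = "999999999"))
  oracle_def <- case_definition("leak", code_predicate("procedure", "999999999"))
  perf <- true_definition_performance(oracle_def, leak, sim$truth)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$ppv, 1)

  # truth must cover the dataset
  drop_id <- sim$test$patients$patient_id[1]
  expect_error(
    true_definition_performance(defs[[1]], sim$test,
                                sim$truth[sim$truth$patient_id != drop_id, ]),
    "referential error")
})

test_that("a definition independent of disease has PPV near prevalence", {
  em <- rbind(default_emissions(),
              data.frame(system = "procedure", code = "777777777",
                         p_background = 0.10, p_t1d = 0.10,
                         p_hemophilia = NA_real_))
  sim <- simulate_claims(sim_config(n_patients = 20000, emissions = em,
                                    n_noise_codes = 0), seed = 13)
  rand_def <- case_definition("independent",
                              code_predicate("procedure", "777777777"))
  perf <- true_definition_performance(rand_def, sim$test, sim$truth)
  n_pos <- perf$tp + perf$fp
  expect_gt(n_pos, 500)
  mc3 <- 3 * sqrt(0.005 * 0.995 / n_pos)
  expect_lt(abs(perf$ppv - 0.005), mc3 + 0.003)
})

test_that("oracle scores are calibrated posteriors", {
  sim <- mid_sim()
  sc <- oracle_scores(sim$test, sim$config)
  expect_true(all(sc$p_case >= 0 & sc$p_case <= 1))
  truth <- sim$truth$latent_t1d[match(sc$patient_id, sim$truth$patient_id)]
  # total predicted case mass matches the realized case count
  expect_lt(abs(sum(sc$p_case) - sum(truth)) / max(sum(truth), 1), 0.35)
  # reliability slope near 1
  cal <- calibration_check(sc$p_case, truth)
  expect_true(cal$ok)
})
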