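test_that("the five screening criteria fire as specified", {
  ds <- toy_dataset()
  sc <- screen_possible_cases(ds)
  row <- function(id) sc[sc$patient_id == id, ]

  # A: confirmed E10 -> c1 only
  expect_identical(row("A")$matched_criteria, "c1")
  # B: insulin + CPR 0.5 + ketoacidosis -> c2 (CPR 0.5 also < 0.6 but not < 0.2)
  expect_true(row("B")$c2); expect_false(row("B")$c5)
  # C: insulin + CPR exactly 0.6 -> c2 must NOT fire (strict <)
  expect_false("C" %in% sc$patient_id)
  # D: GAD positive -> c3
  expect_identical(row("D")$matched_criteria, "c3")
  # E: referral flag + confirmed E101 (prefix E10) -> c1 + c4
  expect_identical(row("E")$matched_criteria, "c1+c4")
  # F: CPR 0.15 -> c5 (and nothing else: no insulin/ketoacidosis for c2)
  expect_identical(row("F")$matched_criteria, "c5")
})

test_that("screening is monotone under added evidence", {
  sim <- simulate_claims(sim_config(n_patients = 800, n_noise_codes = 30,
                                    t1d_prevalence = 0.02), seed = 21)
  ds <- sim$train
  before <- screen_possible_cases(ds)
  # hand every patient an extra positive GAD lab and a confirmed E10 code
  add_ids <- ds$patients$patient_id
  ds2 <- ds
  ds2$labs <- rbind(ds$labs,
                    data.frame(patient_id = add_ids, date = as.Date("2010-01-01"),
                               test = "gad_antibody", value = 1))
  ds2$events <- rbind(ds$events,
                      data.frame(patient_id = add_ids, date = as.Date("2010-01-01"),
                                 system = "icd10_confirmed", code = "E10"))
  after <- screen_possible_cases(ds2)
  expect_true(all(before$patient_id %in% after$patient_id))
  both <- intersect(before$patient_id, after$patient_id)
  for (cr in c("c1", "c2", "c3", "c4", "c5")) {
    b <- before[[cr]][match(both, before$patient_id)]
    a <- after[[cr]][match(both, after$patient_id)]
    expect_true(all(a >= b), label = cr)
  }
})

test_that("adjudication follows truth and flips binomially", {
  truth <- data.frame(patient_id = sprintf("P%04d", 1:1000),
                      latent_t1d = rep(c(TRUE, FALSE), 500))
  v0 <- adjudicate(truth$patient_id, truth, error_rate = 0)
  expect_identical(v0$verdict == "true_t1d", truth$latent_t1d)
  v1 <- adjudicate(truth$patient_id, truth, error_rate = 1)
  expect_identical(v1$verdict == "true_t1d", !truth$latent_t1d)
  v01 <- adjudicate(truth$patient_id, truth, error_rate = 0.1, seed = 17)
  flips <- sum((v01$verdict == "true_t1d") != truth$latent_t1d)
  expect_lt(abs(flips - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # deterministic given seed
  expect_identical(adjudicate(truth$patient_id, truth, 0.1, seed = 17), v01)
  expect_error(adjudicate("QQQ", truth), "referential error")
})

test_that("case exclusions remove transplant and T2D patients", {
  ds <- toy_dataset()
  ds$events <- rbind(
    ds$events,
    data.frame(patient_id = "A", date = as.Date("2010-01-01"),
               system = "procedure",
               code = claim_code_registry()$pancreas_transplant))
  verdicts <- data.frame(patient_id = c("A", "B", "E"),
                         verdict = "true_t1d")
  cases <- build_cases(verdicts, ds)
  expect_identical(cases$status[cases$patient_id == "A"], "excluded_case")
  expect_identical(cases$exclusion_reason[cases$patient_id == "A"], "transplant")
  # B carries suspected E11 -> excluded for T2D
  expect_identical(cases$status[cases$patient_id == "B"], "excluded_case")
  expect_identical(cases$exclusion_reason[cases$patient_id == "B"], "t2d")
  expect_identical(cases$status[cases$patient_id == "E"], "case")
})

test_that("control sampling is ratio-targeted, pool-limited and seeded", {
  n <- 600
  patients <- data.frame(patient_id = sprintf("C%04d", 1:n), sex = "female",
                         birth_year = 1980)
  ds <- study_dataset(patients)
  pool_expect <- function(reviewed, n_cases, ratio)
    sample_controls(ds, reviewed, n_cases, ratio, seed = 2)

  ctl <- pool_expect(patients$patient_id[1:100], n_cases = 2, ratio = 100)
  expect_length(ctl, 200)
  # pool-limited: 150 eligible but 200 wanted
  ctl2 <- pool_expect(patients$patient_id[1:450], n_cases = 2, ratio = 100)
  expect_length(ctl2, 150)
  # deterministic
  expect_identical(pool_expect(patients$patient_id[1:100], 2, 100), ctl)
  # empty pool errors
  expect_error(pool_expect(patients$patient_id, 2, 100), "cohort error")
})

test_that("controls never carry a T1D code and never overlap cases", {
  sim <- simulate_claims(sim_config(n_patients = 6000, n_noise_codes = 100),
                         seed = 8)
  coh <- build_cohort(sim$train, sim$truth, ratio = 50, seed = 4)
  cases <- coh$patient_id[coh$status == "case"]
  controls <- coh$patient_id[coh$status == "control"]
  expect_length(intersect(cases, controls), 0)
  ev <- sim$train$events
  t1d_coded <- unique(ev$patient_id[
    ev$system %in% c("icd10_confirmed", "icd10_suspected") &
      startsWith(ev$code, "E10")])
  expect_length(intersect(controls, t1d_coded), 0)
})

test_that("with error-free adjudication cases equal screened latent cases minus exclusions", {
  sim <- simulate_claims(sim_config(n_patients = 6000, n_noise_codes = 100),
                         seed = 8)
  coh <- build_cohort(sim$train, sim$truth, ratio = 50, seed = 4)
  screened <- screen_possible_cases(sim$train)
  latent <- sim$truth$patient_id[sim$truth$latent_t1d]
  expected_cases <- intersect(screened$patient_id, latent)
  codes <- cohort_codes()
  ev <- sim$train$events
  excl <- union(
    unique(ev$patient_id[ev$system == "procedure" &
                           ev$code %in% codes$transplant_codes]),
    unique(ev$patient_id[ev$system %in% c("icd10_confirmed", "icd10_suspected") &
                           startsWith(ev$code, "E11")]))
  expect_setequal(coh$patient_id[coh$status == "case"],
                  setdiff(expected_cases, excl))
})
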