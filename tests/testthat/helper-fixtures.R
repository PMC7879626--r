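# Shared fixtures. Expensive simulations are cached for the whole test run.

get_cached <- function(key, expr) {
  cache <- getOption("phenoval.test.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(phenoval.test.cache = cache)
  }
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, force(expr), envir = cache)
  }
  get(key, envir = cache, inherits = FALSE)
}

# default study conditions at full scale (used by acceptance checks)
big_sim <- function() {
  get_cached("sim50k", simulate_claims(sim_config(n_patients = 50000), seed = 1))
}

# default study conditions at the package's default population size
mid_sim <- function() {
  get_cached("sim20k", simulate_claims(sim_config(n_patients = 20000), seed = 1))
}

# Hand-built six-patient dataset exercising the screening criteria,
# exclusions and case definitions.
toy_dataset <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    sex = c("male", "female", "male", "female", "male", "female"),
    birth_year = c(1990, 1985, 2000, 1970, 1995, 1980))
  d <- as.Date("2010-06-01")
  events <- data.frame(
    patient_id = c("A", "B", "B", "B", "C", "C", "D", "E", "E"),
    date = d,
    system = c("icd10_confirmed",                      # A: confirmed E10
               "medication", "icd10_confirmed", "icd10_suspected",  # B
               "medication", "icd10_confirmed",        # C: insulin + ketoacidosis
               "icd10_confirmed",                      # D: unrelated dx
               "procedure", "icd10_confirmed"),        # E: needle + E10 subcode
    code = c("E10",
             "insulin_aspart", "E872", "E11",
             "insulin_glargine", "E872",
             "J45",
             "114010970", "E101"))
  labs <- data.frame(
    patient_id = c("B", "C", "D", "F"),
    date = d,
    test = c("serum_cpr", "serum_cpr", "gad_antibody", "serum_cpr"),
    value = c(0.5, 0.6, 1, 0.15))
  flags <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    diabetologist_referral = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    chart_review_verdict = "not_reviewed")
  study_dataset(patients, events, labs, flags, period = "training",
                window = as.Date(c("2009-01-01", "2015-01-01")))
}

# Brute-force classical 2x2 indexes, written independently of the package
# internals, for degenerate-equivalence checks.
naive_indexes <- function(p, pos) {
  stopifnot(all(p %in% c(0, 1)))
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(p)) {
    if (pos[i]) {
      if (p[i] == 1) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (p[i] == 1) fn <- fn + 1 else tn <- tn + 1
    }
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (fn + tn > 0) tn / (fn + tn) else NA_real_
  f <- if (!is.na(sens) && !is.na(ppv) && sens + ppv > 0)
    2 * sens * ppv / (sens + ppv) else NA_real_
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f_score = f)
}
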