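#' Default basal-insulin medication codes
#'
#' The basal-insulin list (long-acting analogs, intermediate-acting
#' insulin, biphasic insulin) identified by their generic names.  This is
#' a user-editable placeholder catalogue: real deployments substitute the
#' local formulary's claim codes.
#'
#' @return character vector of generic medication codes.
#' @export
default_basal_insulin_codes <- function() {
  c("insulin_glargine", "insulin_detemir", "insulin_degludec",
    "insulin_nph", "insulin_biphasic")
}

#' Claims codes with special roles in the pipeline
#'
#' Central registry of the non-diagnosis codes the case definitions,
#' screening criteria and leakage list refer to: injector needles for
#' insulin-dependent (and hemophilia) patients, the two CSII syringe-pump
#' codes, the CPR and insulin-receptor-autoantibody test claims, and the
#' pancreas-transplant procedure used for case exclusion.
#'
#' @return named list of code strings / vectors.
#' @export
claim_code_registry <- function() {
  list(needle = "114010970",
       pump = c("114004810", "114022010"),
       cpr_test = "160012345",
       insulin_receptor_ab_test = "160011010",
       pancreas_transplant = "150285010",
       hba1c = "160010010",
       glucometer = "160151050",
       glycoalbumin = "114015610")
}

#' Default signal-code emission table
#'
#' Per-period Bernoulli emission probabilities for the codes that carry
#' class information, by latent class (`NA` inherits the next class down
#' under the precedence t1d > hemophilia > background).  Rates are chosen
#' so that, at the default 0.5% prevalence, the marginal operating
#' characteristics of the single-code definitions land in the regime
#' typical of claims-validation studies of type 1 diabetes (confirmed-code
#' sensitivity about one third, needle-code PPV raised by restricting to
#' diagnosed patients, rare CSII pump use).
#'
#' @param coding_sensitivity_e10 probability a true case carries the
#'   confirmed E10 code per visited period.
#' @param basal_codes basal-insulin medication codes to include.
#' @return data.frame with columns `system`, `code`, `p_background`,
#'   `p_t1d`, `p_hemophilia`.
#' @export
default_emissions <- function(coding_sensitivity_e10 = 0.33,
                              basal_codes = default_basal_insulin_codes()) {
  reg <- claim_code_registry()
  em <- function(system, code, bg, t1d = NA_real_, hemo = NA_real_) {
    data.frame(system = system, code = code, p_background = bg,
               p_t1d = t1d, p_hemophilia = hemo)
  }
  basal_t1d <- c(0.22, 0.10, 0.08, 0.03, 0.04)
  basal_bg <- c(0.004, 0.002, 0.002, 0.001, 0.003)
  basal_rows <- if (length(basal_codes)) {
    em("medication", basal_codes,
       rep_len(basal_bg, length(basal_codes)),
       rep_len(basal_t1d, length(basal_codes)))
  }
  rbind(
    em("icd10_confirmed", "E10", 0.0033, coding_sensitivity_e10),
    em("icd10_confirmed", "E11", 0.08, 0.05),
    em("icd10_confirmed", "E14", 0.01, 0.15),
    em("icd10_confirmed", "E872", 0.003, 0.30),   # ketoacidosis marker
    em("icd10_confirmed", "D66", 5e-04, NA, 0.90),
    em("icd10_suspected", "E10", 0.004, 0.30),
    em("icd10_suspected", "E11", 0.05, 0.05),
    em("icd10_suspected", "E14", 0.02),
    em("icd10_suspected", "R73", 0.02, 0.15),
    basal_rows,
    em("medication", "insulin_aspart", 0.004, 0.35),
    em("medication", "insulin_lispro", 0.003, 0.20),
    em("medication", "metformin", 0.03, 0.01),
    em("procedure", reg$needle, 2e-04, 0.33, 0.35),
    em("procedure", reg$pump[2], 2e-05, 0.035),
    em("procedure", reg$pump[1], 1e-05, 0.005),
    em("procedure", reg$hba1c, 0.25, 0.90),
    em("procedure", reg$glucometer, 0.005, 0.20),
    em("procedure", reg$glycoalbumin, 0.01, 0.20),
    em("procedure", reg$cpr_test, 0.02, 0.60),
    em("procedure", reg$insulin_receptor_ab_test, 0.002, 0.30),
    em("procedure", reg$pancreas_transplant, 1e-05, 0.005)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic hospital population.  Defaults emulate the
#' study conditions this package targets: a rare insulin-dependent
#' diabetes phenotype (0.5% prevalence) whose confirmed E10 diagnosis code
#' is carried by only about a third of true patients, a hemophilia
#' subpopulation sharing the injector-needle claim code, basal-insulin and
#' CSII-pump codes, lognormal serum-CPR values concentrated below
#' 0.6 ng/ml for true patients, and a background population emitting a
#' large catalogue of noise codes.
#'
#' Per-code emission probabilities are period-level Bernoulli draws: a
#' patient visiting a period carries the code in that period with the
#' stated probability, independently across codes and periods.  Class
#' precedence for a code's probability is t1d > hemophilia > background;
#' `NA` inherits the next class down.
#'
#' @param n_patients total number of simulated patients (across both
#'   periods).
#' @param t1d_prevalence,hemophilia_prevalence latent class probabilities
#'   (independent Bernoulli draws per patient).
#' @param coding_sensitivity_e10 probability a true T1D patient carries the
#'   confirmed E10 code in a visited period.
#' @param chart_review_error probability the adjudication oracle
#'   contradicts latent truth (0 = chart review treated as truth).
#' @param visit_probs probabilities a patient visits only the training
#'   window, both windows, or only the test window (must sum to 1).
#' @param emissions data.frame(system, code, p_background, p_t1d,
#'   p_hemophilia) of signal-code emission probabilities.
#' @param n_noise_codes size of the background noise-code catalogue
#'   (class-independent emission rates, log-uniform over
#'   `noise_rate_range`).
#' @param noise_rate_range range of background noise-code rates.
#' @param labs list of lab-test parameters (`cpr`, `gad`, `ia2`): per-class
#'   testing probabilities, lognormal CPR location/scale by latent status,
#'   antibody positivity probabilities.
#' @param referral_prob per-class probability of the diabetologist-referral
#'   flag.
#' @param male_prob probability a patient is male.
#' @param age_range named list of inclusive age ranges (at window start)
#'   per latent class.
#' @param basal_insulin_codes the basal-insulin medication list used by
#'   the built-in case definitions.
#' @param training_window,test_window half-open calendar windows.
#' @param seed default seed used when [simulate_claims()] is called
#'   without one.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 20000,
                       t1d_prevalence = 0.005,
                       hemophilia_prevalence = 0.002,
                       coding_sensitivity_e10 = 0.33,
                       chart_review_error = 0,
                       visit_probs = c(train_only = 0.25, both = 0.15,
                                       test_only = 0.60),
                       emissions = NULL,
                       n_noise_codes = 1000,
                       noise_rate_range = c(1e-04, 0.05),
                       labs = NULL,
                       referral_prob = c(background = 5e-04, t1d = 0.5),
                       male_prob = 0.455,
                       age_range = list(background = c(0, 90),
                                        t1d = c(8, 40),
                                        hemophilia = c(5, 60)),
                       basal_insulin_codes = default_basal_insulin_codes(),
                       training_window = as.Date(c("2009-01-01", "2015-01-01")),
                       test_window = as.Date(c("2015-01-01", "2020-01-01")),
                       seed = 1L) {
  if (is.null(emissions)) {
    emissions <- default_emissions(coding_sensitivity_e10, basal_insulin_codes)
  }
  if (is.null(labs)) {
    labs <- list(
      cpr = list(test_prob = c(background = 0.02, t1d = 0.60),
                 meanlog = c(background = log(1.8), t1d = log(0.25)),
                 sdlog = c(background = 0.5, t1d = 0.7)),
      gad = list(test_prob = c(background = 0.01, t1d = 0.60),
                 pos_prob = c(background = 0.01, t1d = 0.65)),
      ia2 = list(test_prob = c(background = 0.005, t1d = 0.40),
                 pos_prob = c(background = 0.005, t1d = 0.55)))
  }
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         t1d_prevalence = t1d_prevalence,
         hemophilia_prevalence = hemophilia_prevalence,
         coding_sensitivity_e10 = coding_sensitivity_e10,
         chart_review_error = chart_review_error,
         visit_probs = visit_probs,
         emissions = emissions,
         n_noise_codes = as.integer(n_noise_codes),
         noise_rate_range = noise_rate_range,
         labs = labs,
         referral_prob = referral_prob,
         male_prob = male_prob,
         age_range = age_range,
         basal_insulin_codes = basal_insulin_codes,
         training_window = as.Date(training_window),
         test_window = as.Date(test_window),
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$t1d_prevalence, cfg$hemophilia_prevalence,
             cfg$coding_sensitivity_e10, cfg$chart_review_error,
             cfg$visit_probs, cfg$emissions$p_background,
             cfg$referral_prob, cfg$male_prob)
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients <= 0) {
    stop("configuration error: n_patients must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$visit_probs) - 1) > 1e-8) {
    stop("configuration error: visit_probs must sum to 1", call. = FALSE)
  }
  if (length(cfg$basal_insulin_codes) == 0L) {
    stop("configuration error: basal-insulin code list is empty", call. = FALSE)
  }
  reg <- claim_code_registry()
  required <- c("E10", reg$needle, reg$pump, cfg$basal_insulin_codes)
  missing <- setdiff(required, cfg$emissions$code)
  if (length(missing)) {
    stop("configuration error: emission table lacks code(s) required by the ",
         "built-in case definitions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

# Effective per-patient emission probability under class precedence
# t1d > hemophilia > background (NA inherits the next class down).
effective_prob <- function(row_bg, row_t1d, row_hemo, is_t1d, is_hemo) {
  p <- rep(row_bg, length(is_t1d))
  if (!is.na(row_hemo)) p[is_hemo] <- row_hemo
  if (!is.na(row_t1d)) p[is_t1d] <- row_t1d
  p
}

by_class <- function(param, is_t1d, is_hemo = NULL) {
  p <- rep(param[["background"]], length(is_t1d))
  if (!is.null(is_hemo) && "hemophilia" %in% names(param)) {
    p[is_hemo] <- param[["hemophilia"]]
  }
  p[is_t1d] <- param[["t1d"]]
  p
}

noise_catalogue <- function(cfg) {
  n <- cfg$n_noise_codes
  if (n == 0L) {
    return(data.frame(system = character(), code = character(), p = numeric()))
  }
  n_conf <- ceiling(0.40 * n); n_susp <- ceiling(0.25 * n)
  n_med <- ceiling(0.175 * n)
  n_proc <- max(0L, n - n_conf - n_susp - n_med)
  n <- n_conf + n_susp + n_med + n_proc
  letters_ok <- setdiff(LETTERS, c("E", "D", "R"))  # keep clear of signal ICD codes
  grid <- as.vector(outer(letters_ok, sprintf("%02d", 0:99), paste0))
  icd <- sample(grid, n_conf + n_susp)
  data.frame(
    system = c(rep("icd10_confirmed", n_conf), rep("icd10_suspected", n_susp),
               rep("medication", n_med), rep("procedure", n_proc)),
    code = c(icd, sprintf("generic_%04d", seq_len(n_med)),
             sprintf("17%07d", seq_len(n_proc))),
    p = exp(runif(n, log(cfg$noise_rate_range[1]), log(cfg$noise_rate_range[2]))))
}

rand_dates <- function(n, window) {
  window[1] + floor(runif(n, 0, as.numeric(window[2] - window[1])))
}

# Emit one period's coded events for the patients indexed by `idx`.
emit_period_events <- function(cfg, idx, ids, is_t1d, is_hemo, noise, window) {
  out <- vector("list", nrow(cfg$emissions) + nrow(noise))
  k <- 0L
  for (i in seq_len(nrow(cfg$emissions))) {
    row <- cfg$emissions[i, ]
    p <- effective_prob(row$p_background, row$p_t1d, row$p_hemophilia,
                        is_t1d[idx], is_hemo[idx])
    hit <- idx[runif(length(idx)) < p]
    if (length(hit)) {
      k <- k + 1L
      out[[k]] <- data.frame(patient_id = ids[hit], system = row$system,
                             code = row$code)
    }
  }
  for (i in seq_len(nrow(noise))) {
    n_hit <- rbinom(1L, length(idx), noise$p[i])
    if (n_hit > 0L) {
      k <- k + 1L
      out[[k]] <- data.frame(patient_id = ids[sample(idx, n_hit)],
                             system = noise$system[i], code = noise$code[i])
    }
  }
  ev <- do.call(rbind, out[seq_len(k)])
  if (is.null(ev)) return(empty_events())
  ev$date <- rand_dates(nrow(ev), window)
  ev[, c("patient_id", "date", "system", "code")]
}

emit_period_labs <- function(cfg, idx, ids, is_t1d, is_hemo, window) {
  draws <- list()
  tested_of <- function(param) idx[runif(length(idx)) < by_class(param, is_t1d[idx], is_hemo[idx])]

  t <- tested_of(cfg$labs$cpr$test_prob)
  if (length(t)) {
    draws$cpr <- data.frame(
      patient_id = ids[t], test = "serum_cpr",
      value = rlnorm(length(t),
                     by_class(cfg$labs$cpr$meanlog, is_t1d[t]),
                     by_class(cfg$labs$cpr$sdlog, is_t1d[t])))
  }
  for (ab in c("gad", "ia2")) {
    t <- tested_of(cfg$labs[[ab]]$test_prob)
    if (length(t)) {
      draws[[ab]] <- data.frame(
        patient_id = ids[t], test = paste0(ab, "_antibody"),
        value = as.numeric(runif(length(t)) <
                             by_class(cfg$labs[[ab]]$pos_prob, is_t1d[t])))
    }
  }
  labs <- do.call(rbind, draws)
  if (is.null(labs)) return(empty_labs())
  labs$date <- rand_dates(nrow(labs), window)
  rownames(labs) <- NULL
  labs[, c("patient_id", "date", "test", "value")]
}

#' Simulate a claims/EHR study population with known latent truth
#'
#' Generates disjoint training and test populations plus the latent ground
#' truth.  Patients are assigned latent T1D and hemophilia status
#' independently; every code in the emission table (plus a noise
#' catalogue) is drawn as an independent Bernoulli per patient per visited
#' period; CPR and autoantibody labs and the diabetologist-referral flag
#' follow class-conditional distributions.  Output is reproducible:
#' identical seed and config give identical datasets.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `claims_simulation`: list with `train` and
#'   `test` ([study_dataset()]s), `truth` (data.frame `patient_id`,
#'   `latent_t1d`, `latent_hemophilia`) and `config`.
#' @examples
#' sim <- simulate_claims(sim_config(n_patients = 500, n_noise_codes = 50))
#' sim$train
#' @export
simulate_claims <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_patients
  ids <- sprintf("P%07d", seq_len(n))
  is_t1d <- runif(n) < config$t1d_prevalence
  is_hemo <- runif(n) < config$hemophilia_prevalence
  visit <- sample(c("train_only", "both", "test_only"), n, replace = TRUE,
                  prob = config$visit_probs)
  in_train <- visit != "test_only"
  in_test <- visit == "test_only"  # test group: patients unseen in training

  age_lo <- by_class(vapply(config$age_range, `[`, 0, 1), is_t1d, is_hemo)
  age_hi <- by_class(vapply(config$age_range, `[`, 0, 2), is_t1d, is_hemo)
  age <- floor(runif(n, age_lo, age_hi + 1))
  anchor_year <- ifelse(in_train,
                        as.integer(format(config$training_window[1], "%Y")),
                        as.integer(format(config$test_window[1], "%Y")))
  patients <- data.frame(
    patient_id = ids,
    sex = ifelse(runif(n) < config$male_prob, "male", "female"),
    birth_year = anchor_year - age)

  noise <- noise_catalogue(config)
  idx_train <- which(in_train)
  idx_test <- which(in_test)

  make_ds <- function(idx, window, period) {
    study_dataset(
      patients = patients[idx, , drop = FALSE],
      events = emit_period_events(config, idx, ids, is_t1d, is_hemo, noise, window),
      labs = emit_period_labs(config, idx, ids, is_t1d, is_hemo, window),
      flags = data.frame(
        patient_id = ids[idx],
        diabetologist_referral = runif(length(idx)) <
          by_class(config$referral_prob, is_t1d[idx]),
        chart_review_verdict = "not_reviewed"),
      period = period, window = window)
  }
  train <- make_ds(idx_train, config$training_window, "training")
  test <- make_ds(idx_test, config$test_window, "test")

  structure(list(train = train, test = test,
                 truth = data.frame(patient_id = ids, latent_t1d = is_t1d,
                                    latent_hemophilia = is_hemo),
                 config = config),
            class = "claims_simulation")
}

#' @export
print.claims_simulation <- function(x, ...) {
  cat(sprintf("claims_simulation: %d patients (%d train / %d test), %d latent T1D, %d latent hemophilia\n",
              nrow(x$truth), nrow(x$train$patients), nrow(x$test$patients),
              sum(x$truth$latent_t1d), sum(x$truth$latent_hemophilia)))
  invisible(x)
}

#' Write a simulation to delimited files
#'
#' Writes `train/` and `test/` dataset directories (see [write_dataset()])
#' plus `truth.csv`.
#'
#' @param sim a [simulate_claims()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "claims_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(sim$train, file.path(dir, "train"))
  write_dataset(sim$test, file.path(dir, "test"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Exact posterior case probabilities from generator parameters
#'
#' The "perfectly calibrated scorer": for each patient in `dataset`,
#' computes the exact Bayes posterior probability of latent T1D given the
#' observed signal codes, lab tests (occurrence and values) and the
#' referral flag, using the generative parameters in `config`.  Noise
#' codes are class-independent by construction and cancel from the
#' posterior.  Because case definitions are functions of the coded events
#' alone, these posteriors are exactly calibrated for every definition,
#' which makes this scorer the reference against which the probabilistic
#' confusion matrix can be checked for parameter recovery.
#'
#' @param dataset a [study_dataset()] produced by [simulate_claims()].
#' @param config the [sim_config()] that generated it.
#' @return a `patient_scores` data.frame: `patient_id`, `p_case`,
#'   `p_not_case`.
#' @export
oracle_scores <- function(dataset, config) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(config, "sim_config"))
  ids <- dataset$patients$patient_id
  n <- length(ids)
  em <- config$emissions
  combos <- data.frame(t1d = c(FALSE, TRUE, FALSE, TRUE),
                       hemo = c(FALSE, FALSE, TRUE, TRUE))
  log_prior <- log(ifelse(combos$t1d, config$t1d_prevalence, 1 - config$t1d_prevalence)) +
    log(ifelse(combos$hemo, config$hemophilia_prevalence, 1 - config$hemophilia_prevalence))

  # presence matrix over signal codes
  key_em <- paste(em$system, em$code)
  ev_key <- paste(dataset$events$system, dataset$events$code)
  sig <- ev_key %in% key_em
  X <- matrix(0, n, nrow(em))
  if (any(sig)) {
    ridx <- match(dataset$events$patient_id[sig], ids)
    cidx <- match(ev_key[sig], key_em)
    X[cbind(ridx, cidx)] <- 1
  }

  ll <- matrix(0, n, 4L)
  for (k in 1:4) {
    p <- effective_prob_vec(em, combos$t1d[k], combos$hemo[k])
    ll[, k] <- X %*% (log(p) - log1p(-p)) + sum(log1p(-p))
  }

  # lab occurrence + values
  lab_tab <- dataset$labs
  has <- function(test) ids %in% lab_tab$patient_id[lab_tab$test == test]
  test_ll <- function(tested, p_bg, p_t1d, p_hemo = NULL) {
    for (k in 1:4) {
      p <- if (combos$t1d[k]) p_t1d
           else if (combos$hemo[k] && !is.null(p_hemo)) p_hemo
           else p_bg
      ll[, k] <<- ll[, k] + ifelse(tested, log(p), log1p(-p))
    }
  }
  pk <- function(param, cls) if (cls %in% names(param)) param[[cls]] else NULL
  cpr_tested <- has("serum_cpr")
  test_ll(cpr_tested, config$labs$cpr$test_prob[["background"]],
          config$labs$cpr$test_prob[["t1d"]],
          pk(config$labs$cpr$test_prob, "hemophilia"))
  # CPR value density depends on latent T1D only
  cpr <- lab_tab[lab_tab$test == "serum_cpr", ]
  if (nrow(cpr)) {
    dens <- function(cls) {
      d <- stats::dlnorm(cpr$value, config$labs$cpr$meanlog[[cls]],
                         config$labs$cpr$sdlog[[cls]], log = TRUE)
      v <- rep(0, n)
      agg <- tapply(d, match(cpr$patient_id, ids), sum)
      v[as.integer(names(agg))] <- agg
      v
    }
    d_bg <- dens("background"); d_t1d <- dens("t1d")
    for (k in 1:4) ll[, k] <- ll[, k] + if (combos$t1d[k]) d_t1d else d_bg
  }
  for (ab in c("gad", "ia2")) {
    test_name <- paste0(ab, "_antibody")
    tested <- has(test_name)
    test_ll(tested, config$labs[[ab]]$test_prob[["background"]],
            config$labs[[ab]]$test_prob[["t1d"]])
    rows <- lab_tab[lab_tab$test == test_name, ]
    if (nrow(rows)) {
      for (k in 1:4) {
        cls <- if (combos$t1d[k]) "t1d" else "background"
        p <- config$labs[[ab]]$pos_prob[[cls]]
        d <- ifelse(rows$value == 1, log(p), log1p(-p))
        agg <- tapply(d, match(rows$patient_id, ids), sum)
        ll[as.integer(names(agg)), k] <- ll[as.integer(names(agg)), k] + agg
      }
    }
  }
  ref <- dataset$flags$diabetologist_referral[match(ids, dataset$flags$patient_id)]
  ref[is.na(ref)] <- FALSE
  test_ll(ref, config$referral_prob[["background"]], config$referral_prob[["t1d"]])

  lp <- sweep(ll, 2L, log_prior, `+`)
  m <- apply(lp, 1L, max)
  w <- exp(lp - m)
  p_case <- rowSums(w[, combos$t1d, drop = FALSE]) / rowSums(w)
  patient_scores(ids, p_case)
}

effective_prob_vec <- function(em, t1d, hemo) {
  p <- em$p_background
  if (hemo) p <- ifelse(is.na(em$p_hemophilia), p, em$p_hemophilia)
  if (t1d) p <- ifelse(is.na(em$p_t1d), p, em$p_t1d)
  p
}

#' Construct a patient-score table
#'
#' @param patient_id character ids.
#' @param p_case predicted probabilities of being a true case.
#' @return `patient_scores` data.frame with `p_case` and its complement.
#' @export
patient_scores <- function(patient_id, p_case) {
  stopifnot(length(patient_id) == length(p_case),
            all(p_case >= 0 & p_case <= 1))
  structure(data.frame(patient_id = as.character(patient_id),
                       p_case = as.numeric(p_case),
                       p_not_case = 1 - as.numeric(p_case)),
            class = c("patient_scores", "data.frame"))
}

#' Classical performance of a definition against latent truth
#'
#' The simulation oracle: evaluates a case definition with the ordinary
#' 2x2 confusion matrix against the generator's latent T1D status.  Used
#' to verify that the probabilistic estimator recovers the true operating
#' characteristics.
#'
#' @param definition a [case_definition()].
#' @param dataset a [study_dataset()].
#' @param truth ground-truth data.frame (`patient_id`, `latent_t1d`).
#' @return list of class `classical_performance`: counts `tp`, `fp`, `fn`,
#'   `tn` and proportions `sensitivity`, `ppv` (`ppv` is `NA` with
#'   `undefined = "ppv"` noted when the definition matches nobody).
#' @export
true_definition_performance <- function(definition, dataset, truth) {
  ids <- dataset$patients$patient_id
  miss <- setdiff(ids, truth$patient_id)
  if (length(miss)) {
    stop("referential error: ", length(miss),
         " dataset patient(s) missing from truth", call. = FALSE)
  }
  pos <- ids %in% definition_positives(definition, dataset)
  t1d <- truth$latent_t1d[match(ids, truth$patient_id)]
  tp <- sum(pos & t1d); fp <- sum(pos & !t1d)
  fn <- sum(!pos & t1d); tn <- sum(!pos & !t1d)
  res <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
              undefined = c(if (tp + fn == 0) "sensitivity",
                            if (tp + fp == 0) "ppv"))
  class(res) <- "classical_performance"
  res
}
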