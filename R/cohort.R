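#' Code sets used by cohort construction
#'
#' The configurable code sets behind the gold-standard cohort rules:
#' confirmed diagnosis prefixes identifying the phenotype (T1D /
#' insulin-dependent diabetes), the type 2 diabetes prefix used for case
#' exclusion, the ketoacidosis diagnosis prefix, the insulin medication
#' pattern, pancreas-transplant procedure codes, and the two serum-CPR
#' screening thresholds in ng/ml (strict `<`, as printed on lab criteria).
#'
#' @param t1d_confirmed_prefixes confirmed ICD-10 prefixes counted as a
#'   T1D / insulin-dependent-diabetes diagnosis.
#' @param t2d_prefix 3-digit ICD-10 prefix excluded as type 2 diabetes
#'   (confirmed or suspected).
#' @param ketoacidosis_prefixes confirmed ICD-10 prefixes counted as a
#'   ketoacidosis diagnosis.
#' @param insulin_med_pattern regular expression matching insulin
#'   medication codes.
#' @param transplant_codes pancreas-transplant procedure codes.
#' @param cpr_threshold_screen,cpr_threshold_definite CPR thresholds for
#'   screening criteria 2 and 5.
#' @return named list, class `cohort_codes`.
#' @export
cohort_codes <- function(t1d_confirmed_prefixes = "E10",
                         t2d_prefix = "E11",
                         ketoacidosis_prefixes = "E87",
                         insulin_med_pattern = "^insulin",
                         transplant_codes = claim_code_registry()$pancreas_transplant,
                         cpr_threshold_screen = 0.6,
                         cpr_threshold_definite = 0.2) {
  structure(list(t1d_confirmed_prefixes = t1d_confirmed_prefixes,
                 t2d_prefix = t2d_prefix,
                 ketoacidosis_prefixes = ketoacidosis_prefixes,
                 insulin_med_pattern = insulin_med_pattern,
                 transplant_codes = transplant_codes,
                 cpr_threshold_screen = cpr_threshold_screen,
                 cpr_threshold_definite = cpr_threshold_definite),
            class = "cohort_codes")
}

has_prefix_code <- function(events, systems, prefixes) {
  sel <- events$system %in% systems &
    Reduce(`|`, lapply(prefixes, function(p) startsWith(events$code, p)))
  unique(events$patient_id[sel])
}

#' Screen possible cases by the five clinical criteria
#'
#' Flags every patient matching at least one of:
#' \describe{
#'   \item{c1}{confirmed diagnosis of T1D / insulin-dependent diabetes
#'     (configurable prefix set, default E10);}
#'   \item{c2}{insulin medication prescribed AND minimum serum CPR
#'     < 0.6 ng/ml AND a ketoacidosis diagnosis;}
#'   \item{c3}{GAD or IA-2 autoantibody positive;}
#'   \item{c4}{introduced as definite T1D by a diabetologist (referral
#'     flag);}
#'   \item{c5}{minimum serum CPR < 0.2 ng/ml.}
#' }
#' Both CPR thresholds are strict (`<`).  Screening is monotone: adding
#' events or labs can only add criteria.
#'
#' @param dataset a [study_dataset()].
#' @param codes a [cohort_codes()] configuration.
#' @return data.frame `patient_id`, logical `c1`..`c5`, and
#'   `matched_criteria` (e.g. `"c1+c5"`); one row per patient matching at
#'   least one criterion.
#' @export
screen_possible_cases <- function(dataset, codes = cohort_codes()) {
  stopifnot(inherits(dataset, "study_dataset"))
  ids <- dataset$patients$patient_id
  ev <- dataset$events
  labs <- dataset$labs

  c1_ids <- has_prefix_code(ev, "icd10_confirmed", codes$t1d_confirmed_prefixes)

  cpr <- labs[labs$test == "serum_cpr", ]
  min_cpr <- tapply(cpr$value, cpr$patient_id, min)
  low_cpr_ids <- names(min_cpr)[min_cpr < codes$cpr_threshold_screen]
  insulin_ids <- unique(ev$patient_id[ev$system == "medication" &
                                        grepl(codes$insulin_med_pattern, ev$code)])
  keto_ids <- has_prefix_code(ev, "icd10_confirmed", codes$ketoacidosis_prefixes)
  c2_ids <- intersect(intersect(insulin_ids, low_cpr_ids), keto_ids)

  ab <- labs[labs$test %in% c("gad_antibody", "ia2_antibody"), ]
  c3_ids <- unique(ab$patient_id[ab$value == 1])

  fl <- dataset$flags
  c4_ids <- fl$patient_id[fl$diabetologist_referral %in% TRUE]

  c5_ids <- names(min_cpr)[min_cpr < codes$cpr_threshold_definite]

  res <- data.frame(patient_id = ids,
                    c1 = ids %in% c1_ids, c2 = ids %in% c2_ids,
                    c3 = ids %in% c3_ids, c4 = ids %in% c4_ids,
                    c5 = ids %in% c5_ids)
  res <- res[res$c1 | res$c2 | res$c3 | res$c4 | res$c5, , drop = FALSE]
  crit <- c("c1", "c2", "c3", "c4", "c5")
  res$matched_criteria <- apply(res[, crit], 1L, function(z)
    paste(crit[z], collapse = "+"))
  rownames(res) <- NULL
  res
}

#' Adjudicate possible cases against a truth source
#'
#' Stands in for the diabetologists' medical chart review.  Verdicts equal
#' the truth source, optionally flipped with probability `error_rate`
#' (independent Bernoulli per patient, deterministic given `seed`).
#'
#' @param possible_ids patient ids screened as possible cases.
#' @param truth either a ground-truth data.frame (`patient_id`,
#'   `latent_t1d`) or a flags table carrying `chart_review_verdict`
#'   different from `"not_reviewed"`.
#' @param error_rate probability a verdict contradicts the truth source.
#' @param seed integer seed for the error draws.
#' @return data.frame `patient_id`, `verdict` (`true_t1d` / `not_t1d`).
#' @export
adjudicate <- function(possible_ids, truth, error_rate = 0, seed = 1L) {
  possible_ids <- as.character(possible_ids)
  if ("latent_t1d" %in% names(truth)) {
    idx <- match(possible_ids, truth$patient_id)
    if (anyNA(idx)) {
      stop("referential error: possible case(s) missing from truth: ",
           paste(utils::head(possible_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    is_case <- as.logical(truth$latent_t1d[idx])
  } else if ("chart_review_verdict" %in% names(truth)) {
    idx <- match(possible_ids, truth$patient_id)
    v <- truth$chart_review_verdict[idx]
    if (anyNA(v) || any(v == "not_reviewed")) {
      stop("referential error: possible case(s) without a chart verdict",
           call. = FALSE)
    }
    is_case <- v == "true_t1d"
  } else {
    stop("truth must carry latent_t1d or chart_review_verdict", call. = FALSE)
  }
  if (error_rate > 0) {
    set.seed(seed)
    flip <- runif(length(possible_ids)) < error_rate
    is_case <- xor(is_case, flip)
  }
  data.frame(patient_id = possible_ids,
             verdict = ifelse(is_case, "true_t1d", "not_t1d"))
}

#' Build the case set with clinical exclusions
#'
#' Starts from adjudicated true cases and excludes (a) patients with a
#' pancreas-transplant procedure code (their insulin secretion is restored)
#' and (b) patients carrying a confirmed or suspected type 2 diabetes code.
#'
#' @param verdicts output of [adjudicate()].
#' @param dataset the [study_dataset()] the verdicts refer to.
#' @param codes a [cohort_codes()].
#' @return data.frame `patient_id`, `status` (`case` / `excluded_case`),
#'   `exclusion_reason` (`transplant`, `t2d`, or `NA`).
#' @export
build_cases <- function(verdicts, dataset, codes = cohort_codes()) {
  true_ids <- verdicts$patient_id[verdicts$verdict == "true_t1d"]
  ev <- dataset$events
  transplant_ids <- unique(ev$patient_id[ev$system == "procedure" &
                                           ev$code %in% codes$transplant_codes])
  t2d_ids <- has_prefix_code(ev, c("icd10_confirmed", "icd10_suspected"),
                             codes$t2d_prefix)
  reason <- rep(NA_character_, length(true_ids))
  reason[true_ids %in% t2d_ids] <- "t2d"
  reason[true_ids %in% transplant_ids] <- "transplant"  # transplant reported first
  data.frame(patient_id = true_ids,
             status = ifelse(is.na(reason), "case", "excluded_case"),
             exclusion_reason = reason)
}

#' Sample controls from the unreviewed population
#'
#' Controls are drawn from patients whose charts were never reviewed and
#' who carry no confirmed or suspected T1D code, by simple random sampling
#' without replacement down to `ratio` controls per case (pool-limited).
#'
#' @param dataset a [study_dataset()].
#' @param reviewed_ids patients whose charts were reviewed (all screened
#'   possible cases).
#' @param n_cases number of final cases (sets the target sample size).
#' @param ratio target control:case ratio.
#' @param seed integer seed.
#' @param codes a [cohort_codes()].
#' @return character vector of control patient ids.
#' @export
sample_controls <- function(dataset, reviewed_ids, n_cases, ratio = 233,
                            seed = 1L, codes = cohort_codes()) {
  stopifnot(ratio > 0)
  ev <- dataset$events
  t1d_any <- has_prefix_code(ev, c("icd10_confirmed", "icd10_suspected"),
                             codes$t1d_confirmed_prefixes)
  pool <- setdiff(dataset$patients$patient_id, union(reviewed_ids, t1d_any))
  if (length(pool) == 0L) {
    stop("cohort error: control pool is empty", call. = FALSE)
  }
  n_target <- min(length(pool), round(ratio * n_cases))
  set.seed(seed)
  sort(sample(pool, n_target))
}

#' Build the labeled gold-standard cohort
#'
#' Runs screening, adjudication, case exclusions and control sampling on a
#' training-period dataset, producing the labeled cohort the phenotype
#' model is trained on.
#'
#' @param dataset training-period [study_dataset()].
#' @param truth truth source for [adjudicate()] (ground truth table or
#'   chart-flag table).
#' @param ratio control:case ratio (default 233, the labeled-cohort ratio
#'   this design targets).
#' @param error_rate adjudication error probability.
#' @param seed integer seed (adjudication and control sampling).
#' @param codes a [cohort_codes()].
#' @return data.frame of class `gold_cohort`: `patient_id`, `status`
#'   (`case`, `control`, `excluded_case`), `matched_criteria`,
#'   `exclusion_reason`.
#' @export
build_cohort <- function(dataset, truth, ratio = 233, error_rate = 0,
                         seed = 1L, codes = cohort_codes()) {
  screened <- screen_possible_cases(dataset, codes)
  verdicts <- adjudicate(screened$patient_id, truth, error_rate, seed)
  cases <- build_cases(verdicts, dataset, codes)
  case_ids <- cases$patient_id[cases$status == "case"]
  controls <- sample_controls(dataset, reviewed_ids = screened$patient_id,
                              n_cases = length(case_ids), ratio = ratio,
                              seed = seed + 1L, codes = codes)
  out <- rbind(
    data.frame(patient_id = cases$patient_id, status = cases$status,
               exclusion_reason = cases$exclusion_reason),
    data.frame(patient_id = controls, status = "control",
               exclusion_reason = NA_character_))
  out$matched_criteria <- screened$matched_criteria[
    match(out$patient_id, screened$patient_id)]
  out <- out[, c("patient_id", "status", "matched_criteria", "exclusion_reason")]
  class(out) <- c("gold_cohort", "data.frame")
  out
}

#' @export
print.gold_cohort <- function(x, ...) {
  tab <- table(x$status)
  cat("gold-standard cohort:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}
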