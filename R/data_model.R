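#' phenoval: probabilistic validation of claims-code case definitions
#'
#' Validates boolean case definitions over claims codes against a
#' probabilistic gold standard: a trained phenotype model's predicted case
#' probabilities replace exhaustive chart review, so sensitivity can be
#' estimated as well as PPV.  The package covers the whole workflow:
#' synthetic claims/EHR generation with known latent disease status,
#' rule-based screening and adjudication of a gold-standard cohort,
#' relative-risk feature screening, a gradient-boosted phenotype model,
#' a case-definition engine, and the probabilistic confusion matrix with
#' bootstrap confidence intervals.
#'
#' @importFrom stats predict quantile rbinom rlnorm runif rmultinom
#'   dlnorm setNames lm coef
#' @importFrom utils read.csv write.csv head glob2rx
#' @importFrom graphics barplot par abline
#' @keywords internal
"_PACKAGE"

EVENT_SYSTEMS <- c("icd10_confirmed", "icd10_suspected", "medication", "procedure")
LAB_TESTS <- c("serum_cpr", "gad_antibody", "ia2_antibody")
VERDICTS <- c("true_t1d", "not_t1d", "not_reviewed")
ICD10_PATTERN <- "^[A-Z][0-9]{2,}$"

#' Assemble a validated study dataset
#'
#' Bundles the four long-format tables every downstream stage consumes:
#' patient demographics, dated coded events (confirmed/suspected diagnoses,
#' medications, procedures), lab results (serum C-peptide immunoreactivity
#' and islet autoantibodies) and chart flags.  All referential and value
#' invariants are checked on construction.
#'
#' @param patients data.frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `birth_year` (integer year).
#' @param events data.frame with columns `patient_id`, `date` (`Date` or
#'   ISO-8601 string), `system` (one of `icd10_confirmed`, `icd10_suspected`,
#'   `medication`, `procedure`) and `code`.
#' @param labs data.frame with columns `patient_id`, `date`, `test` (one of
#'   `serum_cpr`, `gad_antibody`, `ia2_antibody`) and `value` (ng/ml for
#'   CPR; 0/1 positivity for antibodies).
#' @param flags data.frame with columns `patient_id`,
#'   `diabetologist_referral` (logical) and `chart_review_verdict`
#'   (`true_t1d`, `not_t1d`, `not_reviewed`).
#' @param period optional label, `"training"` or `"test"`.
#' @param window optional `Date` vector of length 2, the half-open
#'   observation window `[start, end)` the events were drawn from.
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `patients`, `events`, `labs`, `flags`, `period`, `window`.
#' @export
study_dataset <- function(patients, events = NULL, labs = NULL, flags = NULL,
                          period = NA_character_, window = NULL) {
  events <- if (is.null(events)) empty_events() else events
  labs <- if (is.null(labs)) empty_labs() else labs
  flags <- if (is.null(flags)) empty_flags() else flags
  events$date <- as.Date(events$date)
  labs$date <- as.Date(labs$date)
  if (is.character(flags$diabetologist_referral)) {
    flags$diabetologist_referral <- as.logical(toupper(flags$diabetologist_referral))
  }
  ds <- structure(
    list(patients = patients, events = events, labs = labs, flags = flags,
         period = period, window = window),
    class = "study_dataset")
  validate_dataset(ds)
  ds
}

empty_events <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             system = character(), code = character())
}
empty_labs <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             test = character(), value = numeric())
}
empty_flags <- function() {
  data.frame(patient_id = character(), diabetologist_referral = logical(),
             chart_review_verdict = character())
}

fail_rows <- function(what, rows, detail) {
  rows <- utils::head(rows, 5L)
  stop(sprintf("%s (rows %s): %s", what, paste(rows, collapse = ", "), detail),
       call. = FALSE)
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error: table '%s' lacks column(s) %s", table,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a study dataset's invariants
#'
#' Checks schema, enumerations, ICD-10 code shape, value ranges and
#' referential integrity.  Errors name the offending rows.
#'
#' @param ds a [study_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  require_columns(ds$patients, c("patient_id", "sex", "birth_year"), "patients")
  require_columns(ds$events, c("patient_id", "date", "system", "code"), "events")
  require_columns(ds$labs, c("patient_id", "date", "test", "value"), "labs")
  require_columns(ds$flags,
                  c("patient_id", "diabetologist_referral", "chart_review_verdict"),
                  "flags")

  if (anyDuplicated(ds$patients$patient_id)) {
    fail_rows("duplicate patient_id",
              which(duplicated(ds$patients$patient_id)),
              "patient_id must be unique")
  }
  bad <- which(!ds$patients$sex %in% c("male", "female"))
  if (length(bad)) fail_rows("parse error in patients$sex", bad, "must be male/female")

  bad <- which(!ds$events$system %in% EVENT_SYSTEMS)
  if (length(bad)) {
    fail_rows("parse error in events$system", bad,
              sprintf("got %s; expected one of %s",
                      paste(unique(ds$events$system[bad]), collapse = "/"),
                      paste(EVENT_SYSTEMS, collapse = "/")))
  }
  icd <- ds$events$system %in% c("icd10_confirmed", "icd10_suspected")
  bad <- which(icd & !grepl(ICD10_PATTERN, ds$events$code))
  if (length(bad)) {
    fail_rows("parse error in events$code", bad,
              "ICD-10 codes must match letter + >=2 digits")
  }
  bad <- which(is.na(ds$events$date))
  if (length(bad)) fail_rows("parse error in events$date", bad, "unparseable date")

  bad <- which(!ds$labs$test %in% LAB_TESTS)
  if (length(bad)) {
    fail_rows("parse error in labs$test", bad,
              paste("expected one of", paste(LAB_TESTS, collapse = "/")))
  }
  cpr <- ds$labs$test == "serum_cpr"
  bad <- which(cpr & (is.na(ds$labs$value) | ds$labs$value < 0))
  if (length(bad)) fail_rows("invalid serum_cpr value", bad, "must be >= 0 ng/ml")
  bad <- which(!cpr & !ds$labs$value %in% c(0, 1))
  if (length(bad)) fail_rows("invalid antibody value", bad, "must be 0 or 1")

  bad <- which(!ds$flags$chart_review_verdict %in% VERDICTS)
  if (length(bad)) {
    fail_rows("parse error in flags$chart_review_verdict", bad,
              paste("expected one of", paste(VERDICTS, collapse = "/")))
  }

  ids <- ds$patients$patient_id
  for (tab in c("events", "labs", "flags")) {
    bad <- which(!ds[[tab]]$patient_id %in% ids)
    if (length(bad)) {
      fail_rows(sprintf("referential error in %s", tab), bad,
                "patient_id absent from patients table")
    }
  }

  # birth_year must not postdate any event
  if (nrow(ds$events)) {
    by <- ds$patients$birth_year[match(ds$events$patient_id, ids)]
    bad <- which(as.integer(format(ds$events$date, "%Y")) < by)
    if (length(bad)) {
      fail_rows("invalid birth_year", bad, "event predates patient's birth year")
    }
  }
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset (%s period)\n",
              if (is.na(x$period)) "unspecified" else x$period))
  if (!is.null(x$window)) {
    cat(sprintf("  window: [%s, %s)\n", x$window[1], x$window[2]))
  }
  cat(sprintf("  patients: %d  events: %d  labs: %d  flags: %d\n",
              nrow(x$patients), nrow(x$events), nrow(x$labs), nrow(x$flags)))
  invisible(x)
}

#' Read a study dataset from delimited files
#'
#' Reads the four comma-delimited UTF-8 tables (`patients.csv`,
#' `events.csv`, `labs.csv`, `flags.csv`; header row required, one record
#' per row) and validates all invariants.
#'
#' @param dir directory containing the four files.
#' @param period,window passed to [study_dataset()].
#' @return a [study_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(dir, period = NA_character_, window = NULL) {
  paths <- file.path(dir, c("patients.csv", "events.csv", "labs.csv", "flags.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = c(patient_id = "character"))
  study_dataset(patients = rd(paths[1]), events = rd(paths[2]),
                labs = rd(paths[3]), flags = rd(paths[4]),
                period = period, window = window)
}

#' Write a study dataset to delimited files
#'
#' Inverse of [read_dataset()]; column order is fixed so that a read/write
#' round trip reproduces the body rows byte for byte.
#'
#' @param ds a [study_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, cols, name) {
    df <- df[, cols, drop = FALSE]
    if ("date" %in% cols) df$date <- format(df$date, "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(ds$patients, c("patient_id", "sex", "birth_year"), "patients.csv")
  wr(ds$events, c("patient_id", "date", "system", "code"), "events.csv")
  wr(ds$labs, c("patient_id", "date", "test", "value"), "labs.csv")
  wr(ds$flags, c("patient_id", "diabetologist_referral", "chart_review_verdict"),
     "flags.csv")
  invisible(dir)
}

#' Split a dataset into disjoint training and test populations
#'
#' Training patients are those with at least one event in the training
#' window; the test group contains only patients never seen in the training
#' window (and with at least one event in the test window), so the two
#' patient-id sets are disjoint by construction.  Patients visiting in both
#' windows contribute to the training set only.  Windows are half-open
#' `[start, end)`.
#'
#' @param ds a [study_dataset()] spanning both windows.
#' @param training_window,test_window `Date` vectors of length 2; defaults
#'   are calendar blocks 2009-2014 and 2015-2019.
#' @return list with elements `train` and `test`, each a [study_dataset()]
#'   restricted to its window and population.
#' @export
split_by_period <- function(ds,
                            training_window = as.Date(c("2009-01-01", "2015-01-01")),
                            test_window = as.Date(c("2015-01-01", "2020-01-01"))) {
  stopifnot(inherits(ds, "study_dataset"))
  training_window <- as.Date(training_window)
  test_window <- as.Date(test_window)
  if (max(training_window[1], test_window[1]) <
      min(training_window[2], test_window[2])) {
    stop("configuration error: training and test windows overlap", call. = FALSE)
  }
  in_win <- function(d, w) d >= w[1] & d < w[2]
  ev_train <- in_win(ds$events$date, training_window)
  ev_test <- in_win(ds$events$date, test_window)
  train_ids <- unique(ds$events$patient_id[ev_train])
  test_ids <- setdiff(unique(ds$events$patient_id[ev_test]), train_ids)

  subset_ds <- function(ids, ev_keep, win, period) {
    keep_ev <- ev_keep & ds$events$patient_id %in% ids
    keep_lab <- ds$labs$patient_id %in% ids & in_win(ds$labs$date, win)
    study_dataset(
      patients = ds$patients[ds$patients$patient_id %in% ids, , drop = FALSE],
      events = ds$events[keep_ev, , drop = FALSE],
      labs = ds$labs[keep_lab, , drop = FALSE],
      flags = ds$flags[ds$flags$patient_id %in% ids, , drop = FALSE],
      period = period, window = win)
  }
  list(train = subset_ds(train_ids, ev_train, training_window, "training"),
       test = subset_ds(test_ids, ev_test, test_window, "test"))
}
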