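#' Truncate ICD-10 codes to their 3-character category
#'
#' @param code character vector of ICD-10 codes (letter + at least two
#'   digits).
#' @return the first three characters of each code.
#' @examples
#' truncate_icd10(c("E101", "F50"))
#' @export
truncate_icd10 <- function(code) {
  bad <- !grepl(ICD10_PATTERN, code)
  if (any(bad)) {
    stop("parse error: malformed ICD-10 code(s): ",
         paste(utils::head(code[bad], 5), collapse = ", "), call. = FALSE)
  }
  substr(code, 1L, 3L)
}

#' Default leakage list
#'
#' Feature patterns that must never enter the phenotype model because they
#' were used to assemble the gold standard: confirmed T1D, T2D and
#' ketoacidosis diagnoses; suspected diagnoses related to T1D/T2D; the CPR
#' and insulin-receptor-autoantibody test claims; and all insulin
#' medications.  Patterns are globs over namespaced feature names.
#'
#' @return character vector of glob patterns.
#' @export
default_leakage <- function() {
  reg <- claim_code_registry()
  c("confirmed:E10", "confirmed:E11", "confirmed:E87",
    "suspected:E10", "suspected:E11", "suspected:E13", "suspected:E14",
    paste0("proc:", reg$cpr_test),
    paste0("proc:", reg$insulin_receptor_ab_test),
    "med:insulin*")
}

leakage_matches <- function(feature_names, leakage) {
  if (length(leakage) == 0L) return(rep(FALSE, length(feature_names)))
  rx <- paste(vapply(leakage, utils::glob2rx, ""), collapse = "|")
  grepl(rx, feature_names)
}

FEATURE_PREFIX <- c(icd10_confirmed = "confirmed", icd10_suspected = "suspected",
                    medication = "med", procedure = "proc")

#' Build the binary patient-by-feature matrix
#'
#' One 0/1 column per observed (namespace, code) pair — presence of at
#' least one matching event during the period, never a count.  Diagnosis
#' codes are truncated to 3 characters; medication codes are mapped to
#' generic names (codes absent from the map are used verbatim with a
#' warning); leakage features are dropped.  `age` (window-start year minus
#' birth year) and `sex` (1 = male) columns are appended.  Column order is
#' deterministic: lexicographic within namespace (confirmed, suspected,
#' med, proc), then `age`, `sex`.
#'
#' @param dataset a [study_dataset()].
#' @param leakage glob patterns of features to exclude
#'   ([default_leakage()]).
#' @param generic_map optional data.frame (`code`, `generic`) mapping
#'   medication claim codes to generic names.
#' @return sparse `dgCMatrix` (patients x features) with patient ids as
#'   rownames.
#' @export
build_features <- function(dataset, leakage = default_leakage(),
                           generic_map = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  ids <- dataset$patients$patient_id
  ev <- dataset$events
  code <- ev$code
  icd <- ev$system %in% c("icd10_confirmed", "icd10_suspected")
  code[icd] <- truncate_icd10(code[icd])
  med <- ev$system == "medication"
  if (any(med) && !is.null(generic_map)) {
    m <- match(code[med], generic_map$code)
    unmapped <- unique(code[med][is.na(m)])
    if (length(unmapped)) {
      warning("medication code(s) missing from generic map, used verbatim: ",
              paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
    }
    code[med][!is.na(m)] <- generic_map$generic[m[!is.na(m)]]
  }
  fname <- if (nrow(ev)) paste0(FEATURE_PREFIX[ev$system], ":", code) else character(0)
  keep <- !leakage_matches(fname, leakage)

  # deterministic column order: namespace blocks, lexicographic inside
  uniq <- unique(fname[keep])
  ns <- sub(":.*$", "", uniq)
  ord <- order(match(ns, c("confirmed", "suspected", "med", "proc")), uniq,
               method = "radix")
  cols <- uniq[ord]

  i <- match(ev$patient_id[keep], ids)
  X <- Matrix::sparseMatrix(
    i = i, j = match(fname[keep], cols), x = rep(1, length(i)),
    dims = c(length(ids), length(cols)), dimnames = list(ids, cols))
  X@x[] <- 1  # presence, not count (duplicate events collapse)

  ref_year <- if (!is.null(dataset$window)) {
    as.integer(format(dataset$window[1], "%Y"))
  } else if (nrow(ev)) {
    min(as.integer(format(ev$date, "%Y")))
  } else {
    NA_integer_
  }
  age <- ref_year - dataset$patients$birth_year
  sex <- as.numeric(dataset$patients$sex == "male")
  cbind(X, Matrix::Matrix(cbind(age = age, sex = sex), sparse = TRUE))
}

#' Relative risk of case status given a binary feature
#'
#' `RR = P(case | feature) / P(case | no feature)` from the 2x2 table.  A
#' 0.5 continuity correction is added to all four cells whenever any cell
#' is zero (so features present or absent in everyone get a finite RR
#' of 1).
#'
#' @param feature 0/1 vector.
#' @param labels 0/1 case indicator, same length.
#' @return non-negative scalar.
#' @export
relative_risk <- function(feature, labels) {
  feature <- as.numeric(feature); labels <- as.numeric(labels)
  if (!all(feature %in% c(0, 1)) || !all(labels %in% c(0, 1))) {
    stop("type error: feature and labels must be binary 0/1", call. = FALSE)
  }
  a <- sum(feature == 1 & labels == 1); b <- sum(feature == 1 & labels == 0)
  c_ <- sum(feature == 0 & labels == 1); d <- sum(feature == 0 & labels == 0)
  rr_from_cells(a, b, c_, d)
}

rr_from_cells <- function(a, b, c_, d) {
  eps <- ifelse(a == 0 | b == 0 | c_ == 0 | d == 0, 0.5, 0)
  rr <- ((a + eps) / (a + b + 2 * eps)) / ((c_ + eps) / (c_ + d + 2 * eps))
  # a constant feature (an empty exposed or unexposed arm) carries no
  # discrimination: define RR = 1 rather than a prior-dependent value
  ifelse(a + b == 0 | c_ + d == 0, 1, rr)
}

#' Relative risks for every coded feature of a matrix
#'
#' Vectorized [relative_risk()] over the columns of a feature matrix
#' (`age` and `sex` columns are skipped — they bypass screening).
#'
#' @param x feature matrix from [build_features()].
#' @param labels 0/1 case indicator aligned with `x`'s rows.
#' @return named numeric vector of RRs.
#' @export
feature_relative_risks <- function(x, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == nrow(x), all(labels %in% c(0, 1)))
  coded <- setdiff(colnames(x), c("age", "sex"))
  xm <- x[, coded, drop = FALSE]
  n1 <- sum(labels); n0 <- sum(1 - labels)
  a <- as.numeric(Matrix::crossprod(xm, labels))
  b <- as.numeric(Matrix::colSums(xm)) - a
  setNames(rr_from_cells(a, b, n1 - a, n0 - b), coded)
}

#' Select the top-k features by relative risk
#'
#' Features are ranked by RR descending, ties broken lexicographically by
#' name; the first `min(k, available)` are returned.  Protective features
#' (RR < 1) simply rank low; no absolute-value ranking is applied.
#'
#' @param rr named RR vector from [feature_relative_risks()].
#' @param k number of features to keep (default 500).
#' @return character vector of selected feature names, in rank order.
#' @export
select_top_k <- function(rr, k = 500) {
  stopifnot(k >= 1)
  ord <- order(-rr, names(rr), method = "radix")
  names(rr)[ord][seq_len(min(k, length(rr)))]
}

#' Screen a feature matrix down to the top-k columns by RR
#'
#' Convenience wrapper: ranks coded features by [feature_relative_risks()],
#' keeps the top `k` via [select_top_k()], and always retains `age` and
#' `sex` outside the k budget.  Asserts post-selection that no retained
#' feature matches the leakage list.
#'
#' @inheritParams feature_relative_risks
#' @param k top-k cut (default 500).
#' @param leakage glob patterns that must not survive selection.
#' @return the column-subset feature matrix, with the RR ranking attached
#'   as attribute `"rr"`.
#' @export
screen_features <- function(x, labels, k = 500, leakage = default_leakage()) {
  rr <- feature_relative_risks(x, labels)
  sel <- select_top_k(rr, k)
  leaked <- sel[leakage_matches(sel, leakage)]
  if (length(leaked)) {
    stop("leakage violation: selected feature(s) match the leakage list: ",
         paste(utils::head(leaked, 5), collapse = ", "), call. = FALSE)
  }
  out <- x[, c(sel, intersect(c("age", "sex"), colnames(x))), drop = FALSE]
  attr(out, "rr") <- rr[sel]
  out
}
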