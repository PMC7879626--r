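#' Code predicate
#'
#' A leaf of a case-definition expression: true for a patient iff they
#' have at least one event of the given system whose code matches one of
#' `codes` (exactly, or by prefix).
#'
#' @param system one of `icd10_confirmed`, `icd10_suspected`,
#'   `medication`, `procedure`.
#' @param codes non-empty character vector of codes (or prefixes).
#' @param match `"exact"` or `"prefix"` (prefix uses truncation-free
#'   `startsWith`).
#' @return object of class `code_predicate`.
#' @export
code_predicate <- function(system, codes, match = c("exact", "prefix")) {
  match <- match.arg(match)
  stopifnot(system %in% EVENT_SYSTEMS, length(codes) >= 1L)
  structure(list(system = system, codes = as.character(codes), match = match),
            class = "code_predicate")
}

#' Boolean case definition over claims codes
#'
#' An AND/OR expression tree whose leaves are [code_predicate()]s
#' (negation is deliberately unsupported: real-world claims definitions
#' are monotone).  Build trees with [def_all()] and [def_any()].
#'
#' @param name display name.
#' @param expr a [code_predicate()] or a combinator node.
#' @return object of class `case_definition`.
#' @export
case_definition <- function(name, expr) {
  check_expr(expr)
  structure(list(name = name, expr = expr), class = "case_definition")
}

check_expr <- function(expr) {
  if (inherits(expr, "code_predicate")) return(invisible(TRUE))
  if (is.list(expr) && !is.null(expr$op) && expr$op %in% c("and", "or") &&
      length(expr$args) >= 1L) {
    for (a in expr$args) check_expr(a)
    return(invisible(TRUE))
  }
  stop("invalid definition expression: every node must be a code_predicate ",
       "or an and/or combinator with >=1 argument", call. = FALSE)
}

#' @rdname case_definition
#' @param ... child expressions.
#' @export
def_all <- function(...) list(op = "and", args = list(...))

#' @rdname case_definition
#' @export
def_any <- function(...) list(op = "or", args = list(...))

#' @export
print.case_definition <- function(x, ...) {
  cat("case_definition:", x$name, "\n  ", deparse_expr(x$expr), "\n")
  invisible(x)
}

deparse_expr <- function(expr) {
  if (inherits(expr, "code_predicate")) {
    return(sprintf("%s[%s%s]", expr$system,
                   paste(expr$codes, collapse = "|"),
                   if (expr$match == "prefix") "*" else ""))
  }
  paste0("(", paste(vapply(expr$args, deparse_expr, ""),
                    collapse = sprintf(" %s ", toupper(expr$op))), ")")
}

#' The eleven built-in case definitions
#'
#' The candidate definitions combine four code predicates: (1) a confirmed
#' T1D diagnosis (ICD-10 prefix E10); (2) the injector-needle claim code
#' for insulin-dependent patients; (3) any basal-insulin medication code;
#' (4) either CSII syringe-pump claim code.  Returned in the canonical
#' order: 1; 2; 3; 4; 1&2; 1&3; 1&4; 1&(3|4); 1&(2|4); 1&(2|3);
#' 1&(2|3|4).
#'
#' @param basal_codes basal-insulin medication codes (required; the list
#'   is site-specific).
#' @param t1d_prefix confirmed-diagnosis prefix (default "E10").
#' @param needle_code injector-needle procedure code.
#' @param pump_codes CSII syringe-pump procedure codes.
#' @return list of 11 [case_definition()]s.
#' @export
builtin_definitions <- function(basal_codes = default_basal_insulin_codes(),
                                t1d_prefix = "E10",
                                needle_code = claim_code_registry()$needle,
                                pump_codes = claim_code_registry()$pump) {
  if (length(basal_codes) == 0L) {
    stop("configuration error: basal-insulin code list is empty", call. = FALSE)
  }
  p1 <- code_predicate("icd10_confirmed", t1d_prefix, "prefix")
  p2 <- code_predicate("procedure", needle_code)
  p3 <- code_predicate("medication", basal_codes)
  p4 <- code_predicate("procedure", pump_codes)
  list(
    case_definition("1. E10 confirmed", p1),
    case_definition("2. needles", p2),
    case_definition("3. basal insulin", p3),
    case_definition("4. CSII pump", p4),
    case_definition("5. E10 & needles", def_all(p1, p2)),
    case_definition("6. E10 & basal", def_all(p1, p3)),
    case_definition("7. E10 & pump", def_all(p1, p4)),
    case_definition("8. E10 & (basal | pump)", def_all(p1, def_any(p3, p4))),
    case_definition("9. E10 & (needles | pump)", def_all(p1, def_any(p2, p4))),
    case_definition("10. E10 & (needles | basal)", def_all(p1, def_any(p2, p3))),
    case_definition("11. E10 & (needles | basal | pump)",
                    def_all(p1, def_any(p2, p3, p4))))
}

predicate_hit <- function(pred, events) {
  sel <- events$system == pred$system
  if (pred$match == "exact") {
    sel & events$code %in% pred$codes
  } else {
    hit <- rep(FALSE, nrow(events))
    for (cd in pred$codes) hit <- hit | startsWith(events$code, cd)
    sel & hit
  }
}

#' Does a single patient's event set match a definition?
#'
#' A leaf is true iff at least one event matches its predicate; AND/OR
#' nodes evaluate recursively.  Evaluation is pure: independent of event
#' order and of other patients.
#'
#' @param definition a [case_definition()].
#' @param events event rows of one patient.
#' @return logical scalar.
#' @export
matches_definition <- function(definition, events) {
  stopifnot(inherits(definition, "case_definition"))
  eval_expr <- function(expr) {
    if (inherits(expr, "code_predicate")) return(any(predicate_hit(expr, events)))
    vals <- vapply(expr$args, eval_expr, NA)
    if (expr$op == "and") all(vals) else any(vals)
  }
  eval_expr(definition$expr)
}

#' Patient ids matching a definition in a dataset
#'
#' Vectorized evaluation: per-predicate positive id sets are combined by
#' set intersection/union following the expression tree.
#'
#' @param definition a [case_definition()].
#' @param dataset a [study_dataset()].
#' @return character vector of matching patient ids.
#' @export
definition_positives <- function(definition, dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  ev <- dataset$events
  eval_expr <- function(expr) {
    if (inherits(expr, "code_predicate")) {
      return(unique(ev$patient_id[predicate_hit(expr, ev)]))
    }
    sets <- lapply(expr$args, eval_expr)
    if (expr$op == "and") Reduce(intersect, sets) else Reduce(union, sets)
  }
  eval_expr(definition$expr)
}

#' Apply case definitions to a dataset
#'
#' @param definitions list of [case_definition()]s.
#' @param dataset a [study_dataset()].
#' @return data.frame with one row per definition: `definition`,
#'   `n_positive`, `prevalence_pct` (percentage of dataset patients
#'   matching); the per-definition id sets are attached as attribute
#'   `"positives"`.
#' @export
apply_definitions <- function(definitions, dataset) {
  pos <- lapply(definitions, definition_positives, dataset = dataset)
  names(pos) <- vapply(definitions, `[[`, "", "name")
  n_pat <- nrow(dataset$patients)
  out <- data.frame(definition = names(pos),
                    n_positive = vapply(pos, length, 0L),
                    prevalence_pct = if (n_pat > 0)
                      100 * vapply(pos, length, 0L) / n_pat else 0)
  rownames(out) <- NULL
  attr(out, "positives") <- pos
  out
}
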