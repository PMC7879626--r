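as_scores <- function(scores) {
  if (inherits(scores, "patient_scores") ||
      (is.data.frame(scores) && all(c("patient_id", "p_case") %in% names(scores)))) {
    return(setNames(scores$p_case, scores$patient_id))
  }
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  stop("scores must be a patient_scores data.frame or a named numeric vector",
       call. = FALSE)
}

#' Probabilistic confusion matrix from predicted case probabilities
#'
#' The real-valued confusion matrix at the heart of probabilistic
#' phenotype validation: over definition-positive patients the predicted
#' case probabilities accumulate into TPs and their complements into FPs;
#' over definition-negative patients the case probabilities accumulate
#' into FNs and the complements into TNs.  By construction
#' `TPs + FPs = #positive` and `FNs + TNs = #negative`.
#'
#' @param scores a `patient_scores` data.frame or named probability
#'   vector covering every patient under evaluation.
#' @param positives ids of patients matched by the case definition (must
#'   be a subset of the scored ids).
#' @return object of class `prob_confusion`: `TPs`, `FPs`, `FNs`, `TNs`,
#'   `n_positive`, `n_negative`.
#' @examples
#' s <- patient_scores(c("A", "B", "C", "D"), c(0.7, 0.4, 0.9, 0.3))
#' probabilistic_confusion(s, c("A", "C"))
#' @export
probabilistic_confusion <- function(scores, positives) {
  p <- as_scores(scores)
  positives <- as.character(positives)
  miss <- setdiff(positives, names(p))
  if (length(miss)) {
    stop("referential error: positive id(s) without a score: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  z <- names(p) %in% positives
  structure(list(TPs = sum(p[z]), FPs = sum(1 - p[z]),
                 FNs = sum(p[!z]), TNs = sum(1 - p[!z]),
                 n_positive = sum(z), n_negative = sum(!z)),
            class = "prob_confusion")
}

#' @export
print.prob_confusion <- function(x, ...) {
  cat(sprintf("probabilistic confusion: TPs=%.4g FPs=%.4g FNs=%.4g TNs=%.4g (n+=%d, n-=%d)\n",
              x$TPs, x$FPs, x$FNs, x$TNs, x$n_positive, x$n_negative))
  invisible(x)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Performance indexes from a probabilistic confusion matrix
#'
#' sensitivity = TPs/(TPs+FNs); specificity = TNs/(FPs+TNs);
#' PPV = TPs/(TPs+FPs); NPV = TNs/(FNs+TNs);
#' F-score = 2 * sensitivity * PPV / (sensitivity + PPV).
#' Indexes with a zero denominator are reported as `NA` and listed in
#' `undefined` — never silently propagated.
#'
#' @param confusion a [probabilistic_confusion()].
#' @return object of class `performance_estimate` with the five indexes
#'   on proportion scale and the `undefined` index names.
#' @export
performance_indexes <- function(confusion) {
  stopifnot(inherits(confusion, "prob_confusion"))
  with(confusion, {
    if (TPs + FPs + FNs + TNs == 0) {
      stop("metrics error: empty confusion matrix", call. = FALSE)
    }
    sens <- safe_ratio(TPs, TPs + FNs)
    spec <- safe_ratio(TNs, FPs + TNs)
    ppv <- safe_ratio(TPs, TPs + FPs)
    npv <- safe_ratio(TNs, FNs + TNs)
    f <- if (!is.na(sens) && !is.na(ppv) && sens + ppv > 0) {
      2 * sens * ppv / (sens + ppv)
    } else {
      NA_real_
    }
    idx <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
             f_score = f)
    structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                   npv = npv, f_score = f,
                   undefined = names(idx)[is.na(idx)]),
              class = "performance_estimate")
  })
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  PPV %.1f%%  NPV %.1f%%  F %.3f\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv,
              100 * x$npv, x$f_score))
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

INDEX_NAMES <- c("sensitivity", "specificity", "ppv", "npv", "f_score")

indexes_from_cells <- function(TPs, FPs, FNs, TNs) {
  sens <- ifelse(TPs + FNs > 0, TPs / (TPs + FNs), NA_real_)
  spec <- ifelse(FPs + TNs > 0, TNs / (FPs + TNs), NA_real_)
  ppv <- ifelse(TPs + FPs > 0, TPs / (TPs + FPs), NA_real_)
  npv <- ifelse(FNs + TNs > 0, TNs / (FNs + TNs), NA_real_)
  f <- ifelse(!is.na(sens) & !is.na(ppv) & sens + ppv > 0,
              2 * sens * ppv / (sens + ppv), NA_real_)
  cbind(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
        f_score = f)
}

# One multinomial-weight bootstrap of the test population shared across
# definitions; Z is the n x D positivity matrix.
boot_engine <- function(p, Z, n_reps, level, seed) {
  n <- length(p)
  set.seed(seed)
  W <- rmultinom(n_reps, n, rep.int(1 / n, n))  # n x n_reps resample weights
  D <- ncol(Z)
  V <- matrix(0, n, 4L * D)
  for (d in seq_len(D)) {
    z <- Z[, d]
    V[, 4L * (d - 1L) + 1L:4L] <- cbind(p * z, (1 - p) * z,
                                        p * (1 - z), (1 - p) * (1 - z))
  }
  M <- crossprod(W, V)  # n_reps x 4D
  lapply(seq_len(D), function(d) {
    cells <- M[, 4L * (d - 1L) + 1L:4L, drop = FALSE]
    idx <- indexes_from_cells(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
    ci <- matrix(NA_real_, length(INDEX_NAMES), 2L,
                 dimnames = list(INDEX_NAMES, c("lower", "upper")))
    dropped <- integer(length(INDEX_NAMES))
    alpha <- (1 - level) / 2
    for (j in seq_along(INDEX_NAMES)) {
      v <- idx[, j]
      dropped[j] <- sum(is.na(v))
      v <- v[!is.na(v)]
      if (length(v)) ci[j, ] <- quantile(v, c(alpha, 1 - alpha), names = FALSE)
    }
    list(ci = ci, dropped = setNames(dropped, INDEX_NAMES))
  })
}

#' Bootstrap confidence intervals for the performance indexes
#'
#' Patient-level bootstrap of the test population: patients are resampled
#' with replacement (paired score and definition status), the five indexes
#' are recomputed per replicate, and percentile intervals are returned.
#' Replicates where an index is undefined are dropped for that index (the
#' count is reported); if every replicate is undefined for every index an
#' error is raised.  Deterministic given `seed`.
#'
#' @inheritParams probabilistic_confusion
#' @param n_reps bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `ci` (5 x 2 matrix), `dropped` (per-index count of
#'   undefined replicates), `n_reps`, `level`.
#' @export
bootstrap_cis <- function(scores, positives, n_reps = 1000, level = 0.95,
                          seed = 1L) {
  stopifnot(n_reps >= 1, level > 0, level < 1)
  p <- as_scores(scores)
  z <- as.numeric(names(p) %in% as.character(positives))
  res <- boot_engine(p, matrix(z, ncol = 1), n_reps, level, seed)[[1]]
  if (all(res$dropped == n_reps)) {
    stop("CI error: every bootstrap replicate undefined", call. = FALSE)
  }
  c(res, list(n_reps = n_reps, level = level))
}

#' Evaluate case definitions against probabilistic scores
#'
#' The full evaluation table: for each definition, the number and
#' percentage of test patients matching, the five performance indexes
#' from the probabilistic confusion matrix, and percentile bootstrap
#' confidence intervals (the same patient resamples are shared across
#' definitions, so rows are paired).  Specificity and NPV get their own
#' columns even though they are typically near 100% for rare phenotypes.
#'
#' @param scores a `patient_scores` table covering every patient of
#'   `dataset`.
#' @param definitions list of [case_definition()]s (default the 11
#'   built-ins).
#' @param dataset the test-period [study_dataset()].
#' @param n_reps,level,seed bootstrap settings (see [bootstrap_cis()]).
#' @param calibration optional result of [calibration_check()]; a
#'   violation is flagged on the printed report.
#' @return data.frame of class `definition_performance`: one row per
#'   definition with point estimates (proportion scale), CI bounds and
#'   `n_positive` / `prevalence_pct`.
#' @export
evaluate_definitions <- function(scores, definitions = builtin_definitions(),
                                 dataset, n_reps = 1000, level = 0.95,
                                 seed = 1L, calibration = NULL) {
  p <- as_scores(scores)
  miss <- setdiff(dataset$patients$patient_id, names(p))
  if (length(miss)) {
    stop("scores must cover all test patients; missing ",
         length(miss), " id(s)", call. = FALSE)
  }
  p <- p[dataset$patients$patient_id]
  applied <- apply_definitions(definitions, dataset)
  pos_sets <- attr(applied, "positives")
  Z <- vapply(pos_sets, function(ids) as.numeric(names(p) %in% ids),
              numeric(length(p)))
  boots <- boot_engine(p, Z, n_reps, level, seed)

  rows <- lapply(seq_along(definitions), function(d) {
    conf <- probabilistic_confusion(p, pos_sets[[d]])
    est <- performance_indexes(conf)
    ci <- boots[[d]]$ci
    data.frame(definition = applied$definition[d],
               n_positive = applied$n_positive[d],
               prevalence_pct = applied$prevalence_pct[d],
               sensitivity = est$sensitivity,
               sensitivity_lo = ci["sensitivity", 1],
               sensitivity_hi = ci["sensitivity", 2],
               ppv = est$ppv, ppv_lo = ci["ppv", 1], ppv_hi = ci["ppv", 2],
               f_score = est$f_score,
               f_score_lo = ci["f_score", 1], f_score_hi = ci["f_score", 2],
               specificity = est$specificity,
               specificity_lo = ci["specificity", 1],
               specificity_hi = ci["specificity", 2],
               npv = est$npv, npv_lo = ci["npv", 1], npv_hi = ci["npv", 2],
               undefined = paste(est$undefined, collapse = "+"))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_reps") <- n_reps
  attr(out, "level") <- level
  attr(out, "n_patients") <- length(p)
  attr(out, "dropped") <- lapply(boots, `[[`, "dropped")
  attr(out, "calibration") <- calibration
  class(out) <- c("definition_performance", "data.frame")
  out
}

fmt_pct <- function(x, lo, hi) {
  ifelse(is.na(x), "--",
         sprintf("%.1f (%.1f, %.1f)", 100 * x, 100 * lo, 100 * hi))
}

#' @export
print.definition_performance <- function(x, ...) {
  cat(sprintf("Case-definition performance (probabilistic gold standard; %d test patients, %d%% percentile bootstrap, %d reps)\n",
              attr(x, "n_patients"), round(100 * attr(x, "level")),
              attr(x, "n_reps")))
  cal <- attr(x, "calibration")
  if (!is.null(cal) && !isTRUE(cal$ok)) {
    cat(sprintf("  WARNING: score calibration outside tolerance (reliability slope %.2f)\n",
                cal$slope))
  }
  tab <- data.frame(
    `Case definition` = x$definition,
    `N (%)` = sprintf("%d (%.3f)", x$n_positive, x$prevalence_pct),
    Sensitivity = fmt_pct(x$sensitivity, x$sensitivity_lo, x$sensitivity_hi),
    PPV = fmt_pct(x$ppv, x$ppv_lo, x$ppv_hi),
    `F-score` = ifelse(is.na(x$f_score), "--",
                       sprintf("%.3f (%.3f, %.3f)", x$f_score, x$f_score_lo,
                               x$f_score_hi)),
    Specificity = ifelse(is.na(x$specificity), "--",
                         sprintf("%.1f", 100 * x$specificity)),
    NPV = ifelse(is.na(x$npv), "--", sprintf("%.1f", 100 * x$npv)),
    check.names = FALSE)
  print(tab, row.names = FALSE, right = FALSE)
  flagged <- x$definition[nzchar(x$undefined)]
  if (length(flagged)) {
    cat("  undefined indexes (zero denominator) for:",
        paste(flagged, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a performance table to TSV
#'
#' @param x a [evaluate_definitions()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_performance <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
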