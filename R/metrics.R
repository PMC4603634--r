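#' The chance-correction constant for CSMF accuracy
#'
#' Random allocation of causes does not score zero on CSMF accuracy: its
#' expected accuracy, averaged over cause compositions drawn uniformly from
#' the simplex, approaches `1 - exp(-1)` as the cause list grows. CCCSMF
#' accuracy rescales CSMF accuracy so that this chance level maps to zero.
#'
#' `"paper"` mode uses the published three-decimal constant 0.632, the value
#' used in reported CCCSMF tables; `"exact"` mode uses `1 - exp(-1)` at full
#' floating precision. The two differ by less than 2e-4.
#'
#' @param mode `"paper"` (0.632, the default) or `"exact"` (`1 - exp(-1)`).
#' @return A single number strictly less than 1.
#' @seealso [asymptotic_chance_constant()] for the closed form,
#'   [simulate_random_allocation_accuracy()] for its Monte Carlo origin.
#' @export
chance_constant <- function(mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  switch(mode, paper = 0.632, exact = 1 - exp(-1))
}

#' Cause-specific concordance and chance-corrected concordance
#'
#' Individual-level accuracy. For each cause `j`, the concordance `C_j` is
#' the fraction of deaths truly due to `j` that were predicted as `j`
#' (multi-class sensitivity): `C_j = M[j, j] / sum(M[j, ])`. Chance-corrected
#' concordance rescales it so uniform random allocation over a `J`-cause list
#' scores zero in expectation:
#' `CCC_j = (C_j - 1/J) / (1 - 1/J)`,
#' and the overall CCC is the unweighted mean of the `CCC_j`.
#'
#' Causes with no truly assigned deaths (zero row sum) have undefined
#' concordance; they are flagged `defined = FALSE` and excluded from the
#' overall mean. Excluding them (rather than scoring them 0 or 1) is what
#' keeps random allocation's expected CCC at zero when a resampled test set
#' happens to drop a cause.
#'
#' @param x A `confusion_matrix` with at least two causes.
#' @return An object of class `"concordance_result"`; use [tidy()] for the
#'   per-cause table and [glance()] for the overall summary.
#' @examples
#' concordance(va_example_matrix("pcva"))
#' @export
concordance <- function(x) {
  stopifnot(inherits(x, "confusion_matrix"))
  j <- length(x$causes)
  if (j < 2) abort("Concordance needs J >= 2 causes.")
  row_tot <- rowSums(x$counts)
  if (all(row_tot == 0)) abort("All rows are zero; the matrix is empty.")
  defined <- unname(row_tot > 0)
  c_j <- unname(ifelse(defined, diag(x$counts) / row_tot, NA_real_))
  ccc_j <- (c_j - 1 / j) / (1 - 1 / j)
  structure(
    list(
      by_cause = tibble(
        cause = as.character(x$causes),
        n_true = as.integer(unname(row_tot)),
        concordance = c_j,
        ccc = ccc_j,
        defined = defined
      ),
      ccc_overall = mean(ccc_j[defined]),
      n_defined_causes = sum(defined),
      j = j
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, digits = 3, ...) {
  cat(sprintf("Chance-corrected concordance over %d causes (%d with deaths)\n",
              x$j, x$n_defined_causes))
  print(as.data.frame(x$by_cause), digits = digits, row.names = FALSE)
  cat(sprintf("Overall CCC: %.*f\n", digits, x$ccc_overall))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) x$by_cause

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(ccc = x$ccc_overall, n_defined_causes = x$n_defined_causes, j = x$j)
}

#' CSMF accuracy
#'
#' Population-level accuracy: one minus the total absolute deviation between
#' true and predicted cause-specific mortality fractions, normalised by its
#' maximum attainable value `2 * (1 - min_j true_j)` so the result lies in
#' \[0, 1\]. A value of 1 means the predicted cause composition matches the
#' cohort's exactly (whatever the individual-level errors); 0 is the worst
#' possible composition.
#'
#' The minimum in the denominator is taken over the full fixed cause list,
#' including causes with no observed deaths.
#'
#' @param true,pred CSMF distributions: tibbles from [true_csmf()] /
#'   [pred_csmf()], named numeric vectors, or bare numeric vectors of equal
#'   length. When both carry cause names they are aligned by name.
#' @return A single number in \[0, 1\].
#' @examples
#' m <- va_example_matrix("pcva")
#' csmf_accuracy(true_csmf(m), pred_csmf(m))
#' @export
csmf_accuracy <- function(true, pred) {
  tv <- csmf_vector(true, arg = "true")
  causes <- names(tv)
  pv <- csmf_vector(pred, causes = causes, arg = "pred")
  if (length(tv) != length(pv)) {
    abort("`true` and `pred` must be distributions over the same cause list.")
  }
  csmf_accuracy_fast(tv, pv)
}

# numeric core, no validation: used in the Monte Carlo loops
csmf_accuracy_fast <- function(true, pred) {
  denom <- 2 * (1 - min(true))
  if (denom <= 0) {
    abort("CSMF accuracy undefined: the minimum true fraction is 1 (single-cause cohort).")
  }
  1 - sum(abs(true - pred)) / denom
}

#' Chance-corrected CSMF accuracy
#'
#' The linear rescaling `(csmf_accuracy - chance) / (1 - chance)`, so that a
#' method matching random allocation's expected CSMF accuracy scores ~0 and
#' perfect population-level prediction scores 1. Values below zero indicate a
#' method whose population-level estimates are worse than random guessing.
#'
#' @param csmf_accuracy CSMF accuracy value(s) in \[0, 1\]; vectorised.
#' @param chance The chance level to subtract; see [chance_constant()].
#' @return Numeric of the same length as `csmf_accuracy`, each value <= 1.
#' @examples
#' cccsmf_accuracy(0.632)  # chance level -> 0
#' cccsmf_accuracy(1)      # perfect      -> 1
#' @export
cccsmf_accuracy <- function(csmf_accuracy, chance = chance_constant()) {
  if (!is.numeric(chance) || length(chance) != 1 || chance >= 1) {
    abort("`chance` must be a single number < 1.")
  }
  if (any(csmf_accuracy < -1e-12 | csmf_accuracy > 1 + 1e-12, na.rm = TRUE)) {
    abort("`csmf_accuracy` values must lie in [0, 1].")
  }
  (csmf_accuracy - chance) / (1 - chance)
}

#' Evaluate a cause-assignment method from labelled deaths
#'
#' The main entry point: takes a long-format data frame of deaths with true
#' and predicted causes, tabulates the confusion matrix, and computes every
#' metric — per-cause concordance and CCC, overall CCC, CSMF accuracy, and
#' CCCSMF accuracy.
#'
#' @inheritParams build_confusion_matrix
#' @param chance Chance level for CCCSMF; see [chance_constant()].
#' @return An object of class `"va_evaluation"`. [tidy()] gives the per-cause
#'   table (concordance, CCC, true/predicted CSMF); [glance()] the one-row
#'   overall summary.
#' @examples
#' study <- generate_synthetic_study(j = 4, cohort_size = 500, quality = 0.6, seed = 7)
#' va_evaluate(study)
#' @export
va_evaluate <- function(data, causes = NULL, chance = chance_constant(),
                        true = true_cause, pred = predicted_cause, id = death_id) {
  m <- build_confusion_matrix(
    data, causes,
    true = {{ true }}, pred = {{ pred }}, id = {{ id }}
  )
  evaluate_matrix(m, chance = chance)
}

#' Evaluate a pre-tabulated confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @inheritParams va_evaluate
#' @return An object of class `"va_evaluation"`; see [va_evaluate()].
#' @examples
#' evaluate_matrix(va_example_matrix("pcva"))
#' @export
evaluate_matrix <- function(x, chance = chance_constant()) {
  stopifnot(inherits(x, "confusion_matrix"))
  conc <- concordance(x)
  tf <- true_csmf(x)
  pf <- pred_csmf(x)
  acc <- csmf_accuracy_fast(tf$fraction, pf$fraction)
  structure(
    list(
      matrix = x,
      concordance = conc,
      csmf = tibble(cause = tf$cause, csmf_true = tf$fraction, csmf_pred = pf$fraction),
      csmf_accuracy = acc,
      cccsmf_accuracy = cccsmf_accuracy(acc, chance),
      chance = chance
    ),
    class = "va_evaluation"
  )
}

#' @export
print.va_evaluation <- function(x, digits = 3, ...) {
  cat(sprintf("Cause-assignment evaluation: n = %d deaths, J = %d causes\n\n",
              as.integer(x$matrix$n), x$concordance$j))
  print(as.data.frame(tidy.va_evaluation(x)), digits = digits, row.names = FALSE)
  cat(sprintf(
    "\nOverall CCC:     %.*f  (over %d causes with deaths)\nCSMF accuracy:   %.*f\nCCCSMF accuracy: %.*f  (chance level %.4g)\n",
    digits, x$concordance$ccc_overall, x$concordance$n_defined_causes,
    digits, x$csmf_accuracy, digits, x$cccsmf_accuracy, x$chance
  ))
  invisible(x)
}

#' @export
tidy.va_evaluation <- function(x, ...) {
  dplyr::left_join(x$concordance$by_cause, x$csmf, by = "cause")
}

#' @export
glance.va_evaluation <- function(x, ...) {
  tibble(
    ccc = x$concordance$ccc_overall,
    csmf_accuracy = x$csmf_accuracy,
    cccsmf_accuracy = x$cccsmf_accuracy,
    chance = x$chance,
    n = as.integer(x$matrix$n),
    j = x$concordance$j,
    n_defined_causes = x$concordance$n_defined_causes
  )
}
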