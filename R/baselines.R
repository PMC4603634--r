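#' Random Allocation baseline
#'
#' Predicts a cause for each death by drawing uniformly at random from the
#' cause list, ignoring everything about the death itself. This is the
#' reference point both chance corrections are anchored to: its expected
#' per-cause CCC is 0 and its expected CSMF accuracy is the chance level that
#' CCCSMF subtracts.
#'
#' @param n Number of deaths to predict.
#' @param causes A [cause_list()] or character vector of causes (J >= 2).
#' @param seed Optional integer; fixing it makes the draw reproducible
#'   without touching the caller's RNG state.
#' @return Character vector of `n` predicted causes.
#' @examples
#' random_allocation(5, c("Stroke", "Diabetes", "Other"), seed = 1)
#' @export
random_allocation <- function(n, causes, seed = NULL) {
  stop_not_count(n, "n")
  causes <- as_cause_list(causes)
  with_seed_if(seed, sample(as.character(causes), n, replace = TRUE))
}

#' Random-From-Train baseline
#'
#' Predicts each death's cause by drawing uniformly at random from the
#' training set's cause labels, i.e. each cause is predicted with probability
#' equal to its training-set frequency. Individually this is chance-level,
#' but when the training and test sets share a cause composition its
#' *population-level* predictions look nearly perfect — the degenerate case
#' that Dirichlet resampling of the test composition exists to expose.
#'
#' @param training_causes Non-empty character vector of training-set cause
#'   labels (one per training death).
#' @param n Number of deaths to predict.
#' @inheritParams random_allocation
#' @return Character vector of `n` predicted causes.
#' @examples
#' random_from_train(c("a", "a", "b"), n = 5, seed = 1)
#' @export
random_from_train <- function(training_causes, n, seed = NULL) {
  training_causes <- as.character(training_causes)
  if (length(training_causes) == 0) abort("`training_causes` is empty.")
  if (anyNA(training_causes)) abort("`training_causes` contains missing labels.")
  stop_not_count(n, "n")
  with_seed_if(seed, sample(training_causes, n, replace = TRUE))
}
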