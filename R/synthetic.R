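#' Generate a synthetic validation study
#'
#' Produces a labelled cohort for exercising the evaluation machinery: true
#' causes are drawn from a configurable CSMF (explicit, or a symmetric
#' Dirichlet draw), and predictions come from a one-parameter "classifier
#' quality" mixture: with probability `quality` the true cause is predicted,
#' otherwise a cause is drawn uniformly from the full list. A death is
#' therefore predicted correctly with probability
#' `quality + (1 - quality) / J`, so `quality = 0` reproduces Random
#' Allocation exactly and `quality = 1` a perfect classifier.
#'
#' @param j Cause-list length; ignored when `causes` is given.
#' @param cohort_size Number of deaths.
#' @param quality Classifier quality in \[0, 1\].
#' @param causes Optional cause list (character); defaults to `cause_01`, ...
#' @param csmf Optional true CSMF (cause/fraction tibble or numeric vector
#'   over the cause list); when `NULL` one is drawn from Dirichlet(`alpha`).
#' @param alpha Dirichlet concentration used when `csmf` is `NULL`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `death_id`, `true_cause`, `predicted_cause`.
#' @examples
#' study <- generate_synthetic_study(j = 3, cohort_size = 100, quality = 0.8, seed = 1)
#' va_evaluate(study)
#' @export
generate_synthetic_study <- function(j = 5, cohort_size = 10000, quality = 0,
                                     causes = NULL, csmf = NULL, alpha = 1,
                                     seed = NULL) {
  causes <- if (is.null(causes)) default_causes(stop_not_count(j, "j", min = 2L)) else as_cause_list(causes)
  j <- length(causes)
  stop_not_count(cohort_size, "cohort_size")
  if (!is.numeric(quality) || length(quality) != 1 || is.na(quality) ||
      quality < 0 || quality > 1) {
    abort("`quality` must be a single number in [0, 1].")
  }
  with_seed_if(seed, {
    p <- if (is.null(csmf)) rdirichlet(1, j, alpha)[1, ] else csmf_vector(csmf, causes = causes)
    ti <- sample.int(j, cohort_size, replace = TRUE, prob = p)
    copy <- stats::runif(cohort_size) < quality
    pi <- ifelse(copy, ti, sample.int(j, cohort_size, replace = TRUE))
    tibble(
      death_id = sprintf("synth_%06d", seq_len(cohort_size)),
      true_cause = as.character(causes)[ti],
      predicted_cause = as.character(causes)[pi]
    )
  })
}
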