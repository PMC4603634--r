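#' Draw cause compositions from a symmetric Dirichlet
#'
#' The uninformative (`alpha = 1`) symmetric Dirichlet puts equal probability
#' on every possible CSMF distribution over the `J`-simplex. Resampling the
#' test set's cause composition from it is what prevents a validation study
#' from rewarding methods that merely know the test composition a priori.
#'
#' @param causes A [cause_list()], a character vector of causes, or a single
#'   integer `J` (causes are then named `cause_01`, ...).
#' @param alpha Positive concentration parameter; 1 is uniform on the simplex.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `draw`, `cause`, `fraction`; each draw's
#'   fractions are non-negative and sum to 1.
#' @examples
#' draw_csmf(c("a", "b", "c"), seed = 1)
#' @export
draw_csmf <- function(causes, alpha = 1, n_draws = 1, seed = NULL) {
  if (rlang::is_scalar_integerish(causes)) {
    if (causes < 2) abort("`causes` given as an integer must be J >= 2.")
    causes <- default_causes(as.integer(causes))
  }
  causes <- as_cause_list(causes)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number.")
  }
  stop_not_count(n_draws, "n_draws")
  j <- length(causes)
  p <- with_seed_if(seed, rdirichlet(n_draws, j, alpha))
  tibble(
    draw = rep(seq_len(n_draws), each = j),
    cause = rep(as.character(causes), n_draws),
    fraction = as.numeric(t(p))
  )
}

# n x j matrix of symmetric Dirichlet(alpha) draws via normalised gammas
rdirichlet <- function(n, j, alpha = 1) {
  g <- matrix(stats::rgamma(n * j, shape = alpha), nrow = n, ncol = j)
  g / rowSums(g)
}

#' Resample a test set to a target cause composition
#'
#' Draws per-cause cohort counts from a multinomial over the target CSMF,
#' then bootstraps deaths (sampling with replacement) within each true-cause
#' stratum of the source data. Causes with target fraction zero receive no
#' deaths; sampling is with replacement because the target may demand more
#' deaths of a cause than the source holds.
#'
#' @param data Data frame of source deaths, one row per death.
#' @param target Target CSMF: a cause/fraction tibble (e.g. one draw of
#'   [draw_csmf()]) or a named numeric vector summing to 1.
#' @param n Cohort size of the resampled test set; defaults to `nrow(data)`.
#' @param true Unquoted column holding the true cause.
#' @param seed Optional integer seed.
#' @return A tibble of `n` rows sampled from `data` (all columns carried
#'   along), whose true-cause composition follows a multinomial draw from
#'   `target`.
#' @export
resample_test_set <- function(data, target, n = NULL, true = true_cause, seed = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) abort("`data` must be a non-empty data frame.")
  n <- if (is.null(n)) nrow(data) else stop_not_count(n, "n")
  tv <- trimws(as.character(rlang::eval_tidy(rlang::enquo(true), data)))
  target <- csmf_vector(target, arg = "target")
  if (is.null(names(target))) abort("`target` must carry cause names.")
  with_seed_if(seed, {
    counts <- as.integer(stats::rmultinom(1, n, target))
    idx <- resample_indices_by_cause(tv, names(target), counts)
    data[idx, , drop = FALSE]
  })
}

# Stratified bootstrap: for each cause with a positive drawn count, sample
# that many source rows (with replacement) from the cause's stratum.
resample_indices_by_cause <- function(true_labels, causes, counts) {
  strata <- split(seq_along(true_labels), factor(true_labels, levels = causes))
  idx <- vector("list", length(causes))
  for (k in seq_along(causes)) {
    if (counts[k] == 0) next
    pool <- strata[[k]]
    if (length(pool) == 0) {
      abort(sprintf(
        "Cannot resample: %d deaths of cause \"%s\" requested but the source set has none.",
        counts[k], causes[k]
      ))
    }
    idx[[k]] <- pool[sample.int(length(pool), counts[k], replace = TRUE)]
  }
  unlist(idx, use.names = FALSE)
}

#' Evaluate a predictor under Dirichlet resampling of the test composition
#'
#' The out-of-sample evaluation protocol for population-level metrics: for
#' each replicate, a true CSMF is drawn from a symmetric Dirichlet, the test
#' set is bootstrapped to that composition, the predictor is run on the
#' resampled cohort, and every metric is computed from the resulting
#' confusion matrix. The "true" CSMF inside each replicate is the empirical
#' composition of the resampled cohort (the confusion-matrix row sums), not
#' the latent Dirichlet draw.
#'
#' @param data Data frame of test deaths (one row per death) with at least a
#'   true-cause column.
#' @param predictor Function taking the resampled cohort (a data frame) and
#'   returning a character vector of predicted causes, one per row. See
#'   [random_allocation()] / [random_from_train()] for ready-made baselines.
#' @param causes Cause list; defaults to the sorted causes observed in `data`.
#' @param replicates Number of Monte Carlo replicates.
#' @param cohort_size Resampled cohort size per replicate; defaults to
#'   `nrow(data)`.
#' @param alpha Dirichlet concentration (1 = uniform over compositions).
#' @param chance Chance level for CCCSMF; see [chance_constant()].
#' @param true Unquoted true-cause column.
#' @param seed Optional integer seed; fixing it makes the whole summary
#'   reproducible.
#' @return An object of class `"resampling_summary"` holding the
#'   per-replicate metric values and their summaries (mean, median, 2.5th and
#'   97.5th percentiles, Monte Carlo standard error). [tidy()] returns the
#'   summary table, [glance()] a one-row overview.
#' @examples
#' study <- generate_synthetic_study(j = 3, cohort_size = 200, quality = 0.7, seed = 2)
#' evaluate_with_resampling(
#'   study, predictor = function(d) random_allocation(nrow(d), unique(study$true_cause)),
#'   replicates = 20, seed = 3
#' )
#' @export
evaluate_with_resampling <- function(data, predictor, causes = NULL,
                                     replicates = 1000, cohort_size = NULL,
                                     alpha = 1, chance = chance_constant(),
                                     true = true_cause, seed = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) abort("`data` must be a non-empty data frame.")
  if (!is.function(predictor)) abort("`predictor` must be a function(data) -> predicted causes.")
  stop_not_count(replicates, "replicates")
  n <- if (is.null(cohort_size)) nrow(data) else stop_not_count(cohort_size, "cohort_size")
  tv <- trimws(as.character(rlang::eval_tidy(rlang::enquo(true), data)))
  if (is.null(causes)) causes <- sort(unique(tv))
  causes <- as_cause_list(causes)
  check_labels_known(tv, causes, seq_along(tv), "true cause")
  j <- length(causes)

  res <- with_seed_if(seed, {
    out <- matrix(NA_real_, nrow = replicates, ncol = 4)
    for (r in seq_len(replicates)) {
      rr <- tryCatch({
        p <- rdirichlet(1, j, alpha)[1, ]
        counts <- as.integer(stats::rmultinom(1, n, p))
        idx <- resample_indices_by_cause(tv, as.character(causes), counts)
        cohort <- data[idx, , drop = FALSE]
        preds <- trimws(as.character(predictor(cohort)))
        if (length(preds) != length(idx)) {
          abort(sprintf("predictor returned %d predictions for %d deaths", length(preds), length(idx)))
        }
        check_labels_known(preds, causes, idx, "predicted cause")
        ti <- match(tv[idx], causes)
        pi <- match(preds, causes)
        m <- matrix(tabulate(ti + j * (pi - 1L), nbins = j * j), nrow = j)
        metrics_from_counts(m, chance)
      }, error = function(e) {
        abort(sprintf("Replicate %d failed: %s", r, conditionMessage(e)))
      })
      out[r, ] <- rr
    }
    out
  })

  replicates_tbl <- tibble(
    replicate = seq_len(replicates),
    ccc = res[, 1],
    csmf_accuracy = res[, 2],
    cccsmf_accuracy = res[, 3],
    n_defined_causes = as.integer(res[, 4])
  )
  new_resampling_summary(
    replicates_tbl,
    config = list(replicates = replicates, cohort_size = n, alpha = alpha,
                  chance = chance, j = j, causes = as.character(causes), seed = seed)
  )
}

# scalar metrics straight from a J x J count matrix (rows = true)
metrics_from_counts <- function(m, chance) {
  j <- nrow(m)
  n <- sum(m)
  row_tot <- rowSums(m)
  defined <- row_tot > 0
  c_j <- diag(m)[defined] / row_tot[defined]
  ccc <- mean((c_j - 1 / j) / (1 - 1 / j))
  acc <- csmf_accuracy_fast(row_tot / n, colSums(m) / n)
  c(ccc, acc, (acc - chance) / (1 - chance), sum(defined))
}

new_resampling_summary <- function(replicates_tbl, config) {
  long <- tidyr::pivot_longer(
    replicates_tbl[c("replicate", "ccc", "csmf_accuracy", "cccsmf_accuracy")],
    -"replicate", names_to = "metric", values_to = "value"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value),
    median = stats::median(.data$value),
    lower = stats::quantile(.data$value, 0.025, names = FALSE),
    upper = stats::quantile(.data$value, 0.975, names = FALSE),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  summary <- summary[match(c("ccc", "csmf_accuracy", "cccsmf_accuracy"), summary$metric), ]
  structure(
    list(replicates = replicates_tbl, summary = summary, config = config),
    class = "resampling_summary"
  )
}

#' @export
print.resampling_summary <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf(
    "Dirichlet-resampled evaluation: %d replicates, cohort %d, J = %d, alpha = %g\n",
    cfg$replicates, cfg$cohort_size, cfg$j, cfg$alpha
  ))
  print(as.data.frame(x$summary), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.resampling_summary <- function(x, ...) x$summary

#' @export
glance.resampling_summary <- function(x, ...) {
  s <- x$summary
  tibble(
    mean_ccc = s$mean[s$metric == "ccc"],
    mean_csmf_accuracy = s$mean[s$metric == "csmf_accuracy"],
    mean_cccsmf_accuracy = s$mean[s$metric == "cccsmf_accuracy"],
    se_cccsmf_accuracy = s$se[s$metric == "cccsmf_accuracy"],
    replicates = x$config$replicates,
    cohort_size = x$config$cohort_size,
    j = x$config$j
  )
}
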