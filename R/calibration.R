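#' Asymptotic chance level of CSMF accuracy
#'
#' The expected CSMF accuracy of uniform random allocation, averaged over
#' cause compositions drawn uniformly from the simplex, tends to
#' `1 - exp(-1)` as both the cause-list length and the cohort size grow.
#' Rounded to three decimals this is the 0.632 used by [chance_constant()]'s
#' default mode; the package verifies the limit numerically via
#' [simulate_random_allocation_accuracy()].
#'
#' @return `1 - exp(-1)` (about 0.6321206).
#' @export
asymptotic_chance_constant <- function() 1 - exp(-1)

# One batch of Random Allocation replicates at fixed J, using the count-level
# shortcut: truth counts ~ Multinomial(N, p) with p ~ Dirichlet(alpha);
# predicted-cause marginals ~ Multinomial(N, 1/J); diagonal cells
# ~ Binomial(row count, 1/J). Distribution-identical, per metric, to drawing
# N uniform predictions death by death.
ra_replicates <- function(j, n, r, alpha = 1) {
  acc <- conc <- numeric(r)
  unif <- rep(1 / j, j)
  pred <- stats::rmultinom(r, n, unif) / n # J x R predicted marginals
  for (i in seq_len(r)) {
    g <- stats::rgamma(j, alpha)
    p <- g / sum(g)
    tc <- stats::rmultinom(1, n, p)[, 1]
    acc[i] <- csmf_accuracy_fast(tc / n, pred[, i])
    d <- stats::rbinom(j, tc, 1 / j)
    def <- tc > 0
    conc[i] <- mean(d[def] / tc[def])
  }
  list(csmf_accuracy = acc, concordance = conc)
}

se_or_na <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_

#' Monte Carlo CSMF accuracy of Random Allocation
#'
#' For each replicate, a true cause composition is drawn from a symmetric
#' Dirichlet, a cohort of `cohort_size` deaths is generated from it by
#' multinomial sampling, causes are predicted uniformly at random, and the
#' CSMF accuracy is computed from the resulting confusion-matrix marginals.
#' The mean over replicates is the chance level that CCCSMF subtracts.
#'
#' @param j Cause-list length (J >= 2).
#' @param cohort_size Deaths per replicate.
#' @param replicates Monte Carlo replicates.
#' @param alpha Dirichlet concentration for the true composition.
#' @param seed Optional integer seed.
#' @return One-row tibble: `j`, `mean_csmf_accuracy`, `se` (Monte Carlo
#'   standard error, `NA` for a single replicate), `replicates`,
#'   `cohort_size`.
#' @examples
#' simulate_random_allocation_accuracy(j = 3, cohort_size = 1000, replicates = 200, seed = 1)
#' @export
simulate_random_allocation_accuracy <- function(j, cohort_size = 10000,
                                                replicates = 10000,
                                                alpha = 1, seed = NULL) {
  stop_not_count(j, "j", min = 2L)
  stop_not_count(cohort_size, "cohort_size")
  stop_not_count(replicates, "replicates")
  sim <- with_seed_if(seed, ra_replicates(j, cohort_size, replicates, alpha))
  tibble(
    j = as.integer(j),
    mean_csmf_accuracy = mean(sim$csmf_accuracy),
    se = se_or_na(sim$csmf_accuracy),
    replicates = as.integer(replicates),
    cohort_size = as.integer(cohort_size)
  )
}

#' Monte Carlo concordance of Random Allocation
#'
#' Cross-checks the analytic chance level of concordance, `1/J`, used in the
#' CCC correction: the Monte Carlo mean of the overall (unweighted,
#' defined-cause) concordance of uniform random allocation is compared
#' against `1/J`.
#'
#' @inheritParams simulate_random_allocation_accuracy
#' @return One-row tibble: `j`, `mean_concordance`, `analytic` (`1/J`),
#'   `rel_diff` (absolute relative difference), `se`, `replicates`,
#'   `cohort_size`.
#' @export
simulate_random_allocation_concordance <- function(j, cohort_size = 10000,
                                                   replicates = 10000,
                                                   alpha = 1, seed = NULL) {
  stop_not_count(j, "j", min = 2L)
  stop_not_count(cohort_size, "cohort_size")
  stop_not_count(replicates, "replicates")
  sim <- with_seed_if(seed, ra_replicates(j, cohort_size, replicates, alpha))
  m <- mean(sim$concordance)
  tibble(
    j = as.integer(j),
    mean_concordance = m,
    analytic = 1 / j,
    rel_diff = abs(m - 1 / j) / (1 / j),
    se = se_or_na(sim$concordance),
    replicates = as.integer(replicates),
    cohort_size = as.integer(cohort_size)
  )
}

#' Chance-level calibration curve over cause-list lengths
#'
#' Runs the Random Allocation simulation across a grid of cause-list lengths
#' and collects, per `J`: the mean CSMF accuracy (the chance level of the
#' uncorrected metric), its CCCSMF transform, and the mean concordance with
#' its analytic value `1/J` — each with Monte Carlo standard errors.
#'
#' @param j_values Integer vector of cause-list lengths (each >= 2).
#' @inheritParams simulate_random_allocation_accuracy
#' @param chance Chance level used for the CCCSMF column.
#' @return A tibble of class `"calibration_curve"`, one row per `J`.
#' @examples
#' calibration_curve(j_values = c(3, 5, 10), replicates = 200, cohort_size = 1000, seed = 1)
#' @export
calibration_curve <- function(j_values = 3:50, cohort_size = 10000,
                              replicates = 10000, alpha = 1,
                              chance = chance_constant(), seed = NULL) {
  j_values <- vapply(j_values, stop_not_count, integer(1), name = "j_values", min = 2L)
  rows <- with_seed_if(seed, {
    purrr::map(j_values, function(j) {
      sim <- ra_replicates(j, cohort_size, replicates, alpha)
      ccc_vals <- cccsmf_accuracy(sim$csmf_accuracy, chance)
      tibble(
        j = as.integer(j),
        mean_csmf_accuracy = mean(sim$csmf_accuracy),
        se_csmf_accuracy = se_or_na(sim$csmf_accuracy),
        mean_cccsmf = mean(ccc_vals),
        se_cccsmf = se_or_na(ccc_vals),
        mean_concordance = mean(sim$concordance),
        se_concordance = se_or_na(sim$concordance),
        analytic_concordance = 1 / j,
        rel_diff_concordance = abs(mean(sim$concordance) - 1 / j) * j
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$replicates <- as.integer(replicates)
  out$cohort_size <- as.integer(cohort_size)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Baseline schemes with and without test-composition resampling
#'
#' The overfitting demonstration: compares the mean CCCSMF accuracy of three
#' baseline schemes across cause-list lengths.
#'
#' * `train_equals_test` — Random-From-Train whose training distribution is
#'   the test cohort's own cause composition and the test composition is
#'   *not* resampled: the classic leak. Chance-level individually, yet its
#'   CCCSMF is near 1.
#' * `random_allocation` — uniform prediction on a Dirichlet-resampled test
#'   cohort; the anchor that should (and does) score near 0.
#' * `uniform_train_resampled` — Random-From-Train trained on uniformly
#'   distributed labels, evaluated on a Dirichlet-resampled test cohort;
#'   also near 0.
#'
#' All schemes use multinomial count shortcuts (distribution-identical to
#' per-death categorical draws) so 10,000 replicates per cell run in seconds.
#'
#' @param j_values Cause-list lengths to evaluate.
#' @param cohort_size Test-cohort deaths per replicate.
#' @param train_size Training-set size for `uniform_train_resampled`.
#' @param replicates Monte Carlo replicates per cell.
#' @param alpha Dirichlet concentration for drawn compositions.
#' @param chance Chance level for the CCCSMF transform.
#' @param train_mode For `uniform_train_resampled`: `"multinomial"` draws the
#'   training labels from a uniform multinomial; `"exact"` uses exactly equal
#'   per-cause counts (requires `train_size` divisible by `j`).
#' @param seed Optional integer seed.
#' @return A tibble of class `"scheme_comparison"` with columns `j`,
#'   `scheme`, `mean_cccsmf`, `se`, `replicates`.
#' @examples
#' compare_baseline_schemes(j_values = 5, replicates = 200, cohort_size = 1000, seed = 1)
#' @export
compare_baseline_schemes <- function(j_values = c(5, 15, 25, 35, 50),
                                     cohort_size = 10000, train_size = 10000,
                                     replicates = 10000, alpha = 1,
                                     chance = chance_constant(),
                                     train_mode = c("multinomial", "exact"),
                                     seed = NULL) {
  j_values <- vapply(j_values, stop_not_count, integer(1), name = "j_values", min = 2L)
  train_mode <- match.arg(train_mode)
  stop_not_count(cohort_size, "cohort_size")
  stop_not_count(train_size, "train_size")
  stop_not_count(replicates, "replicates")
  n <- cohort_size

  rows <- with_seed_if(seed, {
    purrr::map(j_values, function(j) {
      v <- matrix(NA_real_, replicates, 3)
      unif <- rep(1 / j, j)
      if (train_mode == "exact" && train_size %% j != 0) {
        abort("`train_size` must be divisible by `j` in exact mode.")
      }
      for (r in seq_len(replicates)) {
        g <- stats::rgamma(j, 1)
        p <- g / sum(g)
        te <- stats::rmultinom(1, n, p)[, 1]
        # (a) training distribution = the test cohort's empirical composition,
        #     no resampling between "train" and "test"
        pr_a <- stats::rmultinom(1, n, te / n)[, 1]
        v[r, 1] <- csmf_accuracy_fast(te / n, pr_a / n)
        # (b) Random Allocation on the Dirichlet-resampled cohort
        pr_b <- stats::rmultinom(1, n, unif)[, 1]
        v[r, 2] <- csmf_accuracy_fast(te / n, pr_b / n)
        # (c) uniformly-trained Random-From-Train on the resampled cohort
        tr <- if (train_mode == "exact") {
          rep(train_size / j, j)
        } else {
          stats::rmultinom(1, train_size, unif)[, 1]
        }
        pr_c <- stats::rmultinom(1, n, tr / train_size)[, 1]
        v[r, 3] <- csmf_accuracy_fast(te / n, pr_c / n)
      }
      cc <- cccsmf_accuracy(v, chance)
      tibble(
        j = as.integer(j),
        scheme = c("train_equals_test", "random_allocation", "uniform_train_resampled"),
        mean_cccsmf = colMeans(cc),
        se = apply(cc, 2, se_or_na),
        replicates = as.integer(replicates)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scheme_comparison", class(out))
  out
}
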