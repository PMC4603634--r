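# Brute-force metric oracle: computes every metric directly from the label
# pairs, without ever forming a confusion matrix. Kept deliberately naive
# (per-cause loops over the raw labels) so it is independent of the package's
# tabulation path.
brute_force_metrics <- function(true, pred, causes, chance = 0.632) {
  j <- length(causes)
  n <- length(true)
  conc <- ccc <- rep(NA_real_, j)
  for (k in seq_len(j)) {
    mine <- true == causes[k]
    if (sum(mine) > 0) {
      conc[k] <- sum(mine & pred == causes[k]) / sum(mine)
      ccc[k] <- (conc[k] - 1 / j) / (1 - 1 / j)
    }
  }
  tf <- vapply(causes, function(cs) sum(true == cs) / n, numeric(1))
  pf <- vapply(causes, function(cs) sum(pred == cs) / n, numeric(1))
  acc <- 1 - sum(abs(tf - pf)) / (2 * (1 - min(tf)))
  list(
    concordance = conc,
    ccc = ccc,
    ccc_overall = mean(ccc, na.rm = TRUE),
    csmf_true = tf,
    csmf_pred = pf,
    csmf_accuracy = acc,
    cccsmf_accuracy = (acc - chance) / (1 - chance),
    n_defined = sum(!is.na(conc))
  )
}

# Random small labelled instance over at most `j_max` causes; some causes may
# never occur so undefined-concordance handling gets exercised.
random_instance <- function(n_max = 50, j_max = 6) {
  j <- sample(2:j_max, 1)
  n <- sample(1:n_max, 1)
  causes <- sample(letters, j)
  tibble::tibble(
    death_id = seq_len(n),
    true_cause = sample(causes, n, replace = TRUE),
    predicted_cause = sample(causes, n, replace = TRUE)
  ) -> data
  list(data = data, causes = causes)
}

# The physician-coded worked-example counts, restated independently of the
# fixture function so tests catch accidental edits to either copy.
PCVA_COUNTS <- rbind(
  Stroke   = c(123, 18, 125),
  Diabetes = c(58, 6, 55),
  Other    = c(83, 95, 2112)
)
PCVA_CAUSES <- c("Stroke", "Diabetes", "Other")
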