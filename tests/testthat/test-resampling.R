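test_that("Dirichlet draws live on the simplex with the right marginals", {
  draws <- draw_csmf(5, n_draws = 100000, seed = 12)
  expect_true(all(draws$fraction >= 0))
  sums <- tapply(draws$fraction, draws$draw, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # marginal mean is 1/J; SE of the sample mean ~ 0.0005
  means <- tapply(draws$fraction, draws$cause, mean)
  expect_true(all(abs(means - 0.2) < 0.003))
  # mean minimum component of the uniform 5-simplex is 1/J^2 = 0.04
  mins <- tapply(draws$fraction, draws$draw, min)
  expect_lt(abs(mean(mins) - 0.04), 0.002)
})

test_that("draw_csmf validates arguments and carries cause names", {
  expect_error(draw_csmf(1), "J >= 2")
  expect_error(draw_csmf(3, alpha = 0), "positive")
  d <- draw_csmf(c("x", "y"), seed = 1)
  expect_identical(sort(unique(d$cause)), c("x", "y"))
})

test_that("resampling honours zero-fraction causes and the cohort size", {
  source_data <- tibble::tibble(
    death_id = 1:30,
    true_cause = rep(c("a", "b", "c"), each = 10),
    predicted_cause = rep(c("a", "b", "c"), each = 10)
  )
  target <- c(a = 0.5, b = 0.5, c = 0)
  out <- resample_test_set(source_data, target, n = 1000, seed = 5)
  expect_equal(nrow(out), 1000)
  expect_setequal(unique(out$true_cause), c("a", "b"))
})

test_that("resampling to the empirical distribution is bootstrap-consistent", {
  withr::with_seed(8, {
    src <- generate_synthetic_study(j = 3, cohort_size = 5000, quality = 0.5)
  })
  emp <- table(src$true_cause) / nrow(src)
  target <- stats::setNames(as.numeric(emp), names(emp))
  out <- resample_test_set(src, target, seed = 6)
  new_emp <- table(factor(out$true_cause, levels = names(emp))) / nrow(out)
  # multinomial SE per component < sqrt(0.5*0.5/5000) ~ 0.0071
  expect_true(all(abs(new_emp - emp) < 4 * 0.0071))
})

test_that("uniform-target counts fall within multinomial noise", {
  src <- tibble::tibble(death_id = 1:3, true_cause = c("a", "b", "c"))
  out <- resample_test_set(src, c(a = 1, b = 1, c = 1) / 3, n = 30000, seed = 13)
  counts <- table(factor(out$true_cause, levels = c("a", "b", "c")))
  se <- sqrt(30000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000) < 3 * se))
})

test_that("a demanded cause with no source deaths is a labelled error", {
  src <- tibble::tibble(death_id = 1:4, true_cause = rep("a", 4))
  expect_error(
    resample_test_set(src, c(a = 0.5, b = 0.5), n = 100, seed = 2),
    "\"b\""
  )
})

test_that("a perfect oracle scores 1 on every replicate", {
  withr::with_seed(17, {
    study <- generate_synthetic_study(j = 4, cohort_size = 300, quality = 0.2)
  })
  summ <- evaluate_with_resampling(
    study, predictor = function(d) d$true_cause,
    replicates = 25, seed = 18
  )
  expect_true(all(summ$replicates$ccc == 1))
  expect_true(all(summ$replicates$csmf_accuracy == 1))
  expect_true(all(summ$replicates$cccsmf_accuracy == 1))
})

test_that("resampled evaluation is bit-reproducible under a fixed seed", {
  withr::with_seed(19, {
    study <- generate_synthetic_study(j = 3, cohort_size = 200, quality = 0.5)
  })
  causes <- sort(unique(study$true_cause))
  run <- function() {
    evaluate_with_resampling(
      study, predictor = function(d) random_allocation(nrow(d), causes),
      causes = causes, replicates = 40, seed = 20
    )
  }
  a <- run(); b <- run()
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$summary, b$summary)
})

test_that("summary statistics are recomputable from the stored replicates", {
  withr::with_seed(29, {
    study <- generate_synthetic_study(j = 3, cohort_size = 150, quality = 0.4,
                                      csmf = c(0.3, 0.3, 0.4))
  })
  causes <- sort(unique(study$true_cause))
  summ <- evaluate_with_resampling(
    study, predictor = function(d) random_allocation(nrow(d), causes),
    causes = causes, replicates = 60, seed = 30
  )
  s <- tidy(summ)
  acc_row <- s[s$metric == "csmf_accuracy", ]
  vals <- summ$replicates$csmf_accuracy
  expect_equal(acc_row$mean, mean(vals))
  expect_equal(acc_row$se, sd(vals) / sqrt(60))
  expect_true(acc_row$lower <= acc_row$mean && acc_row$mean <= acc_row$upper)
})

test_that("resampling strips Random-From-Train of its population-level advantage", {
  causes <- paste0("c", 1:5)
  withr::with_seed(33, {
    p <- as.numeric(rgamma(5, 1)); p <- p / sum(p)
    test_set <- generate_synthetic_study(causes = causes, cohort_size = 2000,
                                         quality = 0, csmf = p)
    train_labels <- sample(causes, 2000, replace = TRUE, prob = p)
  })
  # no resampling: train and test share a composition -> CCCSMF looks high
  preds <- random_from_train(train_labels, nrow(test_set), seed = 34)
  no_resample <- glance(va_evaluate(
    dplyr::mutate(test_set, predicted_cause = preds), causes = causes
  ))
  expect_gt(no_resample$cccsmf_accuracy, 0.8)
  # with resampling the advantage disappears
  resampled <- evaluate_with_resampling(
    test_set,
    predictor = function(d) random_from_train(train_labels, nrow(d)),
    causes = causes, replicates = 300, seed = 35
  )
  mean_cc <- tidy(resampled)$mean[tidy(resampled)$metric == "cccsmf_accuracy"]
  expect_lt(mean_cc, 0.2)
})

test_that("doubling the replicate count moves the mean by noise only", {
  withr::with_seed(41, {
    study <- generate_synthetic_study(j = 4, cohort_size = 400, quality = 0)
  })
  causes <- sort(unique(study$true_cause))
  run <- function(r, seed) {
    glance(evaluate_with_resampling(
      study, predictor = function(d) random_allocation(nrow(d), causes),
      causes = causes, replicates = r, seed = seed
    ))
  }
  g500 <- run(500, 42)
  g1000 <- run(1000, 43)
  combined_se <- sqrt(g500$se_cccsmf_accuracy^2 + g1000$se_cccsmf_accuracy^2)
  expect_lt(abs(g500$mean_cccsmf_accuracy - g1000$mean_cccsmf_accuracy), 2 * combined_se)
})
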