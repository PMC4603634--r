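pcva <- confusion_matrix(PCVA_COUNTS, PCVA_CAUSES)

test_that("concordance and CCC match hand arithmetic on the worked example", {
  res <- concordance(pcva)
  c_exp <- c(123 / 266, 6 / 119, 2112 / 2290)
  ccc_exp <- (c_exp - 1 / 3) / (1 - 1 / 3)
  expect_equal(tidy(res)$concordance, c_exp, tolerance = 1e-12)
  expect_equal(tidy(res)$ccc, ccc_exp, tolerance = 1e-12)
  expect_equal(res$ccc_overall, mean(ccc_exp), tolerance = 1e-12)
  expect_equal(round(res$ccc_overall, 3), 0.218)
  expect_equal(glance(res)$n_defined_causes, 3L)
})

test_that("perfect prediction scores 1 and uniform rows score chance level", {
  perfect <- confusion_matrix(diag(c(5, 8, 2)), c("a", "b", "c"))
  res <- concordance(perfect)
  expect_equal(tidy(res)$concordance, rep(1, 3))
  expect_equal(tidy(res)$ccc, rep(1, 3))
  expect_equal(res$ccc_overall, 1)

  uniform <- confusion_matrix(matrix(4, 4, 4), paste0("c", 1:4))
  res_u <- concordance(uniform)
  expect_equal(tidy(res_u)$concordance, rep(0.25, 4))
  expect_equal(tidy(res_u)$ccc, rep(0, 4))
  expect_equal(res_u$ccc_overall, 0)
})

test_that("causes with no true deaths are flagged and excluded from the mean", {
  counts <- rbind(c(3, 1, 0), c(1, 5, 0), c(0, 0, 0))
  m <- confusion_matrix(counts, c("a", "b", "ghost"))
  res <- concordance(m)
  expect_false(tidy(res)$defined[3])
  expect_true(is.na(tidy(res)$concordance[3]))
  expect_equal(res$n_defined_causes, 2L)
  c_def <- c(3 / 4, 5 / 6)
  expect_equal(res$ccc_overall, mean((c_def - 1 / 3) / (2 / 3)), tolerance = 1e-12)
})

test_that("CSMF accuracy matches closed forms", {
  expect_equal(
    csmf_accuracy(true_csmf(pcva), pred_csmf(pcva)),
    1 - (4 / 2675) / (2 * (1 - 119 / 2675)),
    tolerance = 1e-12
  )
  expect_equal(csmf_accuracy(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1)
  # maximally wrong prediction normalised by 2(1 - min true) = 2
  expect_equal(csmf_accuracy(c(1, 0, 0, 0), rep(0.25, 4)), 0.25, tolerance = 1e-12)
})

test_that("CSMF accuracy validates its inputs", {
  expect_error(csmf_accuracy(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(csmf_accuracy(c(1, 0), c(1, 0)), NA)
  # single-cause degenerate: min true fraction is 1
  expect_error(csmf_accuracy(1, 1), "minimum true fraction")
  expect_error(
    csmf_accuracy(
      tibble::tibble(cause = c("a", "b"), fraction = c(0.4, 0.6)),
      tibble::tibble(cause = c("a", "z"), fraction = c(0.4, 0.6))
    ),
    "do not match"
  )
})

test_that("CSMF accuracy stays within [0, 1] for random simplex pairs", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      j <- sample(2:8, 1)
      tf <- as.numeric(rgamma(j, 1)); tf <- tf / sum(tf)
      pf <- as.numeric(rgamma(j, 1)); pf <- pf / sum(pf)
      acc <- csmf_accuracy(tf, pf)
      expect_gte(acc, 0)
      expect_lte(acc, 1)
      expect_lte(cccsmf_accuracy(acc), 1)
    }
  })
})

test_that("CSMF accuracy strictly decreases as predictions drift from truth", {
  tf <- c(0.5, 0.3, 0.2)
  drift <- function(eps) c(0.5 - eps, 0.3 + eps / 2, 0.2 + eps / 2)
  accs <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(e) csmf_accuracy(tf, drift(e)), numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("chance correction of CSMF accuracy is the stated linear transform", {
  expect_equal(cccsmf_accuracy(0.632), 0)
  expect_equal(cccsmf_accuracy(1), 1)
  expect_equal(cccsmf_accuracy(0.5), (0.5 - 0.632) / 0.368, tolerance = 1e-12)
  expect_lt(cccsmf_accuracy(0.5), 0) # worse than chance goes negative
  expect_equal(cccsmf_accuracy(1, chance_constant("exact")), 1)
  expect_error(cccsmf_accuracy(0.5, chance = 1), "< 1")
  expect_error(cccsmf_accuracy(1.5), "0, 1")
})

test_that("chance_constant exposes the published and exact modes", {
  expect_identical(chance_constant(), 0.632)
  expect_identical(chance_constant("paper"), 0.632)
  expect_equal(chance_constant("exact"), 1 - exp(-1), tolerance = 1e-15)
  expect_lt(abs(chance_constant("exact") - chance_constant("paper")), 2e-4)
})

test_that("evaluate_matrix bundles concordance and accuracy consistently", {
  ev <- evaluate_matrix(pcva)
  g <- glance(ev)
  expect_equal(g$csmf_accuracy, 1 - (4 / 2675) / (2 * (1 - 119 / 2675)), tolerance = 1e-12)
  expect_equal(g$cccsmf_accuracy, (g$csmf_accuracy - 0.632) / (1 - 0.632), tolerance = 1e-12)
  expect_equal(g$ccc, concordance(pcva)$ccc_overall)
  expect_equal(g$n, 2675L)

  perfect <- confusion_matrix(diag(c(5, 8, 2)), c("a", "b", "c"))
  gp <- glance(evaluate_matrix(perfect))
  expect_equal(gp$ccc, 1)
  expect_equal(gp$cccsmf_accuracy, 1)
})

test_that("va_evaluate on label pairs equals evaluate_matrix on their table", {
  withr::with_seed(23, {
    inst <- random_instance()
    ev_labels <- va_evaluate(inst$data, causes = inst$causes)
    ev_matrix <- evaluate_matrix(build_confusion_matrix(inst$data, inst$causes))
    expect_equal(glance(ev_labels), glance(ev_matrix))
    expect_equal(tidy(ev_labels), tidy(ev_matrix))
  })
})

test_that("scalar metrics are invariant under cause-list permutation", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      inst <- random_instance()
      perm <- sample(length(inst$causes))
      g1 <- glance(va_evaluate(inst$data, causes = inst$causes))
      g2 <- glance(va_evaluate(inst$data, causes = inst$causes[perm]))
      expect_equal(g1$ccc, g2$ccc, tolerance = 1e-12)
      expect_equal(g1$csmf_accuracy, g2$csmf_accuracy, tolerance = 1e-12)
      expect_equal(g1$cccsmf_accuracy, g2$cccsmf_accuracy, tolerance = 1e-12)
    }
  })
})

test_that("degenerate cause lists are rejected", {
  expect_error(concordance(structure(
    list(counts = matrix(5, 1, 1), causes = "only", n = 5),
    class = "confusion_matrix"
  )), "J >= 2")
})
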