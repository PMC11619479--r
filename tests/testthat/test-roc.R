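test_that("empirical AUC matches hand-computed and boundary cases", {
  expect_equal(empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(empirical_roc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(empirical_roc(1:6, c(0, 0, 1, 0, 1, 1))$auc, 8 / 9)
  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("empirical AUC equals brute-force concordance counting exactly", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(0:30, n, replace = TRUE)  # heavy ties on purpose
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- empirical_roc(scores, labels)
    expect_equal(roc$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
    # independent cross-check against pROC
    p <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
    expect_equal(roc$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone in the cut-off", {
  set.seed(9)
  roc <- empirical_roc(rnorm(100), rbinom(100, 1, 0.5))
  # cutoffs descend along the curve; sensitivity and FPR must not decrease
  expect_true(all(diff(roc$curve$sensitivity) >= 0))
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$cutoff) <= 0))
})

test_that("AUC confidence interval behaves and covers the generator truth", {
  set.seed(33)
  scores <- c(rnorm(50, 2), rnorm(50))
  labels <- rep(c(1, 0), each = 50)
  ci <- auc_ci(scores, labels)
  auc <- empirical_roc(scores, labels)$auc
  expect_true(ci[1] <= auc && auc <= ci[2])
  expect_lte(ci[2], 1)
  expect_identical(ci, auc_ci(scores, labels))
  # coverage of the generator's asymptotic AUC across seeded replicates
  cfg0 <- make_default_config(seed = 1)
  bp <- cfg0$bact_params
  true_auc <- pnorm((bp$positive["meanlog"] - bp$negative["meanlog"]) /
                      sqrt(bp$positive["sdlog"]^2 + bp$negative["sdlog"]^2))
  covered <- vapply(1:40, function(i) {
    d <- join_cohort(generate_cohort(
      make_default_config(seed = 5000 + i, n_samples = 3000)), quiet = TRUE)
    ci <- auc_ci(d$bact_per_ul, d$status == "positive")
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("cut-off at target sensitivity maximizes specificity under the floor", {
  row <- cutoff_at_sensitivity(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1), 100)
  expect_equal(row$cutoff, 3)
  expect_equal(row$specificity, 100)
  row80 <- cutoff_at_sensitivity(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1), 80)
  expect_equal(row80$cutoff, 3)  # cutoff 4 only reaches 2/3 sensitivity
  # vanishing target: largest observed score with at least one true positive
  row0 <- cutoff_at_sensitivity(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1), 1e-6)
  expect_equal(row0$cutoff, 5)
  expect_error(cutoff_at_sensitivity(c(1, 2), c(0, 0), 95), "positive")
})

test_that("cut-off selection agrees with exhaustive search", {
  set.seed(404)
  for (i in 1:15) {
    n <- sample(20:500, 1)
    scores <- round(rlnorm(n, 3, 1.5), 1)
    labels <- rbinom(n, 1, 0.35)
    if (sum(labels) == 0) next
    target <- sample(c(80, 85, 90, 95, 97.5, 99), 1)
    expect_equal(cutoff_at_sensitivity(scores, labels, target)$cutoff,
                 cutoff_bruteforce(scores, labels, target))
  }
})

test_that("sensitivity table rows are consistent and monotone", {
  d <- join_cohort(make_test_cohort(n = 1000, seed = 13), quiet = TRUE)
  labels <- d$status == "positive"
  targets <- c(80, 85, 90, 95, 97.5, 99)
  tab <- sensitivity_table(d$bact_per_ul, labels, targets)
  expect_equal(nrow(tab), 6)
  expect_true(all(diff(tab$cutoff) <= 0))
  expect_true(all(tab$sensitivity >= tab$nominal_sensitivity - 1e-9))
  expect_equal(tab[3, ],
               cutoff_at_sensitivity(d$bact_per_ul, labels, targets[3]))
  expect_equal(nrow(sensitivity_table(d$bact_per_ul, labels, numeric(0))), 0)
})

test_that("combined marker behaves sensibly in degenerate settings", {
  d <- join_cohort(make_test_cohort(n = 1000, seed = 17), quiet = TRUE)
  labels <- d$status == "positive"
  # constant WBC: combined ordering equals BACT-alone ordering
  s <- combine_markers(d$bact_per_ul, rep(5, nrow(d)), labels)
  expect_equal(empirical_roc(s, labels)$auc,
               empirical_roc(d$bact_per_ul, labels)$auc, tolerance = 1e-12)
  # perfectly separable marker
  sep_bact <- ifelse(labels, 1000, 1)
  s2 <- combine_markers(sep_bact, d$wbc_per_ul, labels)
  expect_equal(empirical_roc(s2, labels)$auc, 1.0)
  # shuffled labels: combined AUC collapses to chance
  set.seed(55)
  shuffled <- sample(labels)
  s3 <- combine_markers(d$bact_per_ul, d$wbc_per_ul, shuffled)
  expect_lt(abs(empirical_roc(s3, shuffled)$auc - 0.5), 0.05)
})

test_that("median comparison uses an exact rank test on small samples", {
  out <- compare_groups(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_equal(out$median_a, 2)
  expect_equal(out$median_b, 11)
  expect_equal(out$p_value, 0.1)  # exact two-sided U enumeration, U = 0
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_gte(same$p_value, 0.99)
  expect_error(compare_groups(1:3, c(1, 1, 1)), "two levels|groups")
})
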