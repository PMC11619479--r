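test_that("ratio and angle conversions follow the scattergram geometry", {
  expect_equal(fsc_flh_ratio(31.6, 101.2), 31.6 / 101.2)  # ~0.312
  expect_equal(fsc_flh_ratio(7, 7), 1)
  expect_equal(fsc_flh_ratio(0, 100), 0)
  expect_error(fsc_flh_ratio(10, 0), "b_flh")
  expect_equal(ratio_to_angle(1), 45)
  expect_equal(ratio_to_angle(0), 0)
  expect_equal(ratio_to_angle(0.55), 28.8108, tolerance = 1e-4)
  expect_equal(ratio_to_angle(0.55, integer = TRUE), 28)
  expect_error(ratio_to_angle(-0.1), "non-negative")
  # strictly increasing, mapping [0, Inf) into [0, 90)
  r <- sort(runif(50, 0, 20))
  a <- ratio_to_angle(r)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 90))
})

test_that("Youden fit returns the midpoint convention cut-off", {
  fit <- fit_ratio_cutoff(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                          rep(c("GN", "GP"), each = 3))
  expect_equal(fit$ratio_cutoff, 0.5)
  expect_equal(fit$youden, 1)
  expect_equal(fit$angle_cutoff_int, 26)  # atan(0.5) = 26.57 deg
  # indistinguishable classes: J = 0, flagged
  flat <- fit_ratio_cutoff(c(1, 2, 1, 2), c("GN", "GN", "GP", "GP"))
  expect_equal(flat$youden, 0)
  expect_true(flat$low_separability)
  expect_error(fit_ratio_cutoff(c(0.1, 0.2), c("GN", "GN")), "both Gram classes")
  expect_error(fit_ratio_cutoff(c(0.1, 0.2), c("GN", "XX")), "XX")
})

test_that("Youden fit agrees exactly with the exhaustive-scan oracle", {
  set.seed(606)
  for (i in 1:15) {
    n_gn <- sample(10:300, 1)
    n_gp <- sample(10:200, 1)
    ratios <- c(exp(rnorm(n_gn, -1.16, 0.35)), exp(rnorm(n_gp, -0.38, 0.3)))
    gram <- rep(c("GN", "GP"), c(n_gn, n_gp))
    fit <- fit_ratio_cutoff(ratios, gram)
    oracle <- youden_bruteforce(ratios, gram)
    expect_equal(fit$ratio_cutoff, oracle$cutoff, tolerance = 1e-12)
    expect_equal(fit$youden, oracle$j, tolerance = 1e-12)
  }
})

test_that("angle classification matches the ratio rule up to the boundary convention", {
  set.seed(909)
  n <- 200
  data <- tibble::tibble(
    sample_id = as.character(1:n),
    b_fsc_ch = exp(rnorm(n, 3.5, 0.5)),
    b_flh_ch = exp(rnorm(n, 4.5, 0.3)),
    bact_per_ul = rep(100, n),
    gram_class = sample(c("GN", "GP"), n, replace = TRUE)
  )
  res <- classify_by_angle(data, angle_cutoff = 28, bact_cutoff = 42.2)
  ratio <- data$b_fsc_ch / data$b_flh_ch
  expect_equal(res$predictions$predicted,
               ifelse(ratio < tan(28 * pi / 180), "GN", "GP"))
  # an angle exactly at the threshold goes to the non-GN side
  at_boundary <- tibble::tibble(
    b_fsc_ch = 50, b_flh_ch = 100, bact_per_ul = 100, gram_class = "GN"
  )
  expect_equal(
    classify_by_angle(at_boundary,
                      angle_cutoff = ratio_to_angle(0.5))$predictions$predicted,
    "GP")
  # degenerate cut-offs
  expect_true(all(classify_by_angle(dplyr::mutate(data, b_fsc_ch = 0))$
                    predictions$predicted == "GN"))
  expect_true(all(classify_by_angle(data, angle_cutoff = 90)$
                    predictions$predicted == "GN"))
})

test_that("angle classifier evaluation filters and accounts for exclusions", {
  d <- join_cohort(make_test_cohort(n = 2000, seed = 29), quiet = TRUE)
  res <- classify_by_angle(d, angle_cutoff = 28, bact_cutoff = 42.2)
  n_pos <- sum(d$gram_class %in% c("GN", "GP"))
  expect_equal(nrow(res$predictions) + res$n_excluded_bact, n_pos)
  # GN recall should be high with the default generator
  expect_gt(res$metrics$sensitivity, 80)
  # missing channel values are skipped with a warning and counted
  d2 <- d
  d2$b_fsc_ch[d2$gram_class %in% "GN"][1:3] <- NA
  expect_warning(res2 <- classify_by_angle(d2), "3 sample")
  expect_equal(res2$n_skipped_missing, 3)
})

test_that("scattergram summary recovers class medians and ordering", {
  d <- join_cohort(generate_cohort(
    make_default_config(seed = 42, n_samples = 10000)), quiet = TRUE)
  s <- summarize_scattergram(d)
  gn <- s[s$gram_class == "GN", ]
  gp <- s[s$gram_class == "GP", ]
  expect_lt(abs(gn$median_b_fsc - 31.6), 0.5)
  expect_lt(abs(gp$median_b_fsc - 59.8), 0.5)
  # GN ratio median below GP ratio median, and medians-of-ratios used
  expect_lt(gn$median_ratio, gp$median_ratio)
  p <- attr(s, "p_values")
  expect_lt(p[["b_fsc"]], 0.001)
  # two identical classes: identical medians, p ~ 1
  dup <- tibble::tibble(
    b_fsc_ch = rep(c(30, 40, 50), 2), b_flh_ch = rep(c(100, 90, 80), 2),
    gram_class = rep(c("GN", "GP"), each = 3)
  )
  s2 <- summarize_scattergram(dup)
  expect_equal(s2$median_b_fsc[1], s2$median_b_fsc[2])
  expect_gte(attr(s2, "p_values")[["ratio"]], 0.99)
})

test_that("published validation counts give a high-PPV Gram-negative rule", {
  counts <- reference_angle_confusion()
  m <- diagnostic_metrics(counts)
  expect_equal(round_half_up(m$ppv, 1), 93.4)  # 127/136
  expect_gt(m$ppv, 80)
  expect_equal(m$tp, 127)
  expect_equal(m$tp + m$fn, 142)
  expect_equal(round_half_up(m$sensitivity, 1), round_half_up(100 * 127 / 142, 1))
})

test_that("fitted cut-off on generator data recovers the published operating point", {
  # single replicate here; the replicated check lives in the acceptance suite
  d <- join_cohort(generate_cohort(
    make_default_config(seed = 31, n_samples = 1200)), quiet = TRUE)
  gn <- which(d$gram_class %in% "GN")[1:80]
  gp <- which(d$gram_class %in% "GP")[1:15]
  idx <- c(gn, gp)
  fit <- fit_ratio_cutoff(fsc_flh_ratio(d$b_fsc_ch[idx], d$b_flh_ch[idx]),
                          d$gram_class[idx])
  expect_lt(abs(fit$ratio_cutoff - 0.55), 0.2)
  expect_gt(fit$metrics$sensitivity, 80)
})
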