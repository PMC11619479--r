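#' Empirical ROC curve
#'
#' Builds the empirical ROC curve over every distinct observed score (plus
#' \eqn{\pm\infty} sentinels) under the positivity rule *score \eqn{\ge}
#' cutoff*, and computes the AUC by the trapezoidal rule — identical to the
#' Mann–Whitney concordance probability with ties counted one half.
#'
#' @inheritParams confusion_counts
#' @return An object of class `uf_roc`: list with `curve` (tibble of
#'   `cutoff`, `sensitivity`, `fpr`, `tp`, `fn`, `tn`, `fp`), `auc`,
#'   `n_pos`, `n_neg`. Methods: [tidy()], [glance()] (adds the DeLong CI),
#'   `autoplot()`.
#' @examples
#' roc <- empirical_roc(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1))
#' roc$auc  # 8/9
#' @export
empirical_roc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build a ROC curve")
  }
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  # cumulative counts: at each cutoff, positives are scores >= cutoff
  tp <- vapply(cutoffs, function(c) sum(scores >= c & labels), numeric(1))
  fp <- vapply(cutoffs, function(c) sum(scores >= c & !labels), numeric(1))
  curve <- tibble(
    cutoff = cutoffs,
    sensitivity = tp / n_pos,
    fpr = fp / n_neg,
    tp = as.integer(tp), fn = as.integer(n_pos - tp),
    tn = as.integer(n_neg - fp), fp = as.integer(fp)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$sensitivity, -1) +
                                  tail(curve$sensitivity, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "uf_roc")
}

#' @export
print.uf_roc <- function(x, ...) {
  cat(sprintf("<uf_roc> AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.uf_roc <- function(x, ...) x$curve

#' @export
glance.uf_roc <- function(x, ...) {
  ci <- auc_ci(x$scores, x$labels)
  tibble(auc = x$auc, ci_low = ci[1], ci_high = ci[2],
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.uf_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 − specificity", y = "Sensitivity",
                  title = sprintf("Empirical ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' 95% confidence interval for the empirical AUC
#'
#' DeLong's variance estimate by default (via \pkg{pROC}); a seeded
#' stratified bootstrap with 2,000 resamples is available as a fallback for
#' settings where the DeLong estimate is unreliable.
#'
#' @inheritParams confusion_counts
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap resamples (bootstrap method only).
#' @param seed Seed for the bootstrap (bootstrap method only).
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   boot_n = 2000, seed = 1L) {
  method <- match.arg(method)
  labels <- check_scores_labels(scores, labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("need at least two samples per class for an AUC interval")
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  if (method == "delong") {
    ci <- pROC::ci.auc(roc, method = "delong")
  } else {
    set.seed(seed)
    ci <- pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n)
  }
  c(low = max(0, ci[1]), high = min(1, ci[3]))
}

#' Screening cut-off at a target sensitivity
#'
#' Among all distinct observed scores, returns the **largest** cut-off whose
#' achieved sensitivity is at least the target — i.e. the most specific rule
#' that still honours the sensitivity floor. The smallest observed score
#' always achieves 100% sensitivity, so a cut-off exists for any attainable
#' target.
#'
#' @inheritParams confusion_counts
#' @param target Target sensitivity in percent (0 < target \eqn{\le} 100).
#' @return A one-row tibble (`nominal_sensitivity`, `cutoff`, the achieved
#'   metrics and counts as in [diagnostic_metrics()]).
#' @examples
#' cutoff_at_sensitivity(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 1), target = 100)
#' @export
cutoff_at_sensitivity <- function(scores, labels, target) {
  labels <- check_scores_labels(scores, labels)
  if (!is.numeric(target) || length(target) != 1 || is.na(target) ||
      target <= 0 || target > 100) {
    abort("`target` must be a percentage in (0, 100]")
  }
  if (!any(labels)) abort("no condition-positive samples: target unattainable")
  candidates <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  for (c in candidates) {
    sens <- sum(scores >= c & labels) / n_pos
    if (sens >= target / 100 - 1e-12) {
      metrics <- diagnostic_metrics(confusion_counts(scores, labels, c))
      return(dplyr::bind_cols(tibble(nominal_sensitivity = target, cutoff = c),
                              metrics))
    }
  }
  abort("no cutoff achieves the target sensitivity") # unreachable: min score attains 100%
}

#' Cut-off table across sensitivity targets
#'
#' One [cutoff_at_sensitivity()] row per target, in the order given — the
#' layout of a screening-performance table tabulated at nominal sensitivity
#' levels (80, 85, 90, 95, 97.5, 99).
#'
#' @inheritParams confusion_counts
#' @param targets Numeric vector of target sensitivities (percent).
#' @return A tibble with one row per target.
#' @export
sensitivity_table <- function(scores, labels,
                              targets = c(80, 85, 90, 95, 97.5, 99)) {
  purrr::map_dfr(targets, function(t) cutoff_at_sensitivity(scores, labels, t))
}

#' Combined BACT + WBC marker score
#'
#' Fits a two-covariate linear logistic model on log-transformed counts
#' (offset +1) by maximum likelihood and returns the linear predictor, a
#' score usable by [empirical_roc()]. With a degenerate (constant)
#' covariate the score ordering reduces to the other marker alone.
#'
#' @param bact,wbc Counts per µL.
#' @inheritParams confusion_counts
#' @return Numeric score vector with the fitted model as attribute `"model"`.
#' @export
combine_markers <- function(bact, wbc, labels) {
  labels <- check_scores_labels(bact, labels)
  if (length(wbc) != length(bact)) abort("`bact` and `wbc` must have equal length")
  if (!any(labels) || all(labels)) abort("both classes must be present")
  df <- data.frame(y = labels, lb = log(bact + 1), lw = log(wbc + 1))
  fit <- suppressWarnings(glm(y ~ lb + lw, family = binomial(), data = df))
  beta <- coef(fit)
  if (is.na(beta[["lb"]]) && is.na(beta[["lw"]])) {
    abort("logistic fit failed: both marker coefficients are undefined")
  }
  beta[is.na(beta)] <- 0
  score <- as.numeric(beta[1] + beta[["lb"]] * df$lb + beta[["lw"]] * df$lw)
  attr(score, "model") <- fit
  score
}

#' @importFrom stats coef
NULL

#' Two-group comparison of medians
#'
#' Group medians with a two-sided Mann–Whitney U (Wilcoxon rank-sum)
#' p-value — the appropriate test when medians of skewed, non-normal
#' instrument readouts are compared.
#'
#' @param values Numeric measurements.
#' @param groups Binary group indicator (logical, 0/1 or two-level factor);
#'   the `TRUE`/1 group is reported as `median_a`.
#' @return A one-row tibble: `median_a`, `median_b`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length")
  }
  if (is.factor(groups) || is.character(groups)) {
    lev <- sort(unique(as.character(groups)))
    if (length(lev) != 2) abort("`groups` must have exactly two levels")
    groups <- as.character(groups) == lev[1]
  } else {
    groups <- as_binary_labels(groups, "groups")
  }
  a <- values[groups]
  b <- values[!groups]
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  p <- suppressWarnings(wilcox.test(a, b, exact = NULL))$p.value
  tibble(median_a = median(a), median_b = median(b),
         p_value = p, n_a = length(a), n_b = length(b))
}
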