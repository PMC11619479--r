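#' B_FSC/B_FLH ratio and scattergram angle
#'
#' The bacterial scattergram plots forward scatter (B_FSC, a size proxy) on
#' the ordinate against fluorescence intensity (B_FLH, a nucleic-acid
#' staining proxy) on the abscissa, so the slope of a sample's point cloud
#' is the B_FSC/B_FLH ratio and its angle from the X-axis is
#' \eqn{\arctan(\mathrm{ratio})}. Gram-negative rods are small but stain
#' brightly (low ratio, low angle); Gram-positive cocci aggregate into
#' larger, dimly stained clusters (high ratio).
#'
#' @param b_fsc,b_flh Channel intensities (ch); `b_flh` must be positive.
#' @param ratio Non-negative slope value(s).
#' @param integer Truncate the angle toward zero to a whole degree, the
#'   convention used when quoting a threshold angle (arctan(0.55) =
#'   28.81° is reported as 28°).
#' @return `fsc_flh_ratio()`: the dimensionless ratio. `ratio_to_angle()`:
#'   the angle in degrees in \[0, 90).
#' @examples
#' ratio_to_angle(0.55)                  # 28.81...
#' ratio_to_angle(0.55, integer = TRUE)  # 28
#' @export
fsc_flh_ratio <- function(b_fsc, b_flh) {
  if (any(is.na(b_flh)) || any(b_flh <= 0)) {
    abort("`b_flh` must be positive (channel intensities are > 0)")
  }
  if (any(is.na(b_fsc)) || any(b_fsc < 0)) abort("`b_fsc` must be non-negative")
  b_fsc / b_flh
}

#' @rdname fsc_flh_ratio
#' @export
ratio_to_angle <- function(ratio, integer = FALSE) {
  if (any(is.na(ratio)) || any(ratio < 0)) {
    abort("`ratio` must be non-negative")
  }
  deg <- atan(ratio) * 180 / pi
  if (integer) trunc(deg) else deg
}

#' Fit the optimal Gram-discriminating ratio cut-off
#'
#' Scans every midpoint between adjacent distinct observed ratios and picks
#' the cut-off maximizing the Youden index J = SEN + SPE − 1, where a
#' Gram-negative call is *ratio \eqn{\le} cutoff* (Gram-negatives have the
#' lower ratio). Ties in J are broken toward higher sensitivity. The fitted
#' cut-off is also expressed as a threshold angle from the abscissa.
#'
#' @param ratios Per-sample B_FSC/B_FLH ratios.
#' @param gram_labels Per-sample Gram class, `"GN"` or `"GP"`.
#' @return An object of class `uf_angle_classifier`: list with
#'   `ratio_cutoff`, `angle_cutoff_deg` (full precision),
#'   `angle_cutoff_int` (truncated), `youden`, `metrics` (training
#'   [diagnostic_metrics()] row), `n_gn`, `n_gp` and `method`. A J of 0
#'   marks a low-separability fit (`low_separability = TRUE`).
#' @examples
#' fit <- fit_ratio_cutoff(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
#'                         rep(c("GN", "GP"), each = 3))
#' fit$ratio_cutoff  # 0.5
#' @export
fit_ratio_cutoff <- function(ratios, gram_labels) {
  if (length(ratios) != length(gram_labels)) {
    abort("`ratios` and `gram_labels` must have equal length")
  }
  bad <- setdiff(unique(gram_labels), c("GN", "GP"))
  if (length(bad)) {
    abort(sprintf("unknown Gram label `%s` (expected GN or GP)", bad[1]))
  }
  is_gn <- gram_labels == "GN"
  if (!any(is_gn) || all(is_gn)) abort("both Gram classes must be present")
  if (anyNA(ratios) || any(ratios < 0)) abort("`ratios` must be non-negative")

  s <- sort(unique(ratios))
  if (length(s) < 2) abort("need at least two distinct ratio values")
  candidates <- (head(s, -1) + tail(s, -1)) / 2
  sens <- vapply(candidates, function(c) mean(ratios[is_gn] <= c), numeric(1))
  spec <- vapply(candidates, function(c) mean(ratios[!is_gn] > c), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(sens[best])]
  cutoff <- candidates[pick]

  counts <- confusion(
    tp = sum(is_gn & ratios <= cutoff), fn = sum(is_gn & ratios > cutoff),
    tn = sum(!is_gn & ratios > cutoff), fp = sum(!is_gn & ratios <= cutoff)
  )
  structure(list(
    ratio_cutoff = cutoff,
    angle_cutoff_deg = ratio_to_angle(cutoff),
    angle_cutoff_int = ratio_to_angle(cutoff, integer = TRUE),
    youden = j[pick],
    low_separability = j[pick] <= 1e-12,
    metrics = diagnostic_metrics(counts),
    n_gn = sum(is_gn), n_gp = sum(!is_gn),
    method = "youden_midpoint"
  ), class = "uf_angle_classifier")
}

#' @export
print.uf_angle_classifier <- function(x, ...) {
  cat(sprintf(
    "<uf_angle_classifier> ratio cutoff %.3f (angle %.2f deg, reported %d deg)\n",
    x$ratio_cutoff, x$angle_cutoff_deg, x$angle_cutoff_int))
  cat(sprintf("  training: sens %.1f%% spec %.1f%% (GN n=%d, GP n=%d, J=%.3f)%s\n",
              x$metrics$sensitivity, x$metrics$specificity, x$n_gn, x$n_gp,
              x$youden,
              if (x$low_separability) "  [low separability]" else ""))
  invisible(x)
}

#' @export
tidy.uf_angle_classifier <- function(x, ...) {
  dplyr::bind_cols(
    tibble(ratio_cutoff = x$ratio_cutoff,
           angle_cutoff_deg = x$angle_cutoff_deg,
           angle_cutoff_int = x$angle_cutoff_int),
    x$metrics
  )
}

#' @export
glance.uf_angle_classifier <- function(x, ...) {
  tibble(ratio_cutoff = x$ratio_cutoff, angle_cutoff_int = x$angle_cutoff_int,
         youden = x$youden, n_gn = x$n_gn, n_gp = x$n_gp,
         low_separability = x$low_separability)
}

#' Classify specimens by scattergram angle
#'
#' Applies the threshold-angle rule to culture-positive specimens with
#' adequate bacterial counts: a specimen whose scattergram angle is
#' strictly below the cut-off is predicted Gram-negative, otherwise
#' Gram-positive (an angle exactly at the threshold is the non-GN call).
#' Only samples with BACT \eqn{\ge} `bact_cutoff` enter; samples with
#' missing channel values are skipped with a warning and counted.
#'
#' @param data A joined cohort with `b_fsc_ch`, `b_flh_ch`, `bact_per_ul`
#'   and a Gram truth column `gram_class` (GN / GP / Mixed; Mixed samples
#'   whose organisms are all Gram-negative should already be labelled GN).
#' @param angle_cutoff Threshold angle in degrees (default 28).
#' @param bact_cutoff Minimum BACT per µL for inclusion (default 42.2).
#' @return An object of class `uf_angle_eval`: list with `predictions`
#'   (tibble: sample_id if present, angle, predicted, gram_class),
#'   `confusion` (GN as the positive class), `metrics`, `n_excluded_bact`,
#'   `n_skipped_missing`.
#' @export
classify_by_angle <- function(data, angle_cutoff = 28, bact_cutoff = 42.2) {
  need <- c("b_fsc_ch", "b_flh_ch", "bact_per_ul", "gram_class")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  kept <- dplyr::filter(data, .data$gram_class %in% c("GN", "GP"))
  n_excluded_bact <- sum(kept$bact_per_ul < bact_cutoff)
  kept <- dplyr::filter(kept, .data$bact_per_ul >= bact_cutoff)
  miss <- is.na(kept$b_fsc_ch) | is.na(kept$b_flh_ch)
  n_skipped <- sum(miss)
  if (n_skipped > 0) {
    warn(sprintf("classify_by_angle: skipped %d sample(s) with missing channel values",
                 n_skipped))
  }
  kept <- kept[!miss, , drop = FALSE]
  angle <- ratio_to_angle(fsc_flh_ratio(kept$b_fsc_ch, kept$b_flh_ch))
  predicted <- ifelse(angle < angle_cutoff, "GN", "GP")
  predictions <- tibble(
    sample_id = if ("sample_id" %in% names(kept)) kept$sample_id
                else as.character(seq_len(nrow(kept))),
    angle = angle,
    predicted = predicted,
    gram_class = kept$gram_class
  )
  counts <- confusion(
    tp = sum(predicted == "GN" & kept$gram_class == "GN"),
    fn = sum(predicted == "GP" & kept$gram_class == "GN"),
    tn = sum(predicted == "GP" & kept$gram_class == "GP"),
    fp = sum(predicted == "GN" & kept$gram_class == "GP")
  )
  structure(list(predictions = predictions, confusion = counts,
                 metrics = diagnostic_metrics(counts),
                 angle_cutoff = angle_cutoff, bact_cutoff = bact_cutoff,
                 n_excluded_bact = n_excluded_bact,
                 n_skipped_missing = n_skipped),
            class = "uf_angle_eval")
}

#' @export
print.uf_angle_eval <- function(x, ...) {
  cat(sprintf("<uf_angle_eval> angle < %s deg => GN; n = %d (excluded %d below BACT %.1f, %d missing channels)\n",
              format(x$angle_cutoff), nrow(x$predictions),
              x$n_excluded_bact, x$bact_cutoff, x$n_skipped_missing))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.uf_angle_eval <- function(x, ...) x$predictions

#' @export
glance.uf_angle_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(angle_cutoff = x$angle_cutoff,
                          bact_cutoff = x$bact_cutoff), x$metrics)
}

#' Per-class scattergram channel summary
#'
#' Medians of B_FSC, B_FLH and the per-sample B_FSC/B_FLH ratio for each
#' Gram class (the ratio median is the median of per-sample ratios, not the
#' ratio of medians), with Mann–Whitney p-values for the GN-vs-GP contrast
#' of each quantity.
#'
#' @param data A data frame with `b_fsc_ch`, `b_flh_ch` and `gram_class`
#'   columns (only GN / GP rows are used).
#' @return A tibble with one row per Gram class and attribute `p_values`.
#' @export
summarize_scattergram <- function(data) {
  kept <- dplyr::filter(data, .data$gram_class %in% c("GN", "GP"))
  if (length(unique(kept$gram_class)) < 2) {
    abort("both Gram classes must be present")
  }
  kept$ratio <- fsc_flh_ratio(kept$b_fsc_ch, kept$b_flh_ch)
  summary <- kept |>
    dplyr::group_by(gram_class = .data$gram_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_b_fsc = median(.data$b_fsc_ch),
      median_b_flh = median(.data$b_flh_ch),
      median_ratio = median(.data$ratio),
      .groups = "drop"
    )
  gn <- kept$gram_class == "GN"
  p <- c(
    b_fsc = compare_groups(kept$b_fsc_ch, gn)$p_value,
    b_flh = compare_groups(kept$b_flh_ch, gn)$p_value,
    ratio = compare_groups(kept$ratio, gn)$p_value
  )
  attr(summary, "p_values") <- p
  summary
}

#' Scattergram plot with the threshold-angle ray
#'
#' Plots per-sample channel medians as points in the (B_FLH, B_FSC) plane,
#' coloured by Gram class, with the classification ray at the threshold
#' angle drawn from the origin.
#'
#' @inheritParams classify_by_angle
#' @return A ggplot object.
#' @export
plot_scattergram <- function(data, angle_cutoff = 28) {
  kept <- dplyr::filter(data, .data$gram_class %in% c("GN", "GP"),
                        !is.na(.data$b_fsc_ch), !is.na(.data$b_flh_ch))
  slope <- tan(angle_cutoff * pi / 180)
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$b_flh_ch, y = .data$b_fsc_ch,
                                     colour = .data$gram_class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = slope, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "B_FLH (ch)", y = "B_FSC (ch)", colour = "Culture",
                  title = sprintf("Scattergram with %s deg threshold ray",
                                  format(angle_cutoff))) +
    ggplot2::theme_minimal()
}
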