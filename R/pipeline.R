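positivity_labels <- function(data, positivity = c("1e4", "1e5")) {
  positivity <- match.arg(positivity)
  if (positivity == "1e4") data$status == "positive"
  else data$status == "positive" & data$cfu_category == "ge1e5"
}

#' Screening evaluation of a joined cohort
#'
#' Runs the BACT-count screening analysis against culture on a joined,
#' non-yeast cohort: the cut-off table across nominal sensitivity targets
#' plus, per row, the workload reduction achieved if only screen-positive
#' samples were cultured.
#'
#' @param data A joined cohort from [join_cohort()].
#' @param positivity Culture-positivity criterion: `"1e4"` (any positive,
#'   \eqn{\ge 10^4} CFU/mL) or `"1e5"` (\eqn{\ge 10^5} only).
#' @param targets Nominal sensitivity targets in percent.
#' @param score_col Column holding the screening marker (default
#'   `bact_per_ul`).
#' @return A tibble: one row per target with cutoff, metrics, counts,
#'   `culture_reduction` and `false_negative_rate`.
#' @export
screen_cohort <- function(data, positivity = c("1e4", "1e5"),
                          targets = c(80, 85, 90, 95, 97.5, 99),
                          score_col = "bact_per_ul") {
  labels <- positivity_labels(data, positivity)
  tab <- sensitivity_table(data[[score_col]], labels, targets)
  wl <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    workload_reduction(tab[i, ])[, c("culture_reduction", "false_negative_rate")]
  })
  dplyr::bind_cols(tab, wl)
}

#' Run the full screening pipeline
#'
#' Orchestrates the three analysis stages on a joined cohort, mirroring the
#' order of a screening evaluation study:
#' 1. **screening** — ROC AUC with DeLong CI and the cut-off table at the
#'    requested sensitivity targets ([screen_cohort()]);
#' 2. **agreement** — flag-versus-culture cross-tab above the BACT cut-off,
#'    Cohen's kappa under the named collapsing scheme, and per-Gram flag
#'    metrics ([flag_crosstab()], [cohen_kappa()], [gram_flag_metrics()]);
#' 3. **gram angle** — scattergram summary and the threshold-angle
#'    classifier evaluation ([classify_by_angle()]); skipped with a notice
#'    when channel columns are absent or all-missing.
#'
#' All numbers in the rendered report are recomputable from the emitted
#' CSVs; percentages are rounded half-up to one decimal for display only.
#'
#' @param samples,cultures Sample/culture tibbles, file paths, or a
#'   `uf_cohort` as `samples`.
#' @param positivity Culture-positivity criterion (see [screen_cohort()]).
#' @param targets Sensitivity targets (percent).
#' @param bact_cutoff BACT inclusion cut-off for the agreement and angle
#'   stages (per µL).
#' @param collapsing Kappa collapsing scheme (see [cohen_kappa()]).
#' @param angle_cutoff Threshold angle in degrees.
#' @param out_dir Optional directory; when given, writes `screening.csv`,
#'   `agreement.csv`, `angle_predictions.csv`, `metrics.json` and
#'   `report.md`.
#' @return An object of class `uf_report` (a list of stage results),
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(samples, cultures = NULL,
                         positivity = "1e4",
                         targets = c(80, 85, 90, 95, 97.5, 99),
                         bact_cutoff = 42.2,
                         collapsing = "three_class",
                         angle_cutoff = 28,
                         out_dir = NULL) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(cultures)) cultures <- read_cultures(cultures)
  data <- join_cohort(samples, cultures, quiet = TRUE)

  labels <- positivity_labels(data, positivity)
  roc <- empirical_roc(data$bact_per_ul, labels)
  ci <- auc_ci(data$bact_per_ul, labels)
  screening <- screen_cohort(data, positivity, targets)

  agreement <- flag_crosstab(data, bact_cutoff = bact_cutoff)
  kappa <- cohen_kappa(agreement, collapsing = collapsing)
  gn_metrics <- gram_flag_metrics(agreement, "GN")
  gp_metrics <- gram_flag_metrics(agreement, "GP")

  has_channels <- all(c("b_fsc_ch", "b_flh_ch") %in% names(data)) &&
    any(!is.na(data$b_fsc_ch) & !is.na(data$b_flh_ch))
  if (has_channels) {
    angle <- classify_by_angle(data, angle_cutoff = angle_cutoff,
                               bact_cutoff = bact_cutoff)
    scatter <- summarize_scattergram(data)
  } else {
    message("run_pipeline: channel columns missing; gram-angle stage skipped")
    angle <- NULL
    scatter <- NULL
  }

  report <- structure(list(
    n = nrow(data),
    n_yeast = attr(data, "n_yeast"),
    n_contaminated = attr(data, "n_contaminated"),
    positivity = positivity,
    auc = roc$auc, auc_ci = ci,
    screening = screening,
    agreement = agreement, kappa = kappa,
    gn_flag = gn_metrics, gp_flag = gp_metrics,
    scatter = scatter, angle = angle
  ), class = "uf_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}

#' @export
print.uf_report <- function(x, ...) {
  cat(sprintf("<uf_report> %d non-yeast samples; positivity >= 10^%s CFU/mL\n",
              x$n, sub("1e", "", x$positivity)))
  cat(sprintf("  BACT AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  print(x$kappa)
  if (!is.null(x$angle)) {
    cat(sprintf("  angle rule (<%s deg): GN PPV %.1f%%\n",
                format(x$angle$angle_cutoff), x$angle$metrics$ppv))
  }
  invisible(x)
}

fmt_pct <- function(x) {
  ifelse(is.na(x), "undefined", sprintf("%.1f", round_half_up(x, 1)))
}

#' Write a pipeline report bundle
#'
#' @param report A `uf_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "uf_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$screening, file.path(dir, "screening.csv"))
  readr::write_csv(tidy(report$agreement), file.path(dir, "agreement.csv"))
  if (!is.null(report$angle)) {
    readr::write_csv(report$angle$predictions,
                     file.path(dir, "angle_predictions.csv"))
  }
  metrics <- list(
    n = report$n, positivity = report$positivity,
    auc = report$auc, auc_ci = unname(report$auc_ci),
    kappa = tidy(report$kappa),
    gn_flag = report$gn_flag, gp_flag = report$gp_flag,
    angle = if (!is.null(report$angle)) glance(report$angle) else NULL
  )
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  s <- report$screening
  lines <- c(
    "# UF-5000 screening report",
    "",
    sprintf("Non-yeast samples analysed: %d (excluded: %d yeast, %d contaminated).",
            report$n, report$n_yeast, report$n_contaminated),
    sprintf("Culture positivity criterion: >= 10^%s CFU/mL.",
            sub("1e", "", report$positivity)),
    sprintf("BACT AUC: %.3f (95%% CI %.3f to %.3f).",
            report$auc, report$auc_ci[1], report$auc_ci[2]),
    "",
    "## Cut-off table",
    "",
    "| Nominal SEN | Cutoff (/uL) | SEN | SPE | PPV | NPV | TP | FN | TN | FP | Culture reduction | FN rate |",
    "|---|---|---|---|---|---|---|---|---|---|---|---|",
    sprintf("| %.1f | %.1f | %s | %s | %s | %s | %d | %d | %d | %d | %s | %s |",
            s$nominal_sensitivity, s$cutoff, fmt_pct(s$sensitivity),
            fmt_pct(s$specificity), fmt_pct(s$ppv), fmt_pct(s$npv),
            s$tp, s$fn, s$tn, s$fp,
            fmt_pct(s$culture_reduction), fmt_pct(s$false_negative_rate)),
    "",
    "## Flag agreement",
    "",
    sprintf("Cohen's kappa (%s collapsing): %s (Po %.3f, Pe %.3f, n %d).",
            report$kappa$collapsing,
            if (is.na(report$kappa$kappa)) "undefined"
            else sprintf("%.3f", report$kappa$kappa),
            report$kappa$observed_agreement, report$kappa$expected_agreement,
            report$kappa$n),
    sprintf("GN flag: PPV %s%%, SPE %s%%. GP flag: PPV %s%%, SPE %s%%.",
            fmt_pct(report$gn_flag$ppv), fmt_pct(report$gn_flag$specificity),
            fmt_pct(report$gp_flag$ppv), fmt_pct(report$gp_flag$specificity))
  )
  if (!is.null(report$angle)) {
    m <- report$angle$metrics
    lines <- c(lines, "",
      "## Gram angle rule",
      "",
      sprintf("Angle < %s deg predicts Gram-negative: sens %s%%, spec %s%%, PPV %s%%, NPV %s%% (n = %d).",
              format(report$angle$angle_cutoff), fmt_pct(m$sensitivity),
              fmt_pct(m$specificity), fmt_pct(m$ppv), fmt_pct(m$npv),
              nrow(report$angle$predictions)))
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
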