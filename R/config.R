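#' Default synthetic-cohort generator configuration
#'
#' Returns the calibrated default configuration for [generate_cohort()]. The
#' defaults encode the statistical structure of a hospital UTI-screening
#' cohort analysed with a Sysmex UF-5000 urine flow cytometer:
#'
#' * 31.8% of non-yeast specimens culture-positive for bacteria at
#'   \eqn{\ge 10^4} CFU/mL, of which 88.5% reach \eqn{\ge 10^5} CFU/mL;
#' * yeast in 31/823 of specimens;
#' * Gram-negative organisms in 78% of bacterial positives;
#' * log-normal BACT and WBC counts per stratum whose separation yields a
#'   BACT AUC of about 0.93 against \eqn{\ge 10^4} positivity;
#' * bivariate log-normal B_FSC/B_FLH channel intensities with Gram-class
#'   medians (31.6, 101.2) ch for Gram-negatives and (59.8, 87.6) ch for
#'   Gram-positives, spread so that a ratio cut-off of 0.55 operates at
#'   roughly 95% sensitivity / 93% specificity for Gram-negative calls;
#' * UF-5000 flag behaviour: samples failing the instrument's screening
#'   criteria (WBC \eqn{\ge} 10/µL and BACT \eqn{\ge} 100/µL) carry no
#'   bacterial-information flag, and eligible samples are flagged with
#'   per-class noise.
#'
#' @param seed Integer seed stored in the config; all downstream generation
#'   is deterministic given it.
#' @param n_samples Number of specimens to simulate (default 1522, a
#'   training + validation sized cohort).
#' @param ... Named overrides for any configuration field (see Details).
#'
#' @details Overridable fields: `prev_pos4`, `frac_pos5_given_pos4`,
#' `frac_gram_negative`, `yeast_fraction`, `two_species_prob`,
#' `cross_gram_given_two`, `contaminated_prob`, `training_fraction`,
#' `bact_params`, `wbc_params`, `fsc_flh_params`, `flag_noise`. Count
#' parameters are per-stratum log-scale location/spread pairs
#' (`meanlog`, `sdlog`); channel parameters are per-class lists with
#' `median_fsc`, `median_flh` (ch), `sdlog_fsc`, `sdlog_flh` and a
#' log-scale correlation `corr`. `flag_noise` holds one probability vector
#' over the five informative flags per true class (`GN`, `GP`, `negative`).
#'
#' @return A list of class `uf_config`.
#' @seealso [generate_cohort()], [simulate_flags()], [flag_noise_exact()]
#' @examples
#' cfg <- make_default_config(seed = 42)
#' cfg$prev_pos4
#' @export
make_default_config <- function(seed = 1L, n_samples = 1522L, ...) {
  config <- list(
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    prev_pos4 = 0.318,
    frac_pos5_given_pos4 = 0.885,
    frac_gram_negative = 0.78,
    yeast_fraction = 31 / 823,
    two_species_prob = 8 / 252,
    cross_gram_given_two = 0.25,
    contaminated_prob = 0,
    training_fraction = 823 / 1522,
    bact_params = list(
      negative = c(meanlog = 3.14, sdlog = 2.34),
      positive = c(meanlog = 8.55, sdlog = 2.92)
    ),
    wbc_params = list(
      negative = c(meanlog = 2.48, sdlog = 1.60),
      positive = c(meanlog = 3.80, sdlog = 1.80)
    ),
    fsc_flh_params = list(
      GN = list(median_fsc = 31.6, median_flh = 101.2,
                sdlog_fsc = 0.20, sdlog_flh = 0.28, corr = 0),
      GP = list(median_fsc = 59.8, median_flh = 87.6,
                sdlog_fsc = 0.11, sdlog_flh = 0.093, corr = 0),
      background = list(median_fsc = 45, median_flh = 92,
                        sdlog_fsc = 0.45, sdlog_flh = 0.35, corr = 0)
    ),
    flag_noise = list(
      GN = c(gram_pos = 0.07, gram_neg = 0.77, gram_pos_neg = 0.12,
             unclassified = 0.03, uti = 0.01),
      GP = c(gram_pos = 0.76, gram_neg = 0.06, gram_pos_neg = 0.12,
             unclassified = 0.00, uti = 0.06),
      negative = c(gram_pos = 0.40, gram_neg = 0.10, gram_pos_neg = 0.04,
                   unclassified = 0.15, uti = 0.31)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown)) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  config[names(dots)] <- dots
  structure(config, class = "uf_config")
}

#' Noise-free flag distributions
#'
#' Point-mass flag distributions for [simulate_flags()]: eligible
#' Gram-negative samples always receive the Gram-negative flag, Gram-positive
#' samples the Gram-positive flag, and culture-negative (or yeast) samples
#' the unclassified flag.
#'
#' @return A `flag_noise` list suitable for `make_default_config(flag_noise = ...)`.
#' @export
flag_noise_exact <- function() {
  pm <- function(which) {
    setNames(as.numeric(uf_informative_flags == which), uf_informative_flags)
  }
  list(GN = pm("gram_neg"), GP = pm("gram_pos"), negative = pm("unclassified"))
}

validate_config <- function(config) {
  if (!inherits(config, "uf_config")) {
    abort("`config` must be created by make_default_config()")
  }
  bad <- function(field, msg) {
    abort(sprintf("invalid configuration field `%s`: %s", field, msg))
  }
  if (!is.numeric(config$n_samples) || length(config$n_samples) != 1 ||
      is.na(config$n_samples) || config$n_samples < 1) {
    bad("n_samples", "must be a positive integer")
  }
  for (field in c("prev_pos4", "frac_pos5_given_pos4", "frac_gram_negative",
                  "yeast_fraction", "two_species_prob", "cross_gram_given_two",
                  "contaminated_prob", "training_fraction")) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(field, "must be a fraction in [0, 1]")
    }
  }
  for (field in c("bact_params", "wbc_params")) {
    for (stratum in c("negative", "positive")) {
      p <- config[[field]][[stratum]]
      if (is.null(p) || !all(c("meanlog", "sdlog") %in% names(p)) ||
          p[["sdlog"]] <= 0) {
        bad(field, sprintf("stratum `%s` needs meanlog and positive sdlog", stratum))
      }
    }
  }
  for (cls in c("GN", "GP", "background")) {
    p <- config$fsc_flh_params[[cls]]
    need <- c("median_fsc", "median_flh", "sdlog_fsc", "sdlog_flh", "corr")
    if (is.null(p) || !all(need %in% names(p))) {
      bad("fsc_flh_params", sprintf("class `%s` must supply %s",
                                    cls, paste(need, collapse = ", ")))
    }
    if (p$median_fsc <= 0 || p$median_flh <= 0 ||
        p$sdlog_fsc <= 0 || p$sdlog_flh <= 0) {
      bad("fsc_flh_params", sprintf("class `%s` medians and spreads must be positive", cls))
    }
    if (abs(p$corr) > 1) bad("fsc_flh_params", "correlation must lie in [-1, 1]")
  }
  for (cls in c("GN", "GP", "negative")) {
    p <- config$flag_noise[[cls]]
    if (is.null(p) || !setequal(names(p), uf_informative_flags) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      bad("flag_noise",
          sprintf("class `%s` must be a probability vector over %s",
                  cls, paste(uf_informative_flags, collapse = ", ")))
    }
  }
  invisible(config)
}

#' @export
print.uf_config <- function(x, ...) {
  cat("<uf_config>\n")
  cat(sprintf("  n_samples: %d  seed: %d\n", x$n_samples, x$seed))
  cat(sprintf("  prev_pos4: %.3f  frac_pos5|pos4: %.3f  frac GN: %.2f  yeast: %.4f\n",
              x$prev_pos4, x$frac_pos5_given_pos4, x$frac_gram_negative,
              x$yeast_fraction))
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A `uf_config` object.
#' @param path File path for the YAML mirror of the configuration.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a validated `uf_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$bact_params <- lapply(out$bact_params, as.list)
  out$wbc_params <- lapply(out$wbc_params, as.list)
  out$flag_noise <- lapply(out$flag_noise, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config <- make_default_config(seed = raw$seed %||% 1L,
                                n_samples = raw$n_samples %||% 1522L)
  for (field in intersect(names(raw), names(config))) {
    v <- raw[[field]]
    if (field %in% c("bact_params", "wbc_params", "flag_noise")) {
      v <- lapply(v, function(p) unlist(p))
    }
    config[[field]] <- v
  }
  validate_config(config)
  config
}
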