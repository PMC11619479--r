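## Organism pools used to label synthetic isolates. Frequencies loosely follow
## the rank order reported for hospital urine cultures (E. coli dominant among
## Gram-negatives, enterococci among Gram-positives).
gn_organisms <- c("Escherichia coli" = 0.60, "Klebsiella pneumoniae" = 0.25,
                  "Proteus mirabilis" = 0.10, "Pseudomonas aeruginosa" = 0.05)
gp_organisms <- c("Enterococcus faecium" = 0.35, "Enterococcus faecalis" = 0.35,
                  "Staphylococcus aureus" = 0.15, "Streptococcus agalactiae" = 0.15)

draw_organism <- function(n, gram) {
  pool <- if (gram == "GN") gn_organisms else gp_organisms
  sample(names(pool), n, replace = TRUE, prob = pool)
}

## Bivariate log-normal draw: medians on the natural scale, spreads and
## correlation on the log scale.
rbiv_lognorm <- function(n, params) {
  z1 <- rnorm(n)
  z2 <- params$corr * z1 + sqrt(1 - params$corr^2) * rnorm(n)
  tibble(
    b_fsc_ch = exp(log(params$median_fsc) + params$sdlog_fsc * z1),
    b_flh_ch = exp(log(params$median_flh) + params$sdlog_flh * z2)
  )
}

#' Generate a synthetic urine-screening cohort
#'
#' Simulates one specimen table (instrument readout) and one culture table
#' (gold standard) with the statistical structure described in
#' [make_default_config()]: culture status drawn from the configured
#' prevalences, per-stratum log-normal BACT/WBC counts, Gram-class bivariate
#' log-normal B_FSC/B_FLH channel intensities for bacterial positives and a
#' diffuse low-signal background for everything else. Flags are left unset;
#' see [simulate_flags()] or use [simulate_cohort()] for both steps.
#'
#' @param config A `uf_config` from [make_default_config()].
#' @return An object of class `uf_cohort`: a list with tibbles `samples`
#'   (sample_id, bact_per_ul, wbc_per_ul, ylc_per_ul, ec_per_ul, b_fsc_ch,
#'   b_flh_ch, flag, cohort) and `cultures` (sample_id, status, cfu_category,
#'   organism_1, gram_1, organism_2, gram_2), plus the `config` used.
#'   `cultures` also carries a derived `gram_class` column
#'   (GN / GP / Mixed / NA) used by downstream analyses.
#' @examples
#' cohort <- generate_cohort(make_default_config(seed = 1, n_samples = 200))
#' cohort
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_samples
  set.seed(config$seed)

  is_yeast <- runif(n) < config$yeast_fraction
  is_contam <- !is_yeast & runif(n) < config$contaminated_prob
  is_pos <- !is_yeast & !is_contam & runif(n) < config$prev_pos4
  status <- dplyr::case_when(
    is_yeast ~ "yeast",
    is_contam ~ "contaminated",
    is_pos ~ "positive",
    TRUE ~ "negative"
  )

  grew <- status %in% c("positive", "yeast", "contaminated")
  cfu <- ifelse(grew,
                ifelse(runif(n) < config$frac_pos5_given_pos4, "ge1e5", "1e4_to_1e5"),
                "lt1e4")

  # organisms: only bacterial positives get an identified organism list
  gram_1 <- rep(NA_character_, n)
  gram_2 <- rep(NA_character_, n)
  organism_1 <- rep(NA_character_, n)
  organism_2 <- rep(NA_character_, n)
  pos_idx <- which(status == "positive")
  if (length(pos_idx)) {
    g1 <- ifelse(runif(length(pos_idx)) < config$frac_gram_negative, "GN", "GP")
    two <- runif(length(pos_idx)) < config$two_species_prob
    cross <- two & runif(length(pos_idx)) < config$cross_gram_given_two
    g2 <- rep(NA_character_, length(pos_idx))
    g2[two] <- ifelse(cross[two], ifelse(g1[two] == "GN", "GP", "GN"), g1[two])
    gram_1[pos_idx] <- g1
    gram_2[pos_idx] <- g2
    for (g in c("GN", "GP")) {
      k1 <- g1 == g
      organism_1[pos_idx[k1]] <- draw_organism(sum(k1), g)
      k2 <- !is.na(g2) & g2 == g
      organism_2[pos_idx[k2]] <- draw_organism(sum(k2), g)
    }
  }
  # sample-level Gram class: cross-Gram two-species cultures are Mixed
  gram_class <- dplyr::case_when(
    is.na(gram_1) ~ NA_character_,
    !is.na(gram_2) & gram_2 != gram_1 ~ "Mixed",
    TRUE ~ gram_1
  )

  bact_stratum <- ifelse(status %in% c("positive", "contaminated"),
                         "positive", "negative")
  wbc_stratum <- ifelse(status == "negative", "negative", "positive")
  draw_count <- function(params, stratum) {
    p <- do.call(rbind, params)[stratum, , drop = FALSE]
    rlnorm(n, meanlog = p[, "meanlog"], sdlog = p[, "sdlog"])
  }
  bact <- draw_count(config$bact_params, bact_stratum)
  wbc <- draw_count(config$wbc_params, wbc_stratum)
  ylc <- ifelse(is_yeast, rlnorm(n, log(50), 1), 0)
  ec <- rlnorm(n, log(4), 1)

  # channel features: Gram-class law for bacterial positives (Mixed samples
  # follow their first organism), background otherwise
  chan_class <- ifelse(is.na(gram_1), "background", gram_1)
  chan <- tibble(b_fsc_ch = numeric(n), b_flh_ch = numeric(n))
  for (cls in c("GN", "GP", "background")) {
    idx <- which(chan_class == cls)
    if (length(idx)) chan[idx, ] <- rbiv_lognorm(length(idx),
                                                 config$fsc_flh_params[[cls]])
  }

  cohort_arm <- ifelse(runif(n) < config$training_fraction,
                       "training", "validation")
  sample_id <- sprintf("S%05d", seq_len(n))

  samples <- tibble(
    sample_id = sample_id,
    bact_per_ul = bact,
    wbc_per_ul = wbc,
    ylc_per_ul = ylc,
    ec_per_ul = ec,
    b_fsc_ch = chan$b_fsc_ch,
    b_flh_ch = chan$b_flh_ch,
    flag = NA_character_,
    cohort = cohort_arm
  )
  cultures <- tibble(
    sample_id = sample_id,
    status = status,
    cfu_category = cfu,
    organism_1 = organism_1,
    gram_1 = ifelse(is.na(gram_1), "none", gram_1),
    organism_2 = organism_2,
    gram_2 = ifelse(is.na(gram_2), "none", gram_2),
    gram_class = gram_class
  )
  structure(list(samples = samples, cultures = cultures, config = config),
            class = "uf_cohort")
}

#' Assign UF-5000-style bacterial-information flags
#'
#' Applies the instrument's UTI screening criteria — a sample is eligible for
#' a bacterial-information flag only when WBC \eqn{\ge} 10/µL **and**
#' BACT \eqn{\ge} 100/µL — then draws a flag for each eligible sample from
#' the per-class distribution in `config$flag_noise` (Gram-negative,
#' Gram-positive, or culture-negative/other). Ineligible samples receive
#' `"no_flag"`.
#'
#' @param cohort A `uf_cohort` from [generate_cohort()].
#' @param config Configuration controlling the flag distributions; defaults
#'   to the one stored in `cohort`.
#' @return The cohort with the `flag` column populated.
#' @export
simulate_flags <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "uf_cohort"))
  validate_config(config)
  set.seed(derive_seed(config$seed, 1))
  s <- cohort$samples
  eligible <- s$wbc_per_ul >= 10 & s$bact_per_ul >= 100
  cls <- dplyr::case_when(
    cohort$cultures$gram_class %in% c("GN", "GP") ~ cohort$cultures$gram_class,
    cohort$cultures$gram_class == "Mixed" ~ cohort$cultures$gram_1,
    TRUE ~ "negative"
  )
  flag <- rep("no_flag", nrow(s))
  for (g in c("GN", "GP", "negative")) {
    idx <- which(eligible & cls == g)
    if (length(idx)) {
      p <- config$flag_noise[[g]][uf_informative_flags]
      flag[idx] <- sample(uf_informative_flags, length(idx),
                          replace = TRUE, prob = p)
    }
  }
  cohort$samples$flag <- flag
  cohort
}

#' Generate a cohort and flag it in one step
#'
#' @inheritParams generate_cohort
#' @return A flagged `uf_cohort`.
#' @export
simulate_cohort <- function(config) {
  simulate_flags(generate_cohort(config))
}

#' @export
print.uf_cohort <- function(x, ...) {
  tab <- table(x$cultures$status)
  cat(sprintf("<uf_cohort> %d samples (seed %d)\n",
              nrow(x$samples), x$config$seed))
  cat("  culture status:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to delimited files
#'
#' Emits `samples.csv` and `cultures.csv` (RFC-4180, UTF-8) in the dialect
#' read back by [read_samples()] and [read_cultures()], plus `config.yaml`.
#'
#' @param cohort A `uf_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "uf_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"))
  readr::write_csv(dplyr::select(cohort$cultures, -"gram_class"),
                   file.path(dir, "cultures.csv"))
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
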