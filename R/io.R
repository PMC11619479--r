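sample_cols <- c("sample_id", "bact_per_ul", "wbc_per_ul", "ylc_per_ul",
                 "ec_per_ul", "b_fsc_ch", "b_flh_ch", "flag", "cohort")
culture_cols <- c("sample_id", "status", "cfu_category", "organism_1",
                  "gram_1", "organism_2", "gram_2")

read_checked <- function(path, required, char_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  spec <- do.call(readr::cols, c(
    list(.default = "d"),
    setNames(as.list(rep("c", length(intersect(char_cols, header)))),
             intersect(char_cols, header))
  ))
  x <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    dup <- x$sample_id[duplicated(x$sample_id)][1]
    abort(sprintf("%s: duplicate sample_id `%s`", basename(path), dup))
  }
  x
}

#' Read instrument sample and culture tables
#'
#' Readers for the delimited dialect written by [write_cohort()]:
#' `samples.csv` holds one UF-5000 readout per specimen (counts per µL,
#' B_FSC/B_FLH channel values, flag, cohort arm) and `cultures.csv` the
#' matching gold-standard culture result. Malformed rows (negative counts,
#' unknown enumerations) are rejected with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of sample records or culture records. Culture
#'   records gain a derived `gram_class` column (GN / GP / Mixed / NA).
#' @export
read_samples <- function(path) {
  x <- read_checked(path, sample_cols, c("sample_id", "flag", "cohort"))
  for (col in c("bact_per_ul", "wbc_per_ul", "ylc_per_ul", "ec_per_ul")) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("%s: row %d has invalid %s (must be a non-negative count)",
                    basename(path), bad[1], col))
    }
  }
  for (col in c("b_fsc_ch", "b_flh_ch")) {
    bad <- which(!is.na(x[[col]]) & x[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("%s: row %d has non-positive %s", basename(path), bad[1], col))
    }
  }
  bad <- which(!is.na(x$flag) & !x$flag %in% uf_flag_levels)
  if (length(bad)) {
    abort(sprintf("%s: row %d has unknown flag `%s` (valid: %s)",
                  basename(path), bad[1], x$flag[bad[1]],
                  paste(uf_flag_levels, collapse = ", ")))
  }
  x
}

#' @rdname read_samples
#' @export
read_cultures <- function(path) {
  x <- read_checked(path, culture_cols, culture_cols)
  bad <- which(!x$status %in% uf_status_levels)
  if (length(bad)) {
    abort(sprintf("%s: row %d has unknown status `%s` (valid: %s)",
                  basename(path), bad[1], x$status[bad[1]],
                  paste(uf_status_levels, collapse = ", ")))
  }
  bad <- which(!x$cfu_category %in% uf_cfu_levels)
  if (length(bad)) {
    abort(sprintf("%s: row %d has unknown cfu_category `%s` (valid: %s)",
                  basename(path), bad[1], x$cfu_category[bad[1]],
                  paste(uf_cfu_levels, collapse = ", ")))
  }
  bad <- which(x$status == "positive" & x$cfu_category == "lt1e4")
  if (length(bad)) {
    abort(sprintf("%s: row %d is culture-positive below 10^4 CFU/mL",
                  basename(path), bad[1]))
  }
  dplyr::mutate(x, gram_class = dplyr::case_when(
    .data$status != "positive" ~ NA_character_,
    .data$gram_2 %in% c("GN", "GP") & .data$gram_2 != .data$gram_1 ~ "Mixed",
    TRUE ~ .data$gram_1
  ))
}

#' Join samples to culture results for bacterial analyses
#'
#' Inner-joins the instrument and culture tables on `sample_id` and drops
#' yeast-positive and contaminated cultures, which are excluded from all
#' bacterial analyses (the classic 823 specimens \eqn{\to} 792 non-yeast
#' cultures denominator shift). Exclusion counts are reported via a message
#' and stored as attributes.
#'
#' @param samples,cultures Tibbles from [read_samples()] / [read_cultures()]
#'   or a [generate_cohort()] result.
#' @param quiet Suppress the exclusion-accounting message.
#' @return A joined tibble with attributes `n_yeast`, `n_contaminated`,
#'   `n_unmatched`.
#' @export
join_cohort <- function(samples, cultures, quiet = FALSE) {
  if (inherits(samples, "uf_cohort")) {
    cultures <- samples$cultures
    samples <- samples$samples
  }
  if (anyDuplicated(cultures$sample_id)) {
    abort("duplicate culture records for one sample_id")
  }
  joined <- dplyr::inner_join(samples, cultures, by = "sample_id")
  if (nrow(joined) == 0) abort("no overlapping sample_id between tables")
  n_unmatched <- nrow(samples) + nrow(cultures) - 2 * nrow(joined)
  n_yeast <- sum(joined$status == "yeast")
  n_contam <- sum(joined$status == "contaminated")
  out <- dplyr::filter(joined, !.data$status %in% c("yeast", "contaminated"))
  if (!quiet) {
    message(sprintf(
      "join_cohort: %d matched; excluded %d yeast and %d contaminated; %d unmatched ids",
      nrow(joined), n_yeast, n_contam, n_unmatched))
  }
  attr(out, "n_yeast") <- n_yeast
  attr(out, "n_contaminated") <- n_contam
  attr(out, "n_unmatched") <- n_unmatched
  out
}
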