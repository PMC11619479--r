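#' Reference tables from a published UF-5000 screening evaluation
#'
#' Small printed summary tables from a hospital evaluation of UF-5000
#' screening against urine culture (823 training specimens of which 31 were
#' yeast-positive, leaving 792 non-yeast cultures; 699 validation
#' specimens). They are bundled so that the package's metric machinery can
#' be exercised and regression-tested against published numbers without any
#' per-patient data.
#'
#' * `reference_screening_counts()` — screening performance tabulated at six
#'   nominal sensitivity levels for two culture-positivity criteria
#'   (\eqn{\ge 10^4} and \eqn{\ge 10^5} CFU/mL): the BACT cut-off (per µL)
#'   and the TP/FN/TN/FP counts at each level.
#' * `reference_flag_table()` — the 6 × 4 flag-versus-culture
#'   cross-tabulation of the 455 specimens with BACT \eqn{\ge} 42.2/µL
#'   (a [agreement_table()]).
#' * `reference_angle_table()` — the validation-cohort 2 × 2 classification
#'   of 176 culture-positive specimens (BACT \eqn{\ge} 42.2/µL) by the
#'   28° threshold angle.
#' * `reference_cohort_counts()` — training-cohort denominators: total
#'   specimens, yeast-positive, bacterial positives at each CFU criterion.
#'
#' @return A tibble (or `uf_agreement` for the flag table); see above.
#' @examples
#' counts <- reference_screening_counts()
#' sen95 <- counts[counts$positivity == "1e4" & counts$nominal_sensitivity == 95, ]
#' diagnostic_metrics(sen95)
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_screening_counts <- function() {
  tibble(
    positivity = rep(c("1e4", "1e5"), each = 6),
    nominal_sensitivity = rep(c(80, 85, 90, 95, 97.5, 99), 2),
    cutoff = c(440.8, 223.3, 109.7, 42.2, 29.1, 14.2,
               1001.1, 497.6, 247.1, 100.2, 44.4, 27.1),
    tp = c(202, 214, 227, 240, 246, 249, 178, 190, 201, 212, 217, 221),
    fn = c(50, 38, 25, 12, 6, 3, 45, 33, 22, 11, 6, 2),
    tn = c(484, 445, 402, 325, 293, 209, 524, 508, 470, 406, 339, 292),
    fp = c(56, 95, 138, 215, 247, 331, 45, 61, 97, 163, 230, 277)
  )
}

#' @rdname reference_tables
#' @export
reference_flag_table <- function() {
  counts <- matrix(
    #         GramPos GramNeg Mixed Negative
    c(26, 10, 2, 58,    # gram_pos flag
      2, 109, 0, 14,    # gram_neg flag
      4, 17, 0, 6,      # gram_pos_neg flag
      0, 4, 0, 22,      # unclassified
      2, 1, 0, 45,      # uti
      17, 46, 0, 70),   # no_flag
    nrow = 6, byrow = TRUE
  )
  agreement_table(counts = counts, bact_cutoff = 42.2)
}

#' @rdname reference_tables
#' @export
reference_angle_table <- function() {
  tibble(
    gram_class = c("GN", "GN", "GP", "GP"),
    angle_band = c("below", "at_or_above", "below", "at_or_above"),
    n = c(127, 15, 9, 25)
  )
}

#' @rdname reference_tables
#' @export
reference_cohort_counts <- function() {
  tibble(
    n_specimens = 823,
    n_yeast = 31,
    n_nonyeast = 792,
    n_pos_1e4 = 252,
    n_pos_1e5 = 223
  )
}

#' Confusion counts from the reference angle table
#'
#' Convenience reshaping of [reference_angle_table()] into a
#' [confusion()] object with Gram-negative as the positive class and the
#' below-threshold band as the positive call.
#'
#' @return A `uf_confusion`.
#' @export
reference_angle_confusion <- function() {
  t <- reference_angle_table()
  n <- function(g, b) t$n[t$gram_class == g & t$angle_band == b]
  confusion(tp = n("GN", "below"), fn = n("GN", "at_or_above"),
            fp = n("GP", "below"), tn = n("GP", "at_or_above"))
}
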