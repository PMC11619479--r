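#' Flag-versus-culture agreement table
#'
#' Cross-tabulates UF-5000 bacterial-information flags (rows: Gram Pos,
#' Gram Neg, Gram Pos/Neg, Unclassified, UTI, No flag) against culture
#' categories (columns: GramPos, GramNeg, Mixed, Negative) for samples at or
#' above a BACT cut-off. Two-species cultures of a single Gram class count
#' as that class; cross-Gram pairs form the Mixed column.
#'
#' @param data A joined cohort ([join_cohort()]) with `flag`, `bact_per_ul`,
#'   `status` and `gram_class` columns; alternatively supply `flags` and
#'   `cultures` vectors directly via [agreement_table()].
#' @param bact_cutoff Minimum BACT (per µL) for inclusion (default 42.2, a
#'   screening cut-off at 95% nominal sensitivity).
#' @return An object of class `uf_agreement`: integer matrix flags ×
#'   cultures with attribute `bact_cutoff`. `tidy()` returns the long-form
#'   counts.
#' @export
flag_crosstab <- function(data, bact_cutoff = 42.2) {
  need <- c("flag", "bact_per_ul", "status", "gram_class")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(sprintf("`data` is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  kept <- dplyr::filter(data, .data$bact_per_ul >= bact_cutoff,
                        .data$status %in% c("negative", "positive"))
  culture <- dplyr::case_when(
    kept$status == "negative" ~ "Negative",
    kept$gram_class == "GN" ~ "GramNeg",
    kept$gram_class == "GP" ~ "GramPos",
    kept$gram_class == "Mixed" ~ "Mixed"
  )
  agreement_table(kept$flag, culture, bact_cutoff = bact_cutoff)
}

#' @rdname flag_crosstab
#' @param flags Character vector of flag categories (see levels above).
#' @param cultures Character vector of culture categories.
#' @param counts Optional 6 × 4 matrix of known cell counts (rows in flag
#'   order, columns in culture order), used instead of the paired vectors.
#' @param bact_cutoff Cut-off recorded on the table (metadata only here).
#' @export
agreement_table <- function(flags = NULL, cultures = NULL, counts = NULL,
                            bact_cutoff = NA_real_) {
  if (is.null(counts)) {
    bad <- setdiff(unique(flags), uf_flag_levels)
    if (length(bad)) {
      abort(sprintf("unknown flag category `%s` (valid: %s)",
                    bad[1], paste(uf_flag_levels, collapse = ", ")))
    }
    bad <- setdiff(unique(cultures), uf_culture_levels)
    if (length(bad)) {
      abort(sprintf("unknown culture category `%s` (valid: %s)",
                    bad[1], paste(uf_culture_levels, collapse = ", ")))
    }
    if (length(flags) != length(cultures)) {
      abort("`flags` and `cultures` must be paired")
    }
    counts <- table(factor(flags, levels = uf_flag_levels),
                    factor(cultures, levels = uf_culture_levels))
    counts <- matrix(as.integer(counts), nrow = length(uf_flag_levels),
                     dimnames = dimnames(counts))
  } else {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(6, 4))) abort("`counts` must be 6 x 4")
    if (any(counts < 0) || any(counts != round(counts))) {
      abort("cell counts must be non-negative integers")
    }
    dimnames(counts) <- list(uf_flag_levels, uf_culture_levels)
    storage.mode(counts) <- "integer"
  }
  structure(counts, class = c("uf_agreement", class(counts)),
            bact_cutoff = bact_cutoff)
}

#' @export
print.uf_agreement <- function(x, ...) {
  cat(sprintf("<uf_agreement> n = %d (BACT cutoff %s /uL)\n",
              sum(x), format(attr(x, "bact_cutoff"))))
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.uf_agreement <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(flag = "Var1", culture = "Var2")
}

collapse_agreement <- function(x, collapsing = c("three_class", "four_class")) {
  collapsing <- match.arg(collapsing)
  m <- unclass(x)
  if (collapsing == "three_class") {
    flag_map <- c(gram_pos = "GP", gram_neg = "GN", gram_pos_neg = "Other",
                  unclassified = "Other", uti = "Other", no_flag = "Other")
    cult_map <- c(GramPos = "GP", GramNeg = "GN", Mixed = "Other",
                  Negative = "Other")
    levels <- c("GP", "GN", "Other")
  } else {
    flag_map <- c(gram_pos = "GP", gram_neg = "GN", gram_pos_neg = "Mixed",
                  unclassified = "Negative", uti = "Negative",
                  no_flag = "Negative")
    cult_map <- c(GramPos = "GP", GramNeg = "GN", Mixed = "Mixed",
                  Negative = "Negative")
    levels <- c("GP", "GN", "Mixed", "Negative")
  }
  out <- matrix(0L, length(levels), length(levels),
                dimnames = list(levels, levels))
  for (i in rownames(m)) for (j in colnames(m)) {
    out[flag_map[[i]], cult_map[[j]]] <- out[flag_map[[i]], cult_map[[j]]] + m[i, j]
  }
  out
}

#' Cohen's kappa for flag-versus-culture agreement
#'
#' Unweighted Cohen's kappa \eqn{\kappa = (P_o - P_e)/(1 - P_e)} on a square
#' table obtained by collapsing the 6 × 4 agreement table onto a shared
#' category set. The collapsing scheme is a named, reported parameter —
#' different published analyses collapse differently, and kappa depends
#' strongly on the choice:
#' * `"three_class"` (default): GP, GN, Other (flags Gram Pos/Neg,
#'   Unclassified, UTI and No flag, and cultures Mixed and Negative, all
#'   map to Other);
#' * `"four_class"`: GP, GN, Mixed, Negative (flag Gram Pos/Neg maps to
#'   Mixed; Unclassified, UTI and No flag map to Negative).
#'
#' @param x A `uf_agreement` table or a square numeric matrix (already
#'   collapsed; rows = rater 1, columns = rater 2).
#' @param collapsing Collapsing scheme (ignored for a plain square matrix).
#' @return An object of class `uf_kappa`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `collapsing`, `n` and the
#'   collapsed `table`. `kappa` is `NA` when expected agreement is 1.
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))
#' @export
cohen_kappa <- function(x, collapsing = c("three_class", "four_class")) {
  if (inherits(x, "uf_agreement")) {
    collapsing <- match.arg(collapsing)
    m <- collapse_agreement(x, collapsing)
  } else {
    m <- as.matrix(x)
    if (nrow(m) != ncol(m)) abort("`x` must be square once collapsed")
    collapsing <- "none"
  }
  n <- sum(m)
  if (n == 0) abort("agreement table is empty")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, collapsing = collapsing,
                 n = n, table = m),
            class = "uf_kappa")
}

#' @export
print.uf_kappa <- function(x, ...) {
  cat(sprintf("<uf_kappa> kappa = %s (Po = %.3f, Pe = %.3f, n = %d, scheme = %s)\n",
              if (is.na(x$kappa)) "undefined (Pe = 1)" else sprintf("%.3f", x$kappa),
              x$observed_agreement, x$expected_agreement, x$n, x$collapsing))
  invisible(x)
}

#' @export
tidy.uf_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, observed_agreement = x$observed_agreement,
         expected_agreement = x$expected_agreement,
         collapsing = x$collapsing, n = x$n)
}

#' @export
glance.uf_kappa <- function(x, ...) tidy(x)

#' Gram-flag performance as a binary test
#'
#' Binarizes the agreement table for one Gram class: the class's flag versus
#' all other rows, and the class's culture column versus all other columns
#' (the Mixed column counts as non-target; cross-Gram cultures are not an
#' unambiguous instance of either class).
#'
#' @param x A `uf_agreement` table.
#' @param target `"GN"` or `"GP"`.
#' @return A one-row tibble as from [diagnostic_metrics()], with `target`.
#' @examples
#' gram_flag_metrics(reference_flag_table(), "GN")  # PPV 87.2%
#' @export
gram_flag_metrics <- function(x, target = c("GN", "GP")) {
  target <- match.arg(target)
  if (!inherits(x, "uf_agreement")) abort("`x` must be a uf_agreement table")
  m <- unclass(x)
  flag_row <- if (target == "GN") "gram_neg" else "gram_pos"
  cult_col <- if (target == "GN") "GramNeg" else "GramPos"
  tp <- m[flag_row, cult_col]
  fp <- sum(m[flag_row, ]) - tp
  fn <- sum(m[, cult_col]) - tp
  tn <- sum(m) - tp - fp - fn
  dplyr::bind_cols(tibble(target = target),
                   diagnostic_metrics(confusion(tp = tp, fn = fn,
                                                tn = tn, fp = fp)))
}
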