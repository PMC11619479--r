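#' Confusion counts at a score cut-off
#'
#' `confusion_counts()` tabulates true/false positives and negatives for the
#' positivity rule *score \eqn{\ge} cutoff* (larger bacterial counts indicate
#' infection). `confusion()` builds the same object from known counts, e.g.
#' when re-analysing a published table.
#'
#' @param scores Numeric marker values (e.g. BACT per µL).
#' @param labels Binary condition labels (logical or 0/1); `TRUE`/1 is
#'   condition-positive (culture-positive).
#' @param cutoff Positivity cut-off; `-Inf` calls everything positive.
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return An object of class `uf_confusion` with fields `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_counts(c(1, 2, 3, 4), c(0, 0, 1, 1), cutoff = 3)
#' diagnostic_metrics(confusion(tp = 240, fn = 12, tn = 325, fp = 215))
#' @export
confusion_counts <- function(scores, labels, cutoff) {
  labels <- check_scores_labels(scores, labels)
  call_pos <- scores >= cutoff
  confusion(
    tp = sum(call_pos & labels),
    fn = sum(!call_pos & labels),
    tn = sum(!call_pos & !labels),
    fp = sum(call_pos & !labels)
  )
}

#' @rdname confusion_counts
#' @export
confusion <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "uf_confusion")
}

#' @export
print.uf_confusion <- function(x, ...) {
  cat(sprintf("<uf_confusion> TP=%d FN=%d TN=%d FP=%d (n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

#' @export
tidy.uf_confusion <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp)
}

as_confusion <- function(x) {
  if (inherits(x, "uf_confusion")) return(x)
  if (is.list(x) || is.data.frame(x)) {
    if (all(c("tp", "fn", "tn", "fp") %in% names(x))) {
      return(confusion(tp = x$tp[[1]], fn = x$fn[[1]],
                       tn = x$tn[[1]], fp = x$fp[[1]]))
    }
  }
  abort("expected a `uf_confusion` or a list/data frame with tp, fn, tn, fp")
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, and predictive values as percentages:
#' SEN = TP/(TP+FN), SPE = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#' Values are returned unrounded; reports conventionally round half-up to
#' one decimal ([round_half_up()]). A metric with a zero denominator is
#' `NA` (undefined), never 0.
#'
#' @param counts A `uf_confusion` (or anything coercible via tp/fn/tn/fp).
#' @return A one-row tibble with the four metrics (percent) and the counts.
#' @export
diagnostic_metrics <- function(counts) {
  c <- as_confusion(counts)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble(
    sensitivity = ratio(c$tp, c$tp + c$fn),
    specificity = ratio(c$tn, c$tn + c$fp),
    ppv = ratio(c$tp, c$tp + c$fp),
    npv = ratio(c$tn, c$tn + c$fn),
    tp = c$tp, fn = c$fn, tn = c$tn, fp = c$fp
  )
}

#' Culture workload reduction achieved by a screening cut-off
#'
#' When only screen-positive samples are sent for culture, the fraction of
#' cultures avoided is (TN+FN)/total and the price paid is the fraction of
#' avoided cultures that would have been positive, FN/(TN+FN).
#'
#' @inheritParams diagnostic_metrics
#' @return A one-row tibble: `culture_reduction` and `false_negative_rate`
#'   (percent, unrounded; `false_negative_rate` is `NA` when no sample is
#'   screened out), plus `n_avoided` and `n_total`.
#' @examples
#' workload_reduction(confusion(tp = 240, fn = 12, tn = 325, fp = 215))
#' @export
workload_reduction <- function(counts) {
  c <- as_confusion(counts)
  total <- c$tp + c$fn + c$tn + c$fp
  if (total == 0) abort("confusion counts are all zero")
  avoided <- c$tn + c$fn
  tibble(
    culture_reduction = 100 * avoided / total,
    false_negative_rate = if (avoided == 0) NA_real_ else 100 * c$fn / avoided,
    n_avoided = avoided,
    n_total = total
  )
}
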