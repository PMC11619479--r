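#' Round half away from zero
#'
#' Fixed-point rounding in which a digit of exactly 5 rounds up (away from
#' zero), matching how clinical tables are conventionally typeset. Base R's
#' [round()] rounds half to even, which would print e.g. 52.65 as 52.6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(c(96.439, 42.551, 52.652))
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## Coerce assorted binary label encodings (0/1, logical, two-level factor or
## character) to logical, erroring if not binary.
as_binary_labels <- function(labels, arg = "labels") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) > 2) {
      abort(sprintf("`%s` must be binary; found levels: %s",
                    arg, paste(lev, collapse = ", ")))
    }
    # positive class is the larger level only for 0/1-like strings;
    # otherwise require logical-style TRUE/FALSE
    if (all(lev %in% c("0", "1"))) return(labels == "1")
    if (all(lev %in% c("FALSE", "TRUE"))) return(labels == "TRUE")
    abort(sprintf("`%s` has character levels %s; supply logical or 0/1 labels",
                  arg, paste(lev, collapse = ", ")))
  }
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    u <- unique(labels)
    if (!all(u %in% c(0, 1))) {
      abort(sprintf("`%s` must be coded 0/1; found values: %s",
                    arg, paste(sort(u), collapse = ", ")))
    }
    return(labels == 1)
  }
  abort(sprintf("`%s` must be logical, 0/1 numeric, or a two-level factor", arg))
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) == 0) abort("`scores` must be non-empty")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) abort("missing values are not allowed")
  as_binary_labels(labels)
}

## Derive a secondary RNG seed from a user seed without integer overflow.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset) %% 2147483647)
}
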