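#' Repeat-length ("n.r") arithmetic
#'
#' STR repeat lengths are reported as `whole` complete repeat units plus an
#' optional `remainder` of extra bases, written `"n"` (e.g. `"12"`) when the
#' remainder is zero and `"n.r"` (e.g. `"13.2"`, a microvariant) otherwise.
#' The remainder is a base-pair count in `[0, repeat_size)`, not a decimal
#' fraction: `"13.2"` means 13 full units plus 2 bp.
#'
#' `rl_label()` builds labels from whole/remainder pairs, `rl_parse()` inverts
#' it, `rl_bp()` converts to total base pairs, `rl_units()` to (possibly
#' fractional) repeat units, `rl_is_partial()` tests for a microvariant, and
#' `rl_sort()` orders labels by (whole, remainder).
#'
#' @param whole integer vector of complete repeat counts.
#' @param rem integer vector of remainder base pairs.
#' @param x character vector of repeat-length labels.
#' @param repeat_size repeat unit size in bp.
#' @return `rl_label()` a character vector; `rl_parse()` a data.frame with
#'   columns `whole` and `rem`; `rl_bp()`/`rl_units()` numeric vectors;
#'   `rl_is_partial()` a logical vector; `rl_sort()` the sorted labels.
#' @examples
#' rl_label(c(12L, 13L), c(0L, 2L))  # "12" "13.2"
#' rl_parse("13.2")
#' rl_bp("13.2", 4)                  # 54
#' @name repeat_length
NULL

#' @rdname repeat_length
#' @export
rl_label <- function(whole, rem = 0L) {
  whole <- as.integer(whole)
  rem <- as.integer(rep_len(rem, length(whole)))
  ifelse(rem == 0L, as.character(whole), paste0(whole, ".", rem))
}

#' @rdname repeat_length
#' @export
rl_parse <- function(x) {
  x <- as.character(x)
  parts <- strsplit(x, ".", fixed = TRUE)
  whole <- suppressWarnings(
    vapply(parts, function(p) as.integer(p[[1L]]), integer(1)))
  rem <- suppressWarnings(vapply(parts, function(p) {
    if (length(p) > 1L) as.integer(p[[2L]]) else 0L
  }, integer(1)))
  if (anyNA(whole) || anyNA(rem)) {
    stop("invalid repeat-length label(s): ",
         paste(x[is.na(whole) | is.na(rem)], collapse = ", "))
  }
  data.frame(whole = whole, rem = rem)
}

#' @rdname repeat_length
#' @export
rl_bp <- function(x, repeat_size) {
  p <- rl_parse(x)
  p$whole * repeat_size + p$rem
}

#' @rdname repeat_length
#' @export
rl_units <- function(x, repeat_size) {
  rl_bp(x, repeat_size) / repeat_size
}

#' @rdname repeat_length
#' @export
rl_is_partial <- function(x) {
  rl_parse(x)$rem > 0L
}

#' @rdname repeat_length
#' @export
rl_sort <- function(x) {
  p <- rl_parse(x)
  x[order(p$whole, p$rem)]
}
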