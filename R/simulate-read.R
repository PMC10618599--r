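#' Build an error-free amplicon read for a simulated locus
#'
#' Reconstructs the full amplicon a [make_locus()] locus would emit for a
#' given repeat length: left flank, repeat region of the requested length
#' (with any fixed insert), right flank. Useful for constructing worked
#' examples and truth-known reads without running the full simulator.
#'
#' @param locus a locus built by [make_locus()] (it must carry the simulator
#'   structure attribute).
#' @param length_label repeat length to encode, e.g. `"13"` or `"13.2"`.
#' @return a single read sequence (character).
#' @export
locus_read <- function(locus, length_label) {
  st <- attr(locus, "structure")
  if (is.null(st)) {
    stop("locus ", locus$name, " lacks the simulator structure attribute; ",
         "build it with make_locus()")
  }
  bp <- rl_bp(length_label, locus$repeat_size)
  paste0(st$pre, region_seq(st$motif, bp, st$insert, st$split), st$post)
}
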