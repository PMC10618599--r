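# Bundled panel definitions. Locus names, motifs and reference counts are
# field-typical placeholders; anchors/flanks/references are synthetic,
# generated deterministically by make_locus. The two documented special cases
# are encoded: D13S317's A>T termination-variant SNP rule and D21S11's 13
# fixed non-repeat bases inside the repeat region.
HUMAN_PANEL_DEF <- list(
  list("CSF1PO",     "AGAT",   "12"),
  list("D13S317",    "TATC",   "11",
       right_flank_prefix = "AATCAATCATC", end_offset = 11L,
       snp_rule = list("TATCAATCATC", +1L),
       notes = "A>T termination variant adds one TATC repeat"),
  list("D16S539",    "GATA",   "11"),
  list("D18S51",     "AGAA",   "15"),
  list("D19S433",    "AAGG",   "13.2",
       notes = "reference carries a 2 bp partial repeat (microvariant 13.2)"),
  list("D2S1338",    "TGCC",   "19"),
  list("D21S11",     "TCTA",   "29", insert = "TCGTCTATCTATC",
       notes = "13 fixed non-repeat bases inside the repeat region (bp_modifier 13)"),
  list("D3S1358",    "TCTG",   "16"),
  list("D5S818",     "AGAT",   "11"),
  list("D7S820",     "GATA",   "10"),
  list("D8S1179",    "TCTA",   "13"),
  list("FGA",        "TTTC",   "21"),
  list("PentaD",     "AAAGA",  "10"),
  list("PentaE",     "AAAGA",  "7"),
  list("TH01",       "AATG",   "7"),
  list("TPOX",       "AATG",   "8"),
  list("vWA",        "TCTA",   "17"),
  list("Amelogenin", "GTCAGT", "1",
       notes = "sex locus: no repeat; unit = 6 bp X/Y amplicon length difference; X=1 and Y=2 units")
)

MOUSE_PANEL_DEF <- local({
  names <- c("18-3", "4-2", "5-5", "6-7", "9-2", "12-1", "15-3", "X-1",
             "1-1", "2-1", "3-2", "8-1", "11-2", "17-2", "19-2")
  motifs <- c("TAGA", "GATA", "TCTA", "AGAT", "GGAT", "TATC", "AGAA",
              "GATA", "TAGA", "CTTT", "TCTA", "GATA", "TCCA", "AGAT",
              "TTTC")
  reps <- c("17", "19", "14", "12", "16", "15", "20", "25", "13", "14",
            "12", "16", "15", "14", "18")
  Map(function(n, m, r) list(n, m, r), names, motifs, reps)
})

build_builtin_panel <- function(defs, species, seed0) {
  loci <- lapply(seq_along(defs), function(i) {
    e <- defs[[i]]
    extras <- e[-(1:3)]
    if (!is.null(extras$snp_rule)) {
      extras$snp_rule <- snp_rule(extras$snp_rule[[1L]], extras$snp_rule[[2L]])
    }
    do.call(make_locus, c(list(name = e[[1L]], motif = e[[2L]],
                               n_repeats = e[[3L]], panel = species,
                               seed = seed0 + i),
                          extras))
  })
  str_panel(loci, species = species,
            provenance = "synthetic placeholder anchors and flanks (make_locus); motifs and reference repeat counts are field-typical placeholders")
}

#' Bundled human and mouse STR panels
#'
#' `builtin_panel()` returns one of the two bundled panel scaffolds: the
#' 18-locus human cell-line authentication panel (17 CODIS-derived STR loci
#' plus the Amelogenin sex locus) or the 15-locus mouse panel. Locus names,
#' repeat motifs and reference repeat counts are field-typical; the anchor and
#' flank/reference sequences are *synthetic placeholders* generated
#' deterministically by [make_locus()] (primer-derived anchors are not
#' redistributed), so the bundled panels are usable for simulation and
#' pipeline testing out of the box, and for real data after substituting real
#' anchors via [read_locus_table()]. The same tables ship as comma-separated
#' files under `inst/extdata` (`panel_human_synthetic.csv`,
#' `panel_mouse_synthetic.csv`).
#'
#' The human panel encodes the two documented special cases: the D13S317 SNP
#' rule (`TATCAATCATC:+1`, the A>T termination variant that adds a TATC
#' repeat, with the end anchor placed beyond the termination sequence and
#' `bp_modifier` 11) and the D21S11 `bp_modifier` of 13 (fixed non-repeat
#' bases inside the repeat region). Amelogenin has no repeat; it is
#' represented with a 6 bp unit equal to the X/Y amplicon length difference,
#' calling X as 1 and Y as 2 units (see its `notes`).
#'
#' @param species `"human"` or `"mouse"`.
#' @return a [str_panel()] whose loci carry simulator structure (usable in
#'   [sim_spec()]); `builtin_panels()` returns `list(human = ..., mouse = ...)`.
#' @export
builtin_panel <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  if (species == "human") build_builtin_panel(HUMAN_PANEL_DEF, "human", 1000L)
  else build_builtin_panel(MOUSE_PANEL_DEF, "mouse", 2000L)
}

#' @rdname builtin_panel
#' @export
builtin_panels <- function() {
  list(human = builtin_panel("human"), mouse = builtin_panel("mouse"))
}
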