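# Shared fixtures: all synthetic, generated in code with fixed seeds.

# A plain tetranucleotide test locus (no offsets, no SNP rule).
fix_locus <- function(name = "LOC1", motif = "TATC", n_repeats = 13,
                      seed = 101, ...) {
  make_locus(name, motif, n_repeats = n_repeats, seed = seed, ...)
}

# Small multiplex panel of distinct-motif loci.
fix_panel <- function(n = 6L, seed = 300L) {
  motifs <- c("TATC", "AGAT", "AATG", "TCTA", "GGAA", "TGCC")[seq_len(n)]
  loci <- lapply(seq_len(n), function(i) {
    make_locus(paste0("LOC", i), motifs[i], n_repeats = 10 + i,
               seed = seed + i)
  })
  str_panel(loci, species = "custom")
}

# Independent brute-force oracle: count whole motif units by exhaustive
# left-to-right scan of a span, then leftover bases. Deliberately naive and
# free of the package's modular arithmetic.
oracle_repeat_length <- function(span, motif) {
  whole <- 0L
  pos <- 1L
  size <- nchar(motif)
  while (pos + size - 1L <= nchar(span) &&
         substr(span, pos, pos + size - 1L) == motif) {
    whole <- whole + 1L
    pos <- pos + size
  }
  list(whole = whole, rem = nchar(span) - (pos - 1L))
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Reference sample_profile for a pure (error-free) line: simulate and call.
ref_profile <- function(panel, genotype, sample_name, seed,
                        reads_per_locus = 2000L) {
  spec <- sim_spec(panel, list(sim_component(genotype, 1)),
                   reads_per_locus = reads_per_locus,
                   stutter = stutter_model(0, 1, 0, 0), seed = seed)
  sim <- simulate_sample(spec)
  call_sample(call_reads(sim$reads, panel), sample_name = sample_name)
}

# Fabricate a sample_profile from allele sets alone (equal read counts), for
# concordance tests that don't need spectra.
mk_sample_profile <- function(alleles_by_locus, sample_name = "fab") {
  genotypes <- lapply(names(alleles_by_locus), function(nm) {
    al <- alleles_by_locus[[nm]]
    calls <- data.frame(length = rep(al, each = 500L),
                        span = "")
    call_genotype(classify_profile(tabulate_calls(calls, locus = nm)))
  })
  names(genotypes) <- names(alleles_by_locus)
  structure(list(sample = sample_name, profiles = NULL,
                 genotypes = genotypes, tally = NULL),
            class = "sample_profile")
}

# One-locus major/minor mixture world used by the mixture tests and the
# sensitivity checks: major carries 13/14, minor 15/16 (one and two repeats
# longer than the major's upper allele).
mixture_world <- function() {
  locus <- make_locus("MIXLOC", "TATC", n_repeats = 13, seed = 777)
  panel <- str_panel(list(locus), species = "custom")
  major_gt <- list(MIXLOC = genotype_entry(c("13", "14")))
  minor_gt <- list(MIXLOC = genotype_entry(c("15", "16")))
  major <- ref_profile(panel, major_gt, "major", seed = 11)
  minor <- ref_profile(panel, minor_gt, "minor", seed = 12)
  list(panel = panel, major_gt = major_gt, minor_gt = minor_gt,
       major = major, minor = minor,
       informative = informative_alleles(major, minor, panel))
}

# Simulate a minor:major = 1:ratio mixture and run detection with default
# thresholds. Stutter concentrated at -1 repeat so the +1/+2 informative
# positions carry only partial-artifact background.
mixture_detect <- function(world, ratio, seed, reads_per_locus = 100000L,
                           stutter = stutter_model(0.04, 1, 5e-4, 0.003)) {
  w_minor <- 1 / (ratio + 1)
  spec <- sim_spec(world$panel,
                   list(sim_component(world$major_gt, 1 - w_minor),
                        sim_component(world$minor_gt, w_minor)),
                   reads_per_locus = reads_per_locus,
                   stutter = stutter, seed = seed)
  sim <- simulate_sample(spec)
  run <- call_reads(sim$reads, world$panel)
  res <- estimate_minor_fraction(run, world$informative)
  detect_contamination(res)
}

allele_set_of <- function(profile, locus) {
  g <- profile$genotypes[[locus]]
  if (nrow(g$alleles)) g$alleles$length else character(0)
}
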