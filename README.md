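# strcall

Short tandem repeat (STR) profiling from amplicon deep-sequencing reads, for
cell line authentication and cross-contamination monitoring.

Cell lines are routinely authenticated by genotyping a panel of STR loci —
genomic stretches of 2–6 bp motifs repeated in tandem, whose repeat count is
the allele. Conventional capillary-electrophoresis typing reads fragment
lengths; sequencing the amplicons instead yields per-read resolution, full
sequence context, and quantitative read counts that expose copy-number
imbalance and minor contaminating lines. `strcall` implements the analysis
side of that workflow:

- **Anchor-based repeat calling.** Each locus is defined by a start and end
  anchor sequence flanking the repeat region. For every read (searched in
  both orientations), the inter-anchor distance *d* is measured, a fixed
  `bp_modifier` *m* is subtracted, and the repeat length is
  *d − m = k·s + r*, with *s* the repeat unit size: *k* whole repeats plus
  *r* leftover bases, reported as `k` or the microvariant `k.r` (e.g.
  `13.2`). A per-locus SNP rule can add repeats when a flanking variant
  (e.g. a `TATCAATCATC` termination) creates a repeat unit the distance
  cannot see.
- **Classification.** Per locus, repeat lengths at ≥ 10% of reads are
  alleles; sub-threshold whole-repeat lengths are PCR stutter
  (predominantly one repeat short); sub-threshold partial-repeat lengths are
  noise.
- **Genotypes and copy ratios.** Allele read-count ratios are matched
  against 1:1, 3:2, 2:1, 3:1 — a ~2:1 allelic ratio indicates three copies
  of the locus.
- **Concordance.** Profile comparison as "matched at *m* of *n* loci".
- **Mixture detection.** A minor contributor is detected through
  *informative alleles* — repeat lengths unique to the minor line — with a
  pooled, dose-corrected minor-fraction estimate and a read-count/fraction
  detection rule sensitive down to 1:200 dilutions at 100,000 reads per
  locus.
- **Simulation.** A seeded generator produces FASTQ reads with a
  parameterised stutter/noise model plus truth tables, so every stage is
  testable end to end without external data.

Bundled panels: an 18-locus human scaffold (17 CODIS-derived loci +
Amelogenin) and a 15-locus mouse scaffold. Their anchors and reference
sequences are synthetic placeholders (real primer-derived anchors are not
redistributed); supply your own nine-column locus table for real data.

## Worked example

```r
library(strcall)

# A synthetic two-locus panel and a diploid sample with a microvariant allele
panel <- str_panel(list(
  make_locus("D8X", "TCTA", 13, seed = 1),
  make_locus("D19X", "AAGG", 14, seed = 2)))
gts <- list(D8X  = genotype_entry(c("13", "15")),
            D19X = genotype_entry(c("13.2", "14")))
spec <- sim_spec(panel, list(sim_component(gts, 1)),
                 reads_per_locus = 5000, seed = 42)
fq <- tempfile(fileext = ".fastq.gz")
invisible(simulate_sample(spec, fastq = fq))

run <- process_reads(fq, panel)
profile <- call_sample(run, sample_name = "demo")
profile$profiles$D8X
#> <locus_profile> D8X: 4695 reads
#>   11            11    0.23%  stutter
#>   12            64    1.36%  stutter
#>   13          2251   47.94%  allele
#>   14            93    1.98%  stutter
#>   14.3           1    0.02%  noise
#>   15          2259   48.12%  allele
#>   16            16    0.34%  stutter
profile
#> <sample_profile> demo (2 loci)
#>   D8X          13/15  [1:1]
#>   D19X         13.2/14  [1:1]
```

Read it as: at locus D8X, 13 and 15 repeats are the called alleles at a
balanced 1:1 read ratio; the 12- and 14-repeat classes are stutter (one
repeat below each allele, ~2% of reads); rare partial-repeat lengths are
noise. At D19X the microvariant `13.2` (13 repeats + 2 bp) is a genuine
allele. A shell interface over the same functions is installed at
`exec/strcall` (subcommands `profile`, `simulate`, `compare`, `mixture`,
`panel`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from freshly simulated data, the package's headline checks: the
SNP-rule repeat correction on a termination-variant read pair, the
bp_modifier flank correction, the deepest dilution of the
1:1 … 1:1000 mixture series still detected across seeds, and the mean
allelic read-count ratio of a simulated three-copy locus — and writes them
as JSON.
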