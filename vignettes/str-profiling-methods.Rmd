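---
title: "Methods: anchor-based STR profiling, error classification and mixture detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-based STR profiling, error classification and mixture detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strcall)
```

## The measurement model

An STR locus is typed from amplicon reads by pure distance arithmetic, not
alignment. Each locus definition carries a *start anchor* and an *end anchor*
— short exact sequences in the flanks of the repeat region — plus three
correction parameters. For a read in which each anchor occurs exactly once
(either in the read or in its reverse complement, consistently), the caller
measures the number of bases strictly between the end of the start anchor and
the beginning of the end anchor, giving the raw distance $d$. The repeat
length is then

$$ d - m = k s + r, \qquad 0 \le r < s, $$

where $s$ is the repeat unit size (2–6 bp), $m$ the locus's `bp_modifier`,
$k$ the whole-repeat count and $r$ the remainder, displayed as `k` when
$r = 0$ and as the microvariant label `k.r` otherwise (`13.2` = 13 units
plus 2 bp — a base-pair count, not a decimal fraction).

`bp_modifier` absorbs every fixed non-repeat base inside the measured span:
anchors deliberately placed a few bases away from the repeat region (to avoid
known flank SNPs), and constant non-repeat stretches inside the repeat region
that some loci carry. If the start anchor lands 5 bp upstream of the repeats,
`bp_modifier = 5` removes exactly those 5 bp; the bundled D21S11 scaffold
uses `bp_modifier = 13` for its 13 fixed internal bases.

Some loci have flank SNPs that *create* a repeat unit. The classic case is a
TATC-repeat locus terminating right before `AATCAATCATC`; an A>T variant at
its first base yields `TATCAATCATC`, which contains one extra TATC that the
anchor distance cannot see (the anchors sit beyond the termination region, so
$d$ is unchanged). The locus's SNP rule — a trigger sequence and a signed
increment — adds the increment to $k$ whenever the trigger occurs in the
oriented read. The bundled D13S317 scaffold encodes `TATCAATCATC:+1`.

Read-level outcomes are kept strictly separate: a *call*; a *no-call* (an
anchor missing, or wrongly ordered); *ambiguous* (an anchor occurring more
than once in one orientation, both orientations matching, or — in panel mode
— more than one locus calling the read), which is discarded but counted; and
*malformed* (anchors found but a negative corrected distance), counted
separately. The four categories always partition the input, and the whole
pipeline is quality-score-free: matching is exact, `N` never matches, and an
optional mean-quality read filter and an optional mismatch-tolerant anchor
mode exist but are off by default because they alter stutter/noise
statistics.

## Error taxonomy and allele calling

Amplicon STR data carry two characteristic artifact classes. *Stutter* reads
deviate from a true allele by whole repeat units — predominantly one unit
short, from polymerase slippage — at low frequency. *Noise* reads carry
partial repeats (non-integer lengths) from sequencing errors or off-target
amplification. Per locus the caller tabulates the read-count spectrum over
repeat lengths and classifies with a single threshold, `allele_min_frac`
(default 0.10, directly from the sub-10% character of stutter):

* length at ≥ 10% of locus reads → **allele** — including partial-repeat
  lengths, because genuine microvariant alleles such as `13.2` exist and
  reach allelic frequency;
* whole-repeat length below threshold → **stutter**;
* partial-repeat length below threshold → **noise**.

A profile in which nothing reaches the threshold is flagged `no allele`
rather than forced. The threshold is configurable but mixture work does not
lower it: sub-threshold evidence is handled by the mixture module on the
*unclassified* spectra.

A deliberate resolution worth stating: for frequencies between roughly 5%
and 10% there is no unambiguous way to distinguish a weak microvariant
allele from noise with one sample; the package applies the single ≥ 10% rule
uniformly and reports the full spectrum so a user can inspect borderline
lengths. Ties at the threshold are kept deterministic (both lengths become
alleles, ordered by repeat length).

Genotypes renormalise allele counts over allele reads. With two or more
alleles the top-two read-count ratio is matched against the small-integer
copy ratios $\{1{:}1,\ 3{:}2,\ 2{:}1,\ 3{:}1\}$ and reported when the
absolute deviation is ≤ 0.2, else `undetermined`; a ~2:1 allelic ratio is
the signature of a three-copy locus. The candidate set and tolerance are the
package's own choice — the ratio evidence only supports small integer
states at realistic depths — and loci below `min_reads` (default 100) are
flagged `low-coverage` rather than suppressed.

## Mixture detection

Two cell lines sharing a panel are distinguished inside a mixture through
*informative alleles*: repeat lengths in the minor line's reference profile
absent from the major's at the same locus. Each is annotated with its offset
from the nearest major allele (ties break toward the negative side). An
informative allele exactly one repeat *below* a major allele sits on the
major's dominant −1 stutter position and is excluded from estimation by
default (`stutter_colliding`); alleles one to two repeats *above* the major's
are the preferred markers because the +1 stutter rate is an order of
magnitude lower.

The pooled minor-fraction estimator is dose-corrected: a heterozygous minor
contributes each informative allele in only half of its genome fraction, so
with informative read count $x_i$ out of $n_i$ locus reads and allele dose
$d_i$ (copy fraction within the minor genotype),

$$ \hat{f} = \frac{\sum_i x_i}{\sum_i n_i d_i}, $$

with a Clopper–Pearson interval computed on the pooled count against the raw
read total and rescaled by the same dose factor (an approximation —
informative counts across loci are treated as one binomial; adequate at the
depths involved). Detection is a per-allele rule, not a test on the pooled
estimate: *detected* iff at least one non-colliding informative allele
reaches both `min_frac` (default 0.002) and `min_reads` (default 10). The
defaults are calibrated once against the declared simulator noise model (see
below) so that a 1:200 mixture at 100,000 reads per locus is detected while
1:1000 — whose expected per-allele fraction, 0.0005, sits at the simulator's
partial-noise background — is not. They are thresholds of this package, not
measured properties of any instrument; with real data the false-positive
floor should be re-estimated from pure-line controls.

## The simulator as the stated world

Every empirical claim in the test suite is made against the bundled
generator, so its parameters are fixed, not tuned. A simulated locus is
`left flank + repeat region + right flank` with anchors cut from the flanks
(constraints: no motif tandem run in a flank, each anchor unique in the
reference, validation must pass). Per read: a mixture component is drawn by
weight, an allele by copy-number fraction, then

* a stutter shift with probability `stutter_prob` (default 0.04): −1 repeat
  with weight `minus_one_weight` (default 0.8), the remainder split equally
  between +1 and −2. The −1 dominance is the documented character of
  stutter; the exact shape of the minority tail is this package's choice and
  fully parameterisable;
* a partial-repeat artifact with probability `partial_noise_prob` (default
  5×10⁻⁴): insertion or deletion of 1..s−1 bp in the span;
* per-base substitutions at `substitution_rate` (default 0.003), which never
  change the measured length but destroy anchor matches (~6% of reads for
  two 10 bp anchors), thinning calls uniformly across lengths.

Reads are emitted with uniform Phred-30 qualities (calling ignores quality)
and are byte-reproducible from the seed; a truth table records every read's
component, locus, true and emitted length. `expected_spectrum()` gives the
closed-form emitted-length distribution (weights × copy fractions × stutter
× partial), which the empirical spectra match to total-variation distance
< 0.01 at 100,000 reads.

What the simulator does *not* emulate — and hence what a green test does not
establish: locus-, length- and GC-dependent stutter rates (real stutter
grows with allele length), PCR chimeras between alleles, quality-correlated
Illumina error profiles, amplification bias between loci and between alleles
of different lengths, and index hopping between samples. The mixture
sensitivity boundary in particular (detected at 1:200, not at 1:1000) is a
property of the declared noise model at the declared depth, calibrated to
match the sensitivity a sequencing-based assay can reach, not a measurement
of one.

Mixture-sensitivity simulations use `minus_one_weight = 1` (stutter entirely
at −1): with any +1 stutter mass, an informative allele one repeat above a
major allele would sit on a stutter background comparable to deep-dilution
signal, and the 1:1000 negative control would not be meaningful. The package
default stays 0.8 so that profiles show a realistic minority tail.

## Numerical and interface choices

* Repeat lengths are exact integer pairs (whole, remainder); no floating
  arithmetic touches allele identity. Ordering is lexicographic on (whole,
  remainder).
* Percentages are kept full-precision internally and serialized with two
  decimals; microvariants appear as `"n.r"` strings everywhere.
* Paired reads are scanned independently, never merged; a locus covered by
  both mates is counted twice, which leaves percentage-based statistics
  unbiased when coverage is uniform.
* Amelogenin (no repeat) reuses the one calling engine: the repeat unit is
  set to the 6 bp X/Y amplicon length difference so X and Y type as 1 and 2
  units.
* Degenerate inputs are first-class: empty FASTQ gives a zero tally; a
  zero-call locus gives an empty profile flagged `dropout-suspect` at
  genotype level; identical reference profiles give an explicit
  "indistinguishable" warning in mixture mode.
* Bundled panels are synthetic scaffolds: real per-locus anchors are
  primer-derived and not redistributable, so `make_locus()` generates
  deterministic placeholder references that exercise every code path
  (including the D13S317 SNP rule and D21S11 internal bases). Users load
  real panels through the nine-column table, whose parse/serialize
  round-trip is field-exact.
* Reports (CSV + versioned JSON) contain no timestamps; repeated runs on
  identical inputs are byte-identical.

## Known limitations

Exact anchor matching discards any read with a sequencing error inside an
anchor — a sensitivity cost accepted to keep stutter/noise statistics
interpretable. The copy-ratio candidate set stops at 3:1. Mixtures are
modelled with exactly two contributors; three-plus-contributor deconvolution
and likelihood-ratio interpretation are out of scope, as are population
match statistics.
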