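Package: strcall
Title: Short Tandem Repeat Profiling from Amplicon Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Anchor-based short tandem repeat (STR) genotyping from amplicon
    deep-sequencing reads. Locates a locus's flanking anchor sequences in each
    read, converts the inter-anchor distance into a repeat-length call
    (including microvariant "n.r" alleles and SNP-aware repeat corrections),
    aggregates calls into per-locus spectra with allele/stutter/noise
    classification, calls genotypes with integer copy-ratio estimates, compares
    profiles for cell line authentication, and detects minor contributors in
    mixed samples via informative alleles. Ships human (18-locus) and mouse
    (15-locus) panel scaffolds with synthetic placeholder anchors, and a
    seeded read simulator with a parameterised PCR stutter and noise model for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stringi,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
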