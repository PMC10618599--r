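# Hand-built locus: anchors chosen to be motif-free, span fully controlled.
SA <- "GGATCCGTAA"
EA <- "CCTAGGATTC"
hand_locus <- function(bp_modifier = 0L, snp = NULL) {
  str_locus("HAND", SA, EA, 4L, bp_modifier = bp_modifier, snp_rule = snp)
}
hand_read <- function(span) paste0("ACGTGA", SA, span, EA, "TGCACT")

test_that("exact repeat multiples and microvariants are called from the span", {
  loc <- hand_locus()
  call <- scan_read(hand_read(strrep("TATC", 10)), loc)
  expect_equal(call$status, "call")
  expect_equal(call$length, "10")
  expect_equal(call$orientation, "forward")
  expect_false(call$snp_applied)
  expect_equal(call$span, strrep("TATC", 10))

  # corrected inter-anchor distance of 46 bp at unit size 4 -> 11 whole + 2
  call2 <- scan_read(hand_read(paste0(strrep("TATC", 11), "TA")), loc)
  expect_equal(call2$length, "11.2")
  expect_equal(call2$whole, 11L)
  expect_equal(call2$rem, 2L)

  # missing end anchor -> no-call
  expect_null(scan_read(paste0("ACGTGA", SA, strrep("TATC", 10)), loc))
})

test_that("SNP rule adds its increment when the trigger is present", {
  loc <- hand_locus(snp = snp_rule("TATCAATCATC", +1L))
  base <- paste0(strrep("TATC", 10), "GG")
  with_trigger <- hand_read(paste0(base, "TATCAATCATCGG"))
  without_trigger <- hand_read(paste0(base, "AATCAATCATCGG"))
  c1 <- scan_read(with_trigger, loc)
  c2 <- scan_read(without_trigger, loc)
  expect_true(c1$snp_applied)
  expect_false(c2$snp_applied)
  expect_equal(c1$whole - c2$whole, 1L)
})

test_that("calls are strand-invariant", {
  loc <- hand_locus()
  read <- hand_read(strrep("TATC", 10))
  rc <- strcall:::revcomp(read)
  call <- scan_read(rc, loc)
  expect_equal(call$length, "10")
  expect_equal(call$orientation, "reverse-complement")

  # property: 1000 random reads (some with planted spans) agree with their
  # reverse complements in status and called length
  set.seed(42)
  reads <- c(replicate(500, random_read(80)),
             replicate(500, hand_read(strrep("TATC", sample(5:15, 1)))))
  fwd <- scan_reads(reads, loc)
  rev <- scan_reads(strcall:::revcomp(reads), loc)
  expect_equal(rev$status, fwd$status)
  expect_equal(rev$length, fwd$length)
})

test_that("repeated anchors and negative corrected distances are quarantined", {
  loc <- hand_locus()
  twice <- paste0("ACGTGA", SA, "TATCTATC", SA, "TATC", EA)
  expect_equal(scan_read(twice, loc)$status, "ambiguous")

  # bp_modifier larger than the span -> malformed, not a call
  deep <- hand_locus(bp_modifier = 50L)
  expect_equal(scan_read(hand_read(strrep("TATC", 10)), deep)$status,
               "malformed")
})

test_that("span edits and bp_modifier shift calls by exact amounts", {
  base_span <- strrep("TATC", 8)
  for (extra in 1:3) {
    call <- scan_read(hand_read(paste0(base_span, strrep("TATC", extra))),
                      hand_locus())
    expect_equal(call$whole, 8L + extra)
  }
  # increasing bp_modifier by d reduces the corrected distance by exactly d
  read <- hand_read(strrep("TATC", 10))
  for (d in c(0L, 1L, 4L, 9L)) {
    call <- scan_read(read, hand_locus(bp_modifier = d))
    expect_equal(call$whole * 4L + call$rem, 40L - d)
  }
})

test_that("reads are assigned to exactly one panel locus", {
  panel <- fix_panel(6L)
  target <- panel[["LOC3"]]
  read <- locus_read(target, "12")
  res <- assign_read(read, panel)
  expect_equal(res$status, "assigned")
  expect_equal(res$locus, "LOC3")
  expect_equal(res$call$length, "12")

  set.seed(7)
  expect_equal(assign_read(random_read(120), panel)$status, "unassigned")

  # adversarial read carrying two loci's anchor pairs -> ambiguous
  chimera <- paste0(locus_read(panel[["LOC1"]], "11"),
                    locus_read(panel[["LOC2"]], "12"))
  expect_equal(assign_read(chimera, panel)$status, "ambiguous")
})

test_that("FASTQ processing is a closed loop with the simulator", {
  panel <- fix_panel(6L)
  gts <- lapply(seq_len(6L), function(i) genotype_entry(c(10 + i, 12 + i)))
  names(gts) <- names(panel)
  spec <- sim_spec(panel, list(sim_component(gts, 1)),
                   reads_per_locus = 500L,
                   stutter = stutter_model(0, 1, 0, 0), seed = 99)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  truth <- simulate_sample(spec, fastq = fq)$truth

  run <- process_reads(fq, panel)
  expect_equal(run$tally[["total"]], 3000L)
  expect_equal(run$tally[["assigned"]], 3000L)
  expect_equal(run$tally[["unassigned"]], 0L)
  # per-locus call counts equal the simulator's truth-table counts
  truth_counts <- table(truth$locus)
  for (nm in names(panel)) {
    expect_equal(nrow(run$calls[[nm]]), unname(truth_counts[[nm]]))
    expect_equal(sort(run$calls[[nm]]$length),
                 sort(truth$emitted_length[truth$locus == nm]))
  }
})

test_that("read categories always partition the input", {
  panel <- fix_panel(3L)
  gts <- lapply(1:3, function(i) genotype_entry(10 + i))
  names(gts) <- names(panel)
  spec <- sim_spec(panel, list(sim_component(gts, 1)),
                   reads_per_locus = 400L,
                   stutter = stutter_model(0.1, 0.8, 0.05, 0.02), seed = 1)
  sim <- simulate_sample(spec)
  set.seed(2)
  reads <- c(sim$reads, replicate(100, random_read(150)))
  run <- call_reads(reads, panel)
  t <- run$tally
  expect_equal(t[["assigned"]] + t[["unassigned"]] + t[["ambiguous"]] +
                 t[["malformed"]], t[["total"]])
  expect_equal(t[["total"]], length(reads))
})

test_that("empty and unreadable FASTQ inputs are handled", {
  panel <- fix_panel(2L)
  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  run <- process_reads(empty, panel)
  expect_equal(run$tally[["total"]], 0L)
  expect_equal(sum(vapply(run$calls, nrow, integer(1))), 0L)

  expect_error(process_reads("/nonexistent/reads.fastq", panel), "not found")
  garbled <- withr::local_tempfile(fileext = ".fastq")
  writeLines("not a fastq record", garbled)
  expect_error(process_reads(garbled, panel), basename(garbled))
})
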