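mk_calls <- function(counts) {
  data.frame(length = rep(names(counts), counts), span = "")
}

test_that("tabulation computes the spectrum and percentages", {
  prof <- tabulate_calls(mk_calls(c("12" = 930L, "11" = 40L, "13" = 22L,
                                    "12.2" = 8L)), locus = "T1")
  expect_equal(prof$total, 1000L)
  # keys ordered by repeat length (whole, then remainder)
  expect_equal(names(prof$spectrum), c("11", "12", "12.2", "13"))
  expect_equal(unname(prof$percentages[c("12", "11", "13", "12.2")]),
               c(93.0, 4.0, 2.2, 0.8))
  expect_equal(sum(prof$percentages), 100)

  single <- tabulate_calls(mk_calls(c("9" = 1L)))
  expect_equal(unname(single$percentages), 100)

  empty <- tabulate_calls(NULL, locus = "E")
  expect_equal(empty$total, 0L)
  expect_true("empty" %in% empty$flags)
  expect_error(classify_profile(empty), "empty")
})

test_that("per-length top sequences pick the most frequent span", {
  calls <- data.frame(length = c("10", "10", "10", "11"),
                      span = c("AAAA", "AAAA", "AAAT", "CCCC"))
  prof <- tabulate_calls(calls, locus = "T")
  expect_equal(prof$top_sequences$sequence[prof$top_sequences$length == "10"],
               "AAAA")
  expect_equal(prof$top_sequences$count[prof$top_sequences$length == "10"], 2L)
})

test_that("classification splits allele, stutter and noise at the threshold", {
  # predominant allele with sub-threshold whole (stutter) and partial (noise)
  p1 <- classify_profile(tabulate_calls(mk_calls(
    c("12" = 930L, "11" = 40L, "13" = 22L, "12.2" = 8L))))
  expect_equal(unname(p1$class_labels[c("12", "11", "13", "12.2")]),
               c("allele", "stutter", "stutter", "noise"))

  # heterozygous-like 66/33 with flanking stutters
  p2 <- classify_profile(tabulate_calls(mk_calls(
    c("17" = 660L, "18" = 330L, "16" = 6L, "19" = 4L))))
  expect_equal(sort(names(p2$class_labels[p2$class_labels == "allele"])),
               c("17", "18"))
  expect_equal(unname(p2$class_labels[c("16", "19")]),
               c("stutter", "stutter"))

  # a microvariant above threshold is an allele, not noise
  p3 <- classify_profile(tabulate_calls(mk_calls(
    c("13.2" = 520L, "13" = 440L, "12.2" = 40L))))
  expect_equal(unname(p3$class_labels[c("13.2", "13", "12.2")]),
               c("allele", "allele", "noise"))

  # nothing reaches the threshold -> flagged, everything stutter/noise
  flat <- classify_profile(tabulate_calls(mk_calls(
    stats::setNames(rep(30L, 20), as.character(1:20)))))
  expect_true("no allele" %in% flat$flags)
  expect_false(any(flat$class_labels == "allele"))
})

test_that("class percentages always sum to 100", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    counts <- stats::setNames(sample(1:500, n),
                              rl_label(sample(5:30, n), sample(0:3, n, TRUE)))
    p <- classify_profile(tabulate_calls(mk_calls(counts)))
    expect_equal(sum(p$percentages), 100, tolerance = 1e-4)
    expect_length(p$class_labels, length(p$spectrum))
  }
})

test_that("genotype calls report alleles, flags and copy ratios", {
  g <- call_genotype(classify_profile(tabulate_calls(mk_calls(
    c("17" = 660L, "18" = 340L)))))
  expect_equal(g$alleles$length, c("17", "18"))
  expect_equal(g$alleles$fraction, c(0.66, 0.34))
  expect_equal(g$copy_ratio, "2:1")

  even <- call_genotype(classify_profile(tabulate_calls(mk_calls(
    c("14" = 500L, "15" = 500L)))))
  expect_equal(even$copy_ratio, "1:1")

  solo <- call_genotype(classify_profile(tabulate_calls(mk_calls(
    c("12" = 970L, "11" = 30L)))))
  expect_equal(nrow(solo$alleles), 1L)
  expect_true(is.na(solo$copy_ratio))

  low <- call_genotype(classify_profile(tabulate_calls(mk_calls(
    c("12" = 50L)))), min_reads = 100L)
  expect_true("low-coverage" %in% low$flags)

  drop <- call_genotype(tabulate_calls(NULL, locus = "D"))
  expect_true("dropout-suspect" %in% drop$flags)
  expect_equal(nrow(drop$alleles), 0L)

  # far from every candidate ratio -> undetermined
  odd <- call_genotype(classify_profile(tabulate_calls(mk_calls(
    c("10" = 560L, "11" = 140L)))))  # ratio 4.0
  expect_equal(odd$copy_ratio, "undetermined")
})

test_that("profile concordance counts matching allele sets", {
  base <- list(A = c("10", "11"), B = c("12"), C = c("9", "13.2"),
               D = c("14", "15"), E = c("8", "9"))
  fifteen <- stats::setNames(rep(base, 3),
                             paste0("L", 1:15))
  a <- mk_sample_profile(fifteen, "a")
  self <- compare_profiles(a, a)
  expect_equal(self$matched, 15L)
  expect_equal(self$shared, 15L)

  # mutate exactly 3 allele sets -> 12/15, symmetric in matched count
  mutated <- fifteen
  for (nm in c("L2", "L7", "L11")) mutated[[nm]] <- c("20", "21")
  b <- mk_sample_profile(mutated, "b")
  ab <- compare_profiles(a, b)
  expect_equal(ab$matched, 12L)
  expect_equal(ab$shared, 15L)
  expect_setequal(ab$per_locus$locus[!ab$per_locus$match],
                  c("L2", "L7", "L11"))
  expect_equal(compare_profiles(b, a)$matched, 12L)

  disjoint <- compare_profiles(
    mk_sample_profile(list(X = "10"), "x"),
    mk_sample_profile(list(Y = "11"), "y"))
  expect_equal(disjoint$shared, 0L)
  expect_equal(disjoint$warning, "no shared loci")
})
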