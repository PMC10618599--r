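test_that("make_locus is deterministic and self-consistent", {
  a <- make_locus("L", "TATC", 11, seed = 7)
  b <- make_locus("L", "TATC", 11, seed = 7)
  expect_identical(a, b)
  v <- validate_locus(a)
  expect_true(v$ok)
  expect_equal(v$computed_count, "11")

  expect_error(make_locus("L", "A", 10), "length 2-6")
  expect_error(make_locus("L", "TATC", 10, flank = 8L, anchor_len = 10L),
               "too short")

  # offsets and inserts are absorbed into bp_modifier and still validate
  off <- make_locus("L", "TATC", 10, start_offset = 5L, seed = 3)
  expect_equal(off$bp_modifier, 5L)
  expect_equal(validate_locus(off)$computed_count, "10")
  ins <- make_locus("L", "TCTA", 20, insert = strrep("G", 13), seed = 4)
  expect_equal(ins$bp_modifier, 13L)
  expect_equal(validate_locus(ins)$computed_count, "20")
})

test_that("error-free reads call back to their true alleles", {
  loc <- fix_locus(seed = 9)
  panel <- str_panel(list(loc))
  spec <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry(c("12", "13.2"))), 1)),
    reads_per_locus = 1000L, stutter = stutter_model(0, 1, 0, 0), seed = 5)
  sim <- simulate_sample(spec)
  run <- call_reads(sim$reads, panel)
  expect_equal(run$tally[["assigned"]], 1000L)
  expect_equal(sort(unique(run$calls$LOC1$length)), c("12", "13.2"))
  expect_equal(run$calls$LOC1$length[order(run$calls$LOC1$read_id)],
               sim$truth$emitted_length[order(sim$truth$read_id)])
})

test_that("stutter and mixing frequencies match their binomial oracles", {
  loc <- fix_locus(seed = 13)
  panel <- str_panel(list(loc))
  # homozygous locus, stutter only: called stutter fraction ~ Binomial mean
  spec <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry("13", copies = 2L)), 1)),
    reads_per_locus = 100000L, stutter = stutter_model(0.04, 0.8, 0, 0),
    seed = 17)
  sim <- simulate_sample(spec)
  run <- call_reads(sim$reads, panel)
  stutter_frac <- mean(run$calls$LOC1$length != "13")
  expect_lt(abs(stutter_frac - 0.04), 0.004)
  # of stutter events, the -1 position dominates at minus_one_weight
  st <- run$calls$LOC1$length[run$calls$LOC1$length != "13"]
  expect_lt(abs(mean(st == "12") - 0.8), 0.05)

  # 200:1 component weights: minor read count within the binomial 99% CI
  spec2 <- sim_spec(panel,
                    list(sim_component(list(LOC1 = genotype_entry("13")), 200 / 201),
                         sim_component(list(LOC1 = genotype_entry("16")), 1 / 201)),
                    reads_per_locus = 100000L,
                    stutter = stutter_model(0, 1, 0, 0), seed = 19)
  sim2 <- simulate_sample(spec2)
  minor_n <- sum(sim2$truth$component == 2L)
  band <- stats::qbinom(c(0.005, 0.995), 100000L, 1 / 201)
  expect_gte(minor_n, band[1])
  expect_lte(minor_n, band[2])
})

test_that("expected_spectrum matches closed-form cases", {
  loc <- fix_locus(seed = 23)
  panel <- str_panel(list(loc))
  noerr <- stutter_model(0, 1, 0, 0)

  het <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry(c("12", "14"))), 1)), stutter = noerr)
  expect_equal(expected_spectrum(het, "LOC1"),
               c("12" = 0.5, "14" = 0.5))

  tri <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry(c("12", "14"), copies = c(2L, 1L))), 1)),
    stutter = noerr)
  expect_equal(expected_spectrum(tri, "LOC1"),
               c("12" = 2 / 3, "14" = 1 / 3))

  s <- 0.07
  hom <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry("13", copies = 2L)), 1)),
    stutter = stutter_model(s, 1, 0, 0))
  expect_equal(expected_spectrum(hom, "LOC1"),
               c("12" = s, "13" = 1 - s))

  # always a probability distribution, including with partial noise
  messy <- sim_spec(panel, list(sim_component(
    list(LOC1 = genotype_entry(c("12", "13.2"))), 1)),
    stutter = stutter_model(0.1, 0.7, 0.01, 0.002))
  expect_equal(sum(expected_spectrum(messy, "LOC1")), 1, tolerance = 1e-12)
})

test_that("identical sim specs give byte-identical FASTQ and reconciled truth", {
  panel <- fix_panel(2L)
  gts <- list(LOC1 = genotype_entry(c("11", "12")),
              LOC2 = genotype_entry("12", copies = 2L))
  spec <- sim_spec(panel, list(sim_component(gts, 1)),
                   reads_per_locus = 300L, seed = 29)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  r1 <- simulate_sample(spec, fastq = f1)
  r2 <- simulate_sample(spec, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$truth, r2$truth)

  # truth table reconciles with emitted records
  expect_equal(nrow(r1$truth), length(r1$reads))
  expect_equal(r1$truth$read_id, names(r1$reads))
  expect_equal(unname(table(r1$truth$locus)[names(panel)]),
               unname(rep(300L, 2)), ignore_attr = TRUE)
})

test_that("simulation does not perturb the caller's RNG stream", {
  loc <- fix_locus(seed = 31)
  spec <- sim_spec(str_panel(list(loc)), list(sim_component(
    list(LOC1 = genotype_entry("12")), 1)), reads_per_locus = 10L, seed = 1)
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_sample(spec))
  after <- stats::runif(1)
  expect_identical(before, after)
})
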