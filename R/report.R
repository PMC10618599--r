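REPORT_SCHEMA_VERSION <- "1.0"

fmt_pct <- function(x) sprintf("%.2f", x)

#' Write a sample profile report
#'
#' Emits the per-locus spectrum table (one row per repeat length: locus,
#' repeat length, read count, percent, class, top sequence and its count) and
#' the sample genotype table (locus, alleles, allele fractions, copy ratio,
#' flags) as comma-separated text, plus a structured JSON document carrying
#' both together with the run tally. Percentages are serialized with two
#' decimals; microvariants keep their `"n.r"` labels. No timestamps are
#' written, so repeated runs on identical inputs are byte-identical.
#'
#' @param profile a [call_sample()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; defaults to the sample name.
#' @return named character vector of the three paths written, invisibly.
#' @export
write_profile_report <- function(profile, dir, prefix = profile$sample) {
  stopifnot(inherits(profile, "sample_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectrum <- do.call(rbind, lapply(profile$profiles, function(p) {
    if (p$total == 0L) return(NULL)
    top <- p$top_sequences
    data.frame(locus = p$locus,
               repeat_length = names(p$spectrum),
               reads = as.integer(p$spectrum),
               percent = fmt_pct(p$percentages),
               class = if (!is.null(p$class_labels)) unname(p$class_labels) else "",
               top_sequence = if (!is.null(top)) top$sequence else "",
               top_sequence_reads = if (!is.null(top)) top$count else NA_integer_)
  }))
  genotypes <- do.call(rbind, lapply(profile$genotypes, function(g) {
    data.frame(locus = g$locus,
               alleles = paste(allele_set(g), collapse = "/"),
               fractions = paste(fmt_pct(100 * g$alleles$fraction), collapse = "/"),
               copy_ratio = g$copy_ratio %||% NA_character_,
               flags = paste(g$flags, collapse = ";"))
  }))
  spectrum_path <- file.path(dir, paste0(prefix, "_spectrum.csv"))
  genotype_path <- file.path(dir, paste0(prefix, "_genotypes.csv"))
  json_path <- file.path(dir, paste0(prefix, "_profile.json"))
  utils::write.csv(spectrum, spectrum_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(genotypes, genotype_path, row.names = FALSE, quote = FALSE)
  doc <- list(schema_version = REPORT_SCHEMA_VERSION,
              sample = profile$sample,
              tally = as.list(profile$tally),
              loci = lapply(unname(profile$profiles), function(p) {
                g <- profile$genotypes[[p$locus]]
                list(locus = p$locus, total_reads = p$total,
                     spectrum = if (p$total) lapply(seq_along(p$spectrum), function(i)
                       list(repeat_length = names(p$spectrum)[i],
                            reads = as.integer(p$spectrum[[i]]),
                            percent = as.numeric(fmt_pct(p$percentages[[i]])),
                            class = if (!is.null(p$class_labels))
                              unname(p$class_labels[i]) else NA)) else list(),
                     alleles = allele_set(g),
                     copy_ratio = g$copy_ratio,
                     flags = c(g$flags))
              }))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(spectrum = spectrum_path, genotypes = genotype_path,
              json = json_path))
}

#' Read a genotype table back into a minimal sample profile
#'
#' Inverse of the genotype CSV written by [write_profile_report()], for
#' comparing profiles across runs. Spectra are not recoverable from the
#' genotype table; the returned profile carries allele sets, fractions and
#' copy ratios only, which is what [compare_profiles()] and
#' [informative_alleles()] need.
#'
#' @param path a `*_genotypes.csv` file.
#' @param sample_name sample label; defaults to the file name.
#' @return a `sample_profile` (without `profiles` spectra).
#' @export
read_genotype_table <- function(path, sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- sub("_genotypes\\.csv$", "", basename(path))
  }
  tab <- utils::read.csv(path, colClasses = "character")
  genotypes <- lapply(seq_len(nrow(tab)), function(i) {
    lengths <- strsplit(tab$alleles[i], "/", fixed = TRUE)[[1L]]
    fracs <- suppressWarnings(as.numeric(
      strsplit(tab$fractions[i], "/", fixed = TRUE)[[1L]])) / 100
    keep <- nzchar(lengths)
    alleles <- data.frame(length = lengths[keep], count = NA_integer_,
                          fraction = fracs[keep])
    if (nrow(alleles)) {
      alleles <- alleles[order(-alleles$fraction), , drop = FALSE]
      rownames(alleles) <- NULL
    }
    cr <- tab$copy_ratio[i]
    structure(list(locus = tab$locus[i], alleles = alleles,
                   copy_ratio = if (!nzchar(cr) || is.na(cr)) NA_character_ else cr,
                   flags = setdiff(strsplit(tab$flags[i], ";", fixed = TRUE)[[1L]], "")),
              class = "genotype_call")
  })
  names(genotypes) <- tab$locus
  structure(list(sample = sample_name, profiles = NULL, genotypes = genotypes,
                 tally = NULL),
            class = "sample_profile")
}

#' Write a concordance report
#'
#' @param concordance a [compare_profiles()] result.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return the two paths written, invisibly.
#' @export
write_concordance_report <- function(concordance, dir, prefix = "concordance") {
  stopifnot(inherits(concordance, "profile_concordance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  per <- concordance$per_locus
  if (is.null(per)) {
    per <- data.frame(locus = character(), alleles_a = character(),
                      alleles_b = character(), match = logical())
  }
  utils::write.csv(per, csv_path, row.names = FALSE, quote = FALSE)
  doc <- list(schema_version = REPORT_SCHEMA_VERSION,
              sample_a = concordance$sample_a, sample_b = concordance$sample_b,
              matched = concordance$matched, shared = concordance$shared,
              per_locus = per, only_a = concordance$only_a,
              only_b = concordance$only_b,
              warning = concordance$warning)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Write a mixture report
#'
#' @param result a [detect_contamination()] result.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return the two paths written, invisibly.
#' @export
write_mixture_report <- function(result, dir, prefix = "mixture") {
  stopifnot(inherits(result, "mixture_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  per <- result$per_allele
  if (is.null(per)) {
    per <- data.frame(locus = character(), length = character(),
                      count = integer(), total = integer(),
                      fraction = numeric(), stutter_colliding = logical(),
                      dose = numeric())
  }
  utils::write.csv(per, csv_path, row.names = FALSE, quote = FALSE)
  doc <- list(schema_version = REPORT_SCHEMA_VERSION,
              per_allele = per,
              minor_fraction = result$minor_fraction,
              ci = result$ci,
              supporting_loci = result$supporting_loci,
              decision = result$decision,
              rule = result$rule)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(csv = csv_path, json = json_path))
}
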