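#' Tabulate repeat calls into a locus profile
#'
#' Builds the read-count spectrum over repeat lengths for one locus, with
#' per-length percentages (full precision internally; reports round to two
#' decimals) and the most frequent inter-anchor span sequence per length.
#'
#' @param calls data.frame of call rows for one locus (as produced by
#'   [call_reads()]/[process_reads()]), needing at least a `length` column;
#'   `span` is used for top sequences when present.
#' @param locus locus name recorded on the profile.
#' @return an object of class `locus_profile` with elements `locus`, `total`,
#'   `spectrum` (named counts, sorted by repeat length), `percentages`,
#'   `top_sequences` (data.frame: length, sequence, count), `class_labels`
#'   (`NULL` until [classify_profile()]), `flags`. Zero calls give an empty
#'   profile (flag `"empty"`), excluded from classification.
#' @export
tabulate_calls <- function(calls, locus = "locus") {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(structure(list(locus = locus, total = 0L,
                          spectrum = integer(0), percentages = numeric(0),
                          top_sequences = NULL, class_labels = NULL,
                          flags = "empty"),
                     class = "locus_profile"))
  }
  counts <- table(calls$length)
  labels <- rl_sort(names(counts))
  spectrum <- stats::setNames(as.integer(counts[labels]), labels)
  percentages <- 100 * spectrum / sum(spectrum)
  top_sequences <- NULL
  if (!is.null(calls$span)) {
    top_sequences <- do.call(rbind, lapply(labels, function(lb) {
      sp <- calls$span[calls$length == lb]
      tt <- sort(table(sp), decreasing = TRUE)
      # tie-break: most frequent, then alphabetical, for determinism
      best <- names(tt)[tt == tt[1L]]
      data.frame(length = lb, sequence = sort(best)[1L],
                 count = as.integer(tt[1L]))
    }))
  }
  structure(list(locus = locus, total = sum(spectrum), spectrum = spectrum,
                 percentages = percentages, top_sequences = top_sequences,
                 class_labels = NULL, flags = character(0)),
            class = "locus_profile")
}

#' Classify repeat lengths as allele, stutter or noise
#'
#' Applies the frequency-based error taxonomy: lengths reaching
#' `allele_min_frac` of the locus's reads are alleles (including microvariant
#' partial-repeat lengths — a genuine "13.2" allele is called, not discarded);
#' complete-repeat lengths below the threshold are stutter; partial-repeat
#' lengths below it are noise. If no length reaches the threshold the profile
#' is flagged `"no allele"` and every length is stutter or noise.
#'
#' @param profile a [tabulate_calls()] profile.
#' @param allele_min_frac allele-calling threshold as a fraction of locus
#'   reads; default 0.10 (stutter is by definition sub-10%).
#' @return the profile with `class_labels` filled (named character vector:
#'   length -> `"allele"`/`"stutter"`/`"noise"`) and threshold recorded.
#' @export
classify_profile <- function(profile, allele_min_frac = 0.10) {
  stopifnot(inherits(profile, "locus_profile"))
  if (profile$total == 0L) stop("cannot classify an empty profile")
  frac <- profile$percentages / 100
  partial <- rl_is_partial(names(profile$spectrum))
  cls <- ifelse(frac >= allele_min_frac, "allele",
                ifelse(partial, "noise", "stutter"))
  names(cls) <- names(profile$spectrum)
  profile$class_labels <- cls
  profile$allele_min_frac <- allele_min_frac
  if (!any(cls == "allele")) profile$flags <- union(profile$flags, "no allele")
  profile
}

#' @export
print.locus_profile <- function(x, ...) {
  cat(sprintf("<locus_profile> %s: %d reads\n", x$locus, x$total))
  if (x$total == 0L) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  for (lb in names(x$spectrum)) {
    cat(sprintf("  %-8s %7d  %6.2f%%  %s\n", lb, x$spectrum[[lb]],
                x$percentages[[lb]],
                if (!is.null(x$class_labels)) x$class_labels[[lb]] else ""))
  }
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Call a genotype from a classified locus profile
#'
#' Allele lengths keep their read counts with fractions renormalised over
#' allele reads only, ordered by descending fraction (ties by ascending repeat
#' length). With two or more alleles, the read-count ratio of the top two
#' alleles is matched against the small-integer copy ratios 1:1, 2:1, 3:1 and
#' 3:2; the closest is reported as `copy_ratio` if its absolute deviation from
#' the observed ratio is at most 0.2, else `"undetermined"`. An allelic ratio
#' near 2:1, for instance, indicates three copies of the locus.
#'
#' @param profile a classified [locus_profile].
#' @param min_reads minimum locus read count; below it the call is flagged
#'   `"low-coverage"`. Default 100.
#' @return an object of class `genotype_call`: `locus`, `alleles` (data.frame
#'   `length`, `count`, `fraction`), `copy_ratio` (string or `NA`), `flags`.
#'   An empty profile yields no alleles and the `"dropout-suspect"` flag.
#' @export
call_genotype <- function(profile, min_reads = 100L) {
  stopifnot(inherits(profile, "locus_profile"))
  flags <- character(0)
  if (profile$total == 0L) {
    return(structure(list(locus = profile$locus,
                          alleles = data.frame(length = character(),
                                               count = integer(),
                                               fraction = numeric()),
                          copy_ratio = NA_character_,
                          flags = "dropout-suspect"),
                     class = "genotype_call"))
  }
  if (is.null(profile$class_labels)) profile <- classify_profile(profile)
  if (profile$total < min_reads) flags <- c(flags, "low-coverage")
  if ("no allele" %in% profile$flags) flags <- c(flags, "no allele")
  sel <- names(profile$spectrum)[profile$class_labels == "allele"]
  counts <- profile$spectrum[sel]
  alleles <- data.frame(length = sel, count = as.integer(counts),
                        fraction = if (length(sel)) as.numeric(counts / sum(counts)) else numeric(0))
  if (nrow(alleles)) {
    p <- rl_parse(alleles$length)
    alleles <- alleles[order(-alleles$fraction, p$whole, p$rem), , drop = FALSE]
    rownames(alleles) <- NULL
  }
  copy_ratio <- NA_character_
  if (nrow(alleles) >= 2L) {
    obs <- alleles$count[1L] / alleles$count[2L]
    cands <- c("1:1" = 1, "3:2" = 1.5, "2:1" = 2, "3:1" = 3)
    dev <- abs(obs - cands)
    best <- which.min(dev)
    copy_ratio <- if (dev[best] <= 0.2) names(cands)[best] else "undetermined"
    if (obs > 1.5) flags <- c(flags, "imbalance")
  }
  structure(list(locus = profile$locus, alleles = alleles,
                 copy_ratio = copy_ratio, flags = flags),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  al <- if (nrow(x$alleles)) {
    paste(sprintf("%s (%.1f%%)", x$alleles$length, 100 * x$alleles$fraction),
          collapse = ", ")
  } else "none"
  cat(sprintf("<genotype_call> %s: %s", x$locus, al))
  if (!is.na(x$copy_ratio)) cat(sprintf(" [copy ratio %s]", x$copy_ratio))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Profile a whole sample
#'
#' Tabulates, classifies and genotype-calls every panel locus from a read run.
#'
#' @param run a `str_run` from [call_reads()]/[process_reads()].
#' @param sample_name sample label.
#' @param allele_min_frac see [classify_profile()].
#' @param min_reads see [call_genotype()].
#' @return an object of class `sample_profile`: `sample`, `profiles` (named
#'   list of classified [locus_profile]s), `genotypes` (named list of
#'   [genotype_call]s), `tally` (the run tally).
#' @export
call_sample <- function(run, sample_name = "sample", allele_min_frac = 0.10,
                        min_reads = 100L) {
  stopifnot(inherits(run, "str_run"))
  profiles <- lapply(names(run$calls), function(nm) {
    p <- tabulate_calls(run$calls[[nm]], locus = nm)
    if (p$total > 0L) p <- classify_profile(p, allele_min_frac)
    p
  })
  names(profiles) <- names(run$calls)
  genotypes <- lapply(profiles, call_genotype, min_reads = min_reads)
  structure(list(sample = sample_name, profiles = profiles,
                 genotypes = genotypes, tally = run$tally),
            class = "sample_profile")
}

# Allele length labels of one locus's genotype, sorted.
allele_set <- function(genotype_call) {
  if (is.null(genotype_call) || nrow(genotype_call$alleles) == 0L) character(0)
  else rl_sort(genotype_call$alleles$length)
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s (%d loci)\n", x$sample, length(x$genotypes)))
  for (g in x$genotypes) {
    al <- allele_set(g)
    cat(sprintf("  %-12s %s%s\n", g$locus,
                if (length(al)) paste(al, collapse = "/") else "-",
                if (!is.na(g$copy_ratio)) paste0("  [", g$copy_ratio, "]") else ""))
  }
  invisible(x)
}

#' Compare two sample profiles (concordance)
#'
#' Per locus shared by both profiles, the genotypes match iff their allele
#' repeat-length sets are equal. Supports "matched at m of n loci" style
#' authentication reporting.
#'
#' @param a,b [call_sample()] profiles.
#' @return an object of class `profile_concordance`: `matched`, `shared`,
#'   `per_locus` (data.frame: locus, alleles_a, alleles_b, match), `only_a`,
#'   `only_b`, `warning` (set when no loci are shared).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "sample_profile"), inherits(b, "sample_profile"))
  shared <- intersect(names(a$genotypes), names(b$genotypes))
  per_locus <- NULL
  if (length(shared)) {
    per_locus <- do.call(rbind, lapply(shared, function(nm) {
      sa <- allele_set(a$genotypes[[nm]])
      sb <- allele_set(b$genotypes[[nm]])
      data.frame(locus = nm,
                 alleles_a = paste(sa, collapse = "/"),
                 alleles_b = paste(sb, collapse = "/"),
                 match = setequal(sa, sb))
    }))
  }
  structure(list(sample_a = a$sample, sample_b = b$sample,
                 matched = if (is.null(per_locus)) 0L else sum(per_locus$match),
                 shared = length(shared),
                 per_locus = per_locus,
                 only_a = setdiff(names(a$genotypes), shared),
                 only_b = setdiff(names(b$genotypes), shared),
                 warning = if (!length(shared)) "no shared loci" else NULL),
            class = "profile_concordance")
}

#' @export
print.profile_concordance <- function(x, ...) {
  cat(sprintf("<profile_concordance> %s vs %s: matched at %d of %d loci\n",
              x$sample_a, x$sample_b, x$matched, x$shared))
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  if (!is.null(x$per_locus)) {
    diff <- x$per_locus[!x$per_locus$match, , drop = FALSE]
    for (i in seq_len(nrow(diff))) {
      cat(sprintf("  differs %-12s %s vs %s\n", diff$locus[i],
                  diff$alleles_a[i], diff$alleles_b[i]))
    }
  }
  if (length(x$only_a)) cat("  only in", x$sample_a, ":",
                            paste(x$only_a, collapse = ", "), "\n")
  if (length(x$only_b)) cat("  only in", x$sample_b, ":",
                            paste(x$only_b, collapse = ", "), "\n")
  invisible(x)
}
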