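#' @importFrom Biostrings readDNAStringSet
#' @importFrom stringi stri_count_fixed stri_locate_first_fixed stri_reverse
NULL

# Reverse complement of plain character sequences (A/C/G/T/N).
revcomp <- function(seqs) {
  stri_reverse(chartr("ACGTN", "TGCAN", seqs))
}

as_char_reads <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    stats::setNames(as.character(reads), names(reads))
  } else {
    toupper(as.character(reads))
  }
}

# One-orientation anchor scan. Returns per-read occurrence counts of each
# anchor plus, where an anchor is unique, the end position of the start
# anchor and the start position of the end anchor. Exact matching runs on
# plain strings; the optional mismatch-tolerant mode (off by default, since
# it changes stutter/noise statistics) goes through Biostrings.
match_anchor_pair <- function(seqs, spec, max_mismatch = 0L) {
  if (max_mismatch > 0L) {
    dna <- Biostrings::DNAStringSet(seqs)
    loc1 <- Biostrings::vmatchPattern(spec$start_anchor, dna,
                                      max.mismatch = max_mismatch, fixed = TRUE)
    loc2 <- Biostrings::vmatchPattern(spec$end_anchor, dna,
                                      max.mismatch = max_mismatch, fixed = TRUE)
    ns <- S4Vectors::elementNROWS(loc1)
    ne <- S4Vectors::elementNROWS(loc2)
    s_end <- rep(NA_integer_, length(seqs))
    e_start <- rep(NA_integer_, length(seqs))
    i <- ns == 1L
    if (any(i)) s_end[i] <- unlist(Biostrings::endIndex(loc1)[i], use.names = FALSE)
    i <- ne == 1L
    if (any(i)) e_start[i] <- unlist(Biostrings::startIndex(loc2)[i], use.names = FALSE)
    return(list(n_start = ns, n_end = ne, s_end = s_end, e_start = e_start))
  }
  ns <- stri_count_fixed(seqs, spec$start_anchor)
  ne <- stri_count_fixed(seqs, spec$end_anchor)
  s_end <- stri_locate_first_fixed(seqs, spec$start_anchor)[, 2L]
  e_start <- stri_locate_first_fixed(seqs, spec$end_anchor)[, 1L]
  s_end[ns != 1L] <- NA_integer_
  e_start[ne != 1L] <- NA_integer_
  list(n_start = ns, n_end = ne, s_end = s_end, e_start = e_start)
}

# Core scan against one locus with the reverse complement precomputed (so a
# panel scan reverse-complements each read once, not once per locus).
scan_oriented <- function(fwd, rev, spec, max_mismatch = 0L) {
  n <- length(fwd)
  f <- match_anchor_pair(fwd, spec, max_mismatch)
  r <- match_anchor_pair(rev, spec, max_mismatch)

  multi <- f$n_start > 1L | f$n_end > 1L | r$n_start > 1L | r$n_end > 1L
  ok_f <- !multi & !is.na(f$s_end) & !is.na(f$e_start) & f$e_start > f$s_end
  ok_r <- !multi & !is.na(r$s_end) & !is.na(r$e_start) & r$e_start > r$s_end
  ambiguous <- multi | (ok_f & ok_r)
  use_f <- ok_f & !ambiguous
  use_r <- ok_r & !ambiguous

  status <- rep("no-call", n)
  status[ambiguous] <- "ambiguous"
  whole <- rep(NA_integer_, n)
  rem <- rep(NA_integer_, n)
  len <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  snp_applied <- rep(NA, n)
  span <- rep(NA_character_, n)

  called <- which(use_f | use_r)
  if (length(called)) {
    fsel <- use_f[called]
    s_end <- ifelse(fsel, f$s_end[called], r$s_end[called])
    e_start <- ifelse(fsel, f$e_start[called], r$e_start[called])
    oriented <- ifelse(fsel, fwd[called], rev[called])
    dist <- e_start - s_end - 1L
    corrected <- dist - spec$bp_modifier
    snp <- rep(FALSE, length(called))
    inc <- 0L
    if (!is.null(spec$snp_rule)) {
      snp <- stri_count_fixed(oriented, spec$snp_rule$trigger_sequence) > 0L
      inc <- spec$snp_rule$increment
    }
    w <- corrected %/% spec$repeat_size + ifelse(snp, inc, 0L)
    r_ <- corrected %% spec$repeat_size
    bad <- corrected < 0L | w < 0L
    status[called[bad]] <- "malformed"
    good <- called[!bad]
    whole[good] <- w[!bad]
    rem[good] <- r_[!bad]
    len[good] <- rl_label(w[!bad], r_[!bad])
    orientation[good] <- ifelse(fsel[!bad], "forward", "reverse-complement")
    snp_applied[good] <- snp[!bad]
    span[good] <- substr(oriented[!bad], s_end[!bad] + 1L, e_start[!bad] - 1L)
    status[good] <- "call"
  }
  data.frame(status = status, whole = whole, rem = rem, length = len,
             orientation = orientation, snp_applied = snp_applied,
             span = span, row.names = NULL)
}

#' Scan reads for one locus and call repeat lengths
#'
#' Vectorised core of the caller. Each read and its reverse complement are
#' searched for exact occurrences of the locus's start and end anchors. When
#' exactly one orientation yields a unique, correctly ordered anchor pair, the
#' base-pair distance between the end of the start anchor and the start of the
#' end anchor is measured, `bp_modifier` subtracted, the SNP rule applied if
#' its trigger occurs in the oriented read (adding its increment to the whole
#' repeat count), and the corrected distance divided by `repeat_size` into a
#' whole count plus a remainder of extra bases (a partial repeat, reported as
#' a microvariant `"n.r"` label).
#'
#' Read outcomes (`status`):
#' \describe{
#'   \item{call}{unique anchor pair in one orientation; repeat length called.}
#'   \item{no-call}{either anchor absent (or wrongly ordered) in both
#'     orientations.}
#'   \item{ambiguous}{an anchor occurs more than once in one orientation, or
#'     both orientations yield a valid pair; the read is discarded.}
#'   \item{malformed}{anchors found but the corrected distance (or the
#'     SNP-adjusted count) is negative; counted separately.}
#' }
#'
#' `N` bases never match an anchor (anchors are A/C/G/T only and matching is
#' exact).
#'
#' @param reads character vector or `DNAStringSet` of read sequences.
#' @param spec a [str_locus()].
#' @return a data.frame with one row per read: `status`, `whole`, `rem`,
#'   `length` (label), `orientation` (`"forward"`/`"reverse-complement"`),
#'   `snp_applied`, `span` (bases strictly between the anchors).
#' @seealso [scan_read()] for the single-read wrapper, [process_reads()] for
#'   FASTQ input.
#' @param max_mismatch maximum mismatches tolerated in anchor matching;
#'   default 0 (exact, the intended mode).
#' @export
scan_reads <- function(reads, spec, max_mismatch = 0L) {
  stopifnot(inherits(spec, "str_locus"))
  fwd <- as_char_reads(reads)
  scan_oriented(fwd, revcomp(fwd), spec, max_mismatch)
}

#' Call the repeat length of a single read at one locus
#'
#' @param read_sequence one read sequence (A/C/G/T/N).
#' @param spec a [str_locus()].
#' @param max_mismatch see [scan_reads()].
#' @return `NULL` when neither anchor pair is found (no-call); otherwise an
#'   object of class `repeat_call` with fields `locus`, `status`, `length`,
#'   `whole`, `rem`, `orientation`, `snp_applied`, `span`. Ambiguous and
#'   malformed reads return a `repeat_call` with the corresponding `status`
#'   and `NA` length.
#' @export
scan_read <- function(read_sequence, spec, max_mismatch = 0L) {
  res <- scan_reads(read_sequence[1L], spec, max_mismatch)
  if (res$status == "no-call") return(NULL)
  structure(list(locus = spec$name, status = res$status,
                 length = res$length, whole = res$whole, rem = res$rem,
                 orientation = res$orientation, snp_applied = res$snp_applied,
                 span = res$span),
            class = "repeat_call")
}

#' @export
print.repeat_call <- function(x, ...) {
  if (x$status == "call") {
    cat(sprintf("<repeat_call> %s: %s repeats (%s%s)\n", x$locus, x$length,
                x$orientation, if (isTRUE(x$snp_applied)) ", SNP rule applied" else ""))
  } else {
    cat(sprintf("<repeat_call> %s: %s\n", x$locus, x$status))
  }
  invisible(x)
}

#' Assign reads to panel loci (multiplexed pools)
#'
#' Runs [scan_reads()] against every locus of a panel. A read called by
#' exactly one locus is assigned to it; reads matching no locus are
#' unassigned; reads matching more than one locus (or flagged ambiguous at any
#' locus) are ambiguous and excluded from all locus tallies; reads whose only
#' match is malformed are counted as malformed. The four categories partition
#' the input: assigned + unassigned + ambiguous + malformed = total.
#'
#' @param reads character vector or `DNAStringSet`; names (if any) become
#'   read ids.
#' @param panel a [str_panel()].
#' @param max_mismatch see [scan_reads()].
#' @return an object of class `str_run`: list with `calls` (named list, locus
#'   -> data.frame of call rows) and `tally` (named integer: total, assigned,
#'   unassigned, ambiguous, malformed).
#' @export
call_reads <- function(reads, panel, max_mismatch = 0L) {
  stopifnot(inherits(panel, "str_panel"))
  fwd <- as_char_reads(reads)
  rev <- revcomp(fwd)
  n <- length(fwd)
  per_locus <- lapply(panel$loci,
                      function(l) scan_oriented(fwd, rev, l, max_mismatch))
  call_mat <- matrix(FALSE, nrow = n, ncol = length(per_locus),
                     dimnames = list(NULL, names(per_locus)))
  amb_any <- mal_any <- rep(FALSE, n)
  for (j in seq_along(per_locus)) {
    st <- per_locus[[j]]$status
    call_mat[, j] <- st == "call"
    amb_any <- amb_any | st == "ambiguous"
    mal_any <- mal_any | st == "malformed"
  }
  ncalls <- rowSums(call_mat)
  ambiguous <- amb_any | ncalls > 1L
  assigned <- !ambiguous & ncalls == 1L
  malformed <- !ambiguous & !assigned & mal_any
  unassigned <- !ambiguous & !assigned & !malformed

  calls <- lapply(names(per_locus), function(nm) {
    sel <- assigned & call_mat[, nm]
    d <- per_locus[[nm]][sel, c("length", "whole", "rem", "orientation",
                                "snp_applied", "span"), drop = FALSE]
    d$read_id <- if (!is.null(names(fwd))) names(fwd)[sel] else which(sel)
    rownames(d) <- NULL
    d
  })
  names(calls) <- names(per_locus)
  structure(list(calls = calls,
                 tally = c(total = n, assigned = sum(assigned),
                           unassigned = sum(unassigned),
                           ambiguous = sum(ambiguous),
                           malformed = sum(malformed))),
            class = "str_run")
}

#' @export
print.str_run <- function(x, ...) {
  t <- x$tally
  cat(sprintf("<str_run> %d reads: %d assigned, %d unassigned, %d ambiguous, %d malformed\n",
              t[["total"]], t[["assigned"]], t[["unassigned"]],
              t[["ambiguous"]], t[["malformed"]]))
  for (nm in names(x$calls)) {
    cat(sprintf("  %-12s %d calls\n", nm, nrow(x$calls[[nm]])))
  }
  invisible(x)
}

#' Assign one read within a panel
#'
#' @param read_sequence one read sequence.
#' @param panel a [str_panel()].
#' @return a list with `status` (`"assigned"`, `"unassigned"`, `"ambiguous"`
#'   or `"malformed"`), `locus` (name or `NA`) and `call` (a `repeat_call` or
#'   `NULL`).
#' @export
assign_read <- function(read_sequence, panel) {
  run <- call_reads(read_sequence[1L], panel)
  t <- run$tally
  if (t[["assigned"]] == 1L) {
    nm <- names(run$calls)[vapply(run$calls, nrow, integer(1)) == 1L]
    row <- run$calls[[nm]]
    call <- structure(list(locus = nm, status = "call", length = row$length,
                           whole = row$whole, rem = row$rem,
                           orientation = row$orientation,
                           snp_applied = row$snp_applied, span = row$span),
                      class = "repeat_call")
    return(list(status = "assigned", locus = nm, call = call))
  }
  status <- if (t[["ambiguous"]] == 1L) "ambiguous"
  else if (t[["malformed"]] == 1L) "malformed"
  else "unassigned"
  list(status = status, locus = NA_character_, call = NULL)
}

# Mean Phred score per read from a FASTQ quality string vector.
mean_phred <- function(qual_strings) {
  vapply(qual_strings,
         function(q) mean(as.integer(charToRaw(q)) - 33L),
         numeric(1), USE.NAMES = FALSE)
}

#' Process FASTQ file(s) against a panel
#'
#' Reads one or more FASTQ (optionally gzipped) files, scans every record
#' independently (paired mates are not merged) and groups repeat calls by
#' locus. Base qualities are ignored in calling; an optional mean-quality
#' filter can drop low-quality reads before scanning.
#'
#' @param fastq_files character vector of FASTQ / FASTQ.gz paths.
#' @param panel a [str_panel()].
#' @param min_mean_quality optional minimum mean Phred score; reads below it
#'   are dropped (counted in `filtered`). Default `NULL` (off).
#' @return a `str_run` (see [call_reads()]); its tally additionally reports
#'   `filtered` when the quality filter is active.
#' @export
process_reads <- function(fastq_files, panel, min_mean_quality = NULL) {
  stopifnot(inherits(panel, "str_panel"))
  seqs <- character(0)
  quals <- character(0)
  for (f in fastq_files) {
    if (!file.exists(f)) stop("FASTQ file not found: ", f)
    x <- tryCatch(
      readDNAStringSet(f, format = "fastq",
                       with.qualities = !is.null(min_mean_quality)),
      error = function(e) stop("failed to read FASTQ '", f, "': ",
                               conditionMessage(e)))
    seqs <- c(seqs, stats::setNames(as.character(x), names(x)))
    if (!is.null(min_mean_quality)) {
      quals <- c(quals, as.character(S4Vectors::mcols(x)$qualities))
    }
  }
  filtered <- 0L
  if (!is.null(min_mean_quality) && length(seqs)) {
    keep <- mean_phred(quals) >= min_mean_quality
    filtered <- sum(!keep)
    seqs <- seqs[keep]
  }
  if (!length(seqs)) {
    empty <- lapply(panel$loci, function(l) {
      data.frame(length = character(), whole = integer(), rem = integer(),
                 orientation = character(), snp_applied = logical(),
                 span = character(), read_id = character())
    })
    run <- structure(list(calls = empty,
                          tally = c(total = 0L, assigned = 0L, unassigned = 0L,
                                    ambiguous = 0L, malformed = 0L)),
                     class = "str_run")
  } else {
    run <- call_reads(seqs, panel)
  }
  if (!is.null(min_mean_quality)) {
    run$tally <- c(run$tally, filtered = filtered)
    run$tally[["total"]] <- run$tally[["total"]] + filtered
  }
  run
}
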