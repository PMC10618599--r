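`%||%` <- function(a, b) if (is.null(a)) b else a

.DNA_RE <- "^[ACGT]+$"

#' SNP-aware repeat correction rule
#'
#' Some STR loci carry a flanking SNP that effectively creates (or removes) a
#' repeat unit. The canonical case is a TATC-repeat locus that normally
#' terminates right before `AATCAATCATC`; an A>T variant at the first position
#' turns the termination into `TATCAATCATC`, adding one TATC repeat that the
#' inter-anchor distance cannot see. A `snp_rule` states the trigger sequence
#' to search for in the (oriented) read and the signed number of repeats to
#' add to the call when it is found.
#'
#' @param trigger_sequence non-empty A/C/G/T string searched in the read.
#' @param increment non-zero signed integer, repeats added when the trigger is
#'   present.
#' @return an object of class `snp_rule`.
#' @examples
#' snp_rule("TATCAATCATC", +1L)
#' @export
snp_rule <- function(trigger_sequence, increment) {
  trigger_sequence <- toupper(as.character(trigger_sequence))
  if (length(trigger_sequence) != 1L || !grepl(.DNA_RE, trigger_sequence)) {
    stop("snp_rule: trigger_sequence must be a non-empty A/C/G/T string")
  }
  increment <- as.integer(increment)
  if (is.na(increment) || increment == 0L) {
    stop("snp_rule: increment must be a non-zero integer")
  }
  structure(list(trigger_sequence = trigger_sequence, increment = increment),
            class = "snp_rule")
}

#' @export
format.snp_rule <- function(x, ...) {
  sprintf("%s:%+d", x$trigger_sequence, x$increment)
}

#' @export
print.snp_rule <- function(x, ...) {
  cat("<snp_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

# Parse the one-column "TRIGGER:+n" encoding; "" -> NULL.
parse_snp_rule <- function(s) {
  s <- trimws(s %||% "")
  if (is.na(s) || !nzchar(s)) return(NULL)
  m <- regmatches(s, regexec("^([ACGTacgt]+):([+-]?[0-9]+)$", s))[[1L]]
  if (length(m) != 3L) {
    stop("cannot parse SNP_modifier '", s, "' (expected TRIGGER:+n)")
  }
  snp_rule(m[[2L]], as.integer(m[[3L]]))
}

#' Define one STR locus
#'
#' A locus is described by the calling parameters of the nine-column locus
#' table: its name, an optional reference sequence (used only for QC), the
#' start/end anchor sequences that flank the repeat region in the amplicon,
#' the repeat unit size, a `bp_modifier` subtracted from the raw inter-anchor
#' distance (to discount anchor offsets from the repeat region and any fixed
#' non-repeat bases inside it), a declared reference repeat count, and an
#' optional [snp_rule()].
#'
#' @param name locus identifier, e.g. `"D13S317"`.
#' @param start_anchor,end_anchor non-empty A/C/G/T strings located in the
#'   read to delimit the repeat region; must differ from each other.
#' @param repeat_size repeat unit size in bp, between 2 and 6.
#' @param reference_sequence optional reference amplicon sequence (may be
#'   `""`); when present, [validate_locus()] checks the locus against it.
#' @param bp_modifier non-negative integer bp subtracted from the measured
#'   inter-anchor distance before dividing by `repeat_size`.
#' @param reference_repeat_count declared repeat count of the reference
#'   sequence, as a repeat-length label (may be a microvariant, e.g.
#'   `"13.2"`); `NA` when unknown.
#' @param snp_rule optional [snp_rule()].
#' @param notes free-text notes.
#' @param panel panel tag: `"human"`, `"mouse"` or `"custom"`.
#' @return an object of class `str_locus`.
#' @seealso [read_locus_table()], [validate_locus()], [make_locus()]
#' @export
str_locus <- function(name, start_anchor, end_anchor, repeat_size,
                      reference_sequence = "", bp_modifier = 0L,
                      reference_repeat_count = NA_character_,
                      snp_rule = NULL, notes = "", panel = "custom") {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) stop("locus name must be non-empty")
  start_anchor <- toupper(as.character(start_anchor))
  end_anchor <- toupper(as.character(end_anchor))
  for (a in c(start_anchor, end_anchor)) {
    if (!grepl(.DNA_RE, a)) {
      stop("locus ", name, ": anchors must be non-empty A/C/G/T strings")
    }
  }
  if (start_anchor == end_anchor) {
    stop("locus ", name, ": start and end anchors must differ")
  }
  repeat_size <- as.integer(repeat_size)
  if (is.na(repeat_size) || repeat_size < 2L || repeat_size > 6L) {
    stop("locus ", name, ": repeat_size must be an integer in [2, 6]")
  }
  bp_modifier <- as.integer(bp_modifier)
  if (is.na(bp_modifier) || bp_modifier < 0L) {
    stop("locus ", name, ": bp_modifier must be a non-negative integer")
  }
  reference_sequence <- toupper(as.character(reference_sequence %||% ""))
  if (nzchar(reference_sequence) && !grepl(.DNA_RE, reference_sequence)) {
    stop("locus ", name, ": reference_sequence must be A/C/G/T")
  }
  if (!is.na(reference_repeat_count)) {
    rc <- rl_parse(as.character(reference_repeat_count))
    if (rc$rem >= repeat_size) {
      stop("locus ", name, ": reference repeat remainder ", rc$rem,
           " must be < repeat_size ", repeat_size)
    }
    reference_repeat_count <- rl_label(rc$whole, rc$rem)
  }
  if (!is.null(snp_rule) && !inherits(snp_rule, "snp_rule")) {
    stop("locus ", name, ": snp_rule must be a snp_rule object or NULL")
  }
  structure(
    list(name = name,
         reference_sequence = reference_sequence,
         start_anchor = start_anchor,
         end_anchor = end_anchor,
         repeat_size = repeat_size,
         bp_modifier = bp_modifier,
         reference_repeat_count = as.character(reference_repeat_count),
         snp_rule = snp_rule,
         notes = as.character(notes %||% ""),
         panel = match.arg(panel, c("human", "mouse", "custom"))),
    class = "str_locus")
}

#' @export
print.str_locus <- function(x, ...) {
  cat("<str_locus> ", x$name, "\n", sep = "")
  cat("  repeat_size: ", x$repeat_size, " bp; bp_modifier: ", x$bp_modifier,
      "; reference count: ", x$reference_repeat_count, "\n", sep = "")
  cat("  anchors: ", x$start_anchor, " ... ", x$end_anchor, "\n", sep = "")
  if (!is.null(x$snp_rule)) cat("  SNP rule: ", format(x$snp_rule), "\n", sep = "")
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Bundle loci into a panel
#'
#' @param loci list of [str_locus()] objects with unique names.
#' @param species species label (`"human"`, `"mouse"`, `"custom"`, ...).
#' @param provenance free-text provenance note.
#' @return an object of class `str_panel`; behaves like a named list of loci.
#' @export
str_panel <- function(loci, species = "custom", provenance = "") {
  if (inherits(loci, "str_locus")) loci <- list(loci)
  if (!length(loci) || !all(vapply(loci, inherits, logical(1), "str_locus"))) {
    stop("str_panel: loci must be a non-empty list of str_locus objects")
  }
  nms <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate locus name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(loci) <- nms
  structure(list(loci = loci, species = as.character(species),
                 provenance = as.character(provenance)),
            class = "str_panel")
}

#' @export
length.str_panel <- function(x) length(x$loci)

#' @export
names.str_panel <- function(x) names(x$loci)

#' @export
`[[.str_panel` <- function(x, i) x$loci[[i]]

#' @export
print.str_panel <- function(x, ...) {
  cat("<str_panel> ", x$species, " (", length(x), " loci)\n", sep = "")
  for (l in x$loci) {
    cat(sprintf("  %-12s %d bp unit, bp_modifier %d, ref %s%s\n",
                l$name, l$repeat_size, l$bp_modifier,
                l$reference_repeat_count,
                if (!is.null(l$snp_rule)) paste0(", SNP ", format(l$snp_rule)) else ""))
  }
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.str_panel <- function(x, ...) {
  do.call(rbind, lapply(x$loci, function(l) {
    data.frame(
      name = l$name,
      reference_sequence = l$reference_sequence,
      start_anchor = l$start_anchor,
      end_anchor = l$end_anchor,
      repeat_size = l$repeat_size,
      bp_modifier = l$bp_modifier,
      reference_repeat_count = l$reference_repeat_count %||% NA_character_,
      snp_modifier = if (is.null(l$snp_rule)) "" else format(l$snp_rule),
      notes = l$notes,
      row.names = NULL)
  }))
}

#' Read a nine-column STR locus table
#'
#' Parses the comma-separated locus-definition format: a header row followed
#' by one row per locus with nine columns, in order: name, reference sequence,
#' start target sequence, end target sequence, repeat size, bp_modifier,
#' reference repeat count, SNP_modifier, notes. Lines starting with `#` are
#' ignored. The SNP_modifier column uses the `"TRIGGER:+n"` encoding (empty
#' for no rule); the reference repeat count may be a microvariant label such
#' as `"13.2"`.
#'
#' @param path path to the comma-separated table.
#' @param species species label stored on the returned panel.
#' @return a [str_panel()].
#' @seealso [write_locus_table()] for the inverse.
#' @export
read_locus_table <- function(path, species = "custom") {
  if (!file.exists(path)) stop("locus table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("no locus rows in ", path)
  fields <- count.fields(textConnection(lines), sep = ",", quote = "\"")
  bad <- which(fields != 9L)
  if (length(bad)) {
    stop("malformed locus table row ", bad[1L], " in ", path, ": expected 9 ",
         "comma-separated columns, found ", fields[bad[1L]])
  }
  tab <- utils::read.csv(textConnection(lines), header = TRUE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(tab) == 0L) stop("no locus rows in ", path)
  loci <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    size <- suppressWarnings(as.integer(row[[5L]]))
    bpm <- suppressWarnings(as.integer(row[[6L]]))
    if (is.na(size)) stop("row ", i, ": non-numeric repeat size '", row[[5L]], "'")
    if (is.na(bpm)) stop("row ", i, ": non-numeric bp_modifier '", row[[6L]], "'")
    refc <- trimws(row[[7L]])
    str_locus(name = row[[1L]],
              reference_sequence = row[[2L]],
              start_anchor = row[[3L]],
              end_anchor = row[[4L]],
              repeat_size = size,
              bp_modifier = bpm,
              reference_repeat_count = if (nzchar(refc)) refc else NA_character_,
              snp_rule = parse_snp_rule(row[[8L]]),
              notes = row[[9L]],
              panel = if (species %in% c("human", "mouse")) species else "custom")
  })
  str_panel(loci, species = species, provenance = paste0("loaded from ", basename(path)))
}

#' Write a panel back to the nine-column table format
#'
#' Field-exact inverse of [read_locus_table()]: reading the written file
#' reproduces the panel's locus definitions.
#'
#' @param panel a [str_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(panel, path) {
  stopifnot(inherits(panel, "str_panel"))
  df <- as.data.frame(panel)
  df$reference_repeat_count[is.na(df$reference_repeat_count)] <- ""
  if (any(grepl(",", df$notes, fixed = TRUE))) {
    stop("notes must not contain commas (nine-column table is unquoted)")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Count exact occurrences of `pattern` in `subject` (plain strings).
count_occurrences <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Validate a locus against its reference sequence
#'
#' Quality-control check used when adding loci: each anchor must occur exactly
#' once in the reference sequence; the inter-anchor distance is then measured,
#' `bp_modifier` subtracted, the SNP rule applied if its trigger is present,
#' and the resulting repeat count compared with the declared reference repeat
#' count. A count mismatch is reported as a QC warning, not an error; a
#' missing or repeated anchor is an error. Loci without a reference sequence
#' pass trivially (nothing to check).
#'
#' @param locus a [str_locus()].
#' @return an object of class `locus_validation` with elements `locus`, `ok`
#'   (no errors), `errors`, `warnings`, `computed_count`, `declared_count`.
#' @export
validate_locus <- function(locus) {
  stopifnot(inherits(locus, "str_locus"))
  errors <- character()
  warnings <- character()
  computed <- NA_character_
  ref <- locus$reference_sequence
  if (nzchar(ref)) {
    ns <- count_occurrences(locus$start_anchor, ref)
    ne <- count_occurrences(locus$end_anchor, ref)
    if (ns == 0L) errors <- c(errors, "start anchor absent from reference sequence")
    if (ns > 1L) errors <- c(errors, sprintf("start anchor occurs %d times in reference", ns))
    if (ne == 0L) errors <- c(errors, "end anchor absent from reference sequence")
    if (ne > 1L) errors <- c(errors, sprintf("end anchor occurs %d times in reference", ne))
    if (!length(errors)) {
      s_end <- regexpr(locus$start_anchor, ref, fixed = TRUE) +
        nchar(locus$start_anchor) - 1L
      e_start <- regexpr(locus$end_anchor, ref, fixed = TRUE)
      dist <- e_start - s_end - 1L
      if (dist < 0L) {
        errors <- c(errors, "end anchor precedes start anchor in reference")
      } else {
        corrected <- dist - locus$bp_modifier
        if (corrected < 0L) {
          errors <- c(errors, sprintf(
            "corrected distance negative (%d bp span - %d bp modifier)",
            dist, locus$bp_modifier))
        } else {
          whole <- corrected %/% locus$repeat_size
          rem <- corrected %% locus$repeat_size
          if (!is.null(locus$snp_rule) &&
              grepl(locus$snp_rule$trigger_sequence, ref, fixed = TRUE)) {
            whole <- whole + locus$snp_rule$increment
          }
          computed <- rl_label(whole, rem)
          declared <- locus$reference_repeat_count
          if (!is.na(declared) && computed != declared) {
            warnings <- c(warnings, sprintf(
              "computed %s != declared %s repeats", computed, declared))
          }
        }
      }
    }
  }
  structure(list(locus = locus$name, ok = !length(errors), errors = errors,
                 warnings = warnings, computed_count = computed,
                 declared_count = locus$reference_repeat_count),
            class = "locus_validation")
}

#' @export
print.locus_validation <- function(x, ...) {
  status <- if (!x$ok) "FAIL" else if (length(x$warnings)) "WARN" else "PASS"
  cat(sprintf("<locus_validation> %s: %s", x$locus, status))
  if (!is.na(x$computed_count)) {
    cat(sprintf(" (computed %s, declared %s)", x$computed_count, x$declared_count))
  }
  cat("\n")
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Validate every locus in a panel
#'
#' @param panel a [str_panel()].
#' @return a list of [validate_locus()] reports, one per locus.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "str_panel"))
  lapply(panel$loci, validate_locus)
}
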