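.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# TRUE if `flank` contains `motif` twice in a row (a tandem run that could be
# confused with the repeat region).
has_tandem_run <- function(flank, motif) {
  grepl(paste0(motif, motif), flank, fixed = TRUE)
}

# Repeat region of `bp` total bases: full motif units with the insert placed
# after `split` units, then a motif-prefix partial. Only the total length
# matters to distance-based calling; the layout mirrors the reference.
region_seq <- function(motif, bp, insert = "", split = 0L) {
  size <- nchar(motif)
  whole <- bp %/% size
  rem <- bp %% size
  s <- min(split, whole)
  paste0(strrep(motif, s), insert, strrep(motif, whole - s),
         substr(motif, 1L, rem))
}

#' Construct a synthetic STR locus with a full reference sequence
#'
#' Builds a locus whose reference amplicon is `left flank + repeat region +
#' right flank`, with anchors taken from the flanks. Flanks are random but
#' constrained: neither contains the motif as a tandem run, and each anchor
#' occurs exactly once in the reference, so the locus always passes
#' [validate_locus()]. Anchors may be offset from the repeat region
#' (`start_offset`/`end_offset` intervening bases) and the region may carry
#' fixed non-repeat bases (`insert`); both are absorbed into `bp_modifier`.
#' Reproducible: the same arguments and seed give an identical locus.
#'
#' @param name locus name.
#' @param motif repeat unit, 2-6 bp.
#' @param n_repeats reference repeat count, a label (microvariants such as
#'   `"13.2"` allowed).
#' @param flank flank length in bp on each side (must fit the anchor and
#'   offset).
#' @param anchor_len anchor length in bp.
#' @param start_offset,end_offset bases between each anchor and the repeat
#'   region.
#' @param insert fixed non-repeat bases inside the repeat region (placed after
#'   half the reference units), e.g. the extra nucleotides some loci carry
#'   among their repeats.
#' @param right_flank_prefix fixed sequence at the start of the right flank
#'   (used to model termination-sequence SNP cases; see [snp_rule()]).
#' @param snp_rule optional [snp_rule()] attached to the locus.
#' @param notes,panel passed to [str_locus()].
#' @param seed integer seed controlling flank generation.
#' @return a validated [str_locus()] carrying a `structure` attribute used by
#'   [simulate_sample()] to rebuild reads (`pre`, `post`, `insert`, `split`).
#' @export
make_locus <- function(name, motif, n_repeats = 11, flank = 60L,
                       anchor_len = 10L, start_offset = 0L, end_offset = 0L,
                       insert = "", right_flank_prefix = "", snp_rule = NULL,
                       notes = "", panel = "custom", seed = 1L) {
  motif <- toupper(motif)
  if (!grepl(.DNA_RE, motif) || nchar(motif) < 2L || nchar(motif) > 6L) {
    stop("motif must be an A/C/G/T string of length 2-6")
  }
  size <- nchar(motif)
  rc <- rl_parse(as.character(n_repeats))
  if (rc$rem >= size) stop("n_repeats remainder must be < motif length")
  if (flank < anchor_len + max(start_offset, end_offset)) {
    stop("flank (", flank, " bp) too short for anchor_len ", anchor_len,
         " plus offsets")
  }
  insert <- toupper(insert)
  if (nzchar(insert) && !grepl(.DNA_RE, insert)) stop("insert must be A/C/G/T")
  right_flank_prefix <- toupper(right_flank_prefix)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  bp_mod <- start_offset + end_offset + nchar(insert)
  split <- rc$whole %/% 2L
  region_bp <- rc$whole * size + rc$rem
  region <- region_seq(motif, region_bp, insert, split)

  for (attempt in seq_len(200L)) {
    left <- random_dna(flank)
    right <- paste0(right_flank_prefix,
                    random_dna(flank - nchar(right_flank_prefix)))
    if (has_tandem_run(left, motif) || has_tandem_run(right, motif)) next
    # anchor ends start_offset bp before the region; end anchor begins
    # end_offset bp after it
    s_anchor <- substr(left, flank - start_offset - anchor_len + 1L,
                       flank - start_offset)
    e_anchor <- substr(right, end_offset + 1L, end_offset + anchor_len)
    if (s_anchor == e_anchor) next
    ref <- paste0(left, region, right)
    if (count_occurrences(s_anchor, ref) != 1L) next
    if (count_occurrences(e_anchor, ref) != 1L) next
    locus <- str_locus(name = name, reference_sequence = ref,
                       start_anchor = s_anchor, end_anchor = e_anchor,
                       repeat_size = size, bp_modifier = bp_mod,
                       reference_repeat_count = rl_label(rc$whole, rc$rem),
                       snp_rule = snp_rule, notes = notes, panel = panel)
    v <- validate_locus(locus)
    if (!v$ok || length(v$warnings)) next
    attr(locus, "structure") <- list(
      motif = motif,
      pre = substr(ref, 1L, flank),
      post = substr(ref, flank + nchar(region) + 1L, nchar(ref)),
      insert = insert, split = split)
    return(locus)
  }
  stop("make_locus: could not generate valid flanks for ", name,
       " in 200 attempts (constraints too tight)")
}

#' PCR stutter and sequencing-noise model
#'
#' Parameterises the error taxonomy of amplicon STR sequencing: stutter reads
#' whose repeat count is shifted by whole units (predominantly one repeat
#' shorter), low-frequency partial-repeat artifacts (noise), and per-base
#' substitution errors (which do not change the measured length but can
#' destroy an anchor match).
#'
#' Defaults are the conditions used throughout the package's validation:
#' stutter probability 4% per read, 80% of stutter events at -1 repeat with
#' the remainder split between +1 and -2, partial-repeat artifacts at 0.05%,
#' and substitutions at 0.3% per base.
#'
#' @param stutter_prob probability a read's repeat count is shifted.
#' @param minus_one_weight fraction of stutter events at -1 repeat; the rest
#'   is split equally between +1 and -2.
#' @param partial_noise_prob probability of a partial-repeat artifact (a
#'   random 1..repeat_size-1 bp insertion or deletion in the repeat region).
#' @param substitution_rate per-base substitution error probability.
#' @return an object of class `stutter_model`.
#' @export
stutter_model <- function(stutter_prob = 0.04, minus_one_weight = 0.8,
                          partial_noise_prob = 5e-4,
                          substitution_rate = 0.003) {
  p <- c(stutter_prob, minus_one_weight, partial_noise_prob, substitution_rate)
  if (any(p < 0) || any(p > 1)) stop("all stutter_model parameters must be in [0, 1]")
  structure(list(stutter_prob = stutter_prob,
                 minus_one_weight = minus_one_weight,
                 partial_noise_prob = partial_noise_prob,
                 substitution_rate = substitution_rate),
            class = "stutter_model")
}

#' Describe one mixture component
#'
#' @param genotype named list, locus name -> data.frame with columns `length`
#'   (repeat-length labels) and `copies` (integer copy numbers >= 1). Helper
#'   [genotype_entry()] builds one element.
#' @param weight mixing weight of this component.
#' @return an object of class `sim_component`.
#' @export
sim_component <- function(genotype, weight = 1) {
  stopifnot(is.list(genotype), length(names(genotype)) == length(genotype))
  genotype <- lapply(genotype, function(g) {
    g <- as.data.frame(g)
    stopifnot(all(c("length", "copies") %in% names(g)))
    g$length <- as.character(g$length)
    g$copies <- as.integer(g$copies)
    if (any(g$copies < 1L)) stop("copy numbers must be >= 1")
    g
  })
  structure(list(genotype = genotype, weight = as.numeric(weight)),
            class = "sim_component")
}

#' @rdname sim_component
#' @param length repeat-length labels of the component's alleles at one locus.
#' @param copies integer copy number per allele (recycled).
#' @export
genotype_entry <- function(length, copies = 1L) {
  data.frame(length = as.character(length),
             copies = as.integer(rep_len(copies, base::length(length))))
}

#' Full generative description of a synthetic sample
#'
#' @param loci a [str_panel()] or list of [make_locus()] loci (each must carry
#'   the simulator `structure` attribute).
#' @param components list of [sim_component()]s; weights must sum to 1
#'   (within 1e-6).
#' @param reads_per_locus reads emitted per locus.
#' @param stutter a [stutter_model()].
#' @param read_length reads are truncated to this length (the amplicon may be
#'   shorter).
#' @param seed integer seed; identical specs give byte-identical output.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(loci, components, reads_per_locus = 1000L,
                     stutter = stutter_model(), read_length = 250L,
                     seed = 1L) {
  if (inherits(loci, "str_panel")) loci <- loci$loci
  if (inherits(loci, "str_locus")) loci <- list(loci)
  stopifnot(all(vapply(loci, inherits, logical(1), "str_locus")))
  for (l in loci) {
    if (is.null(attr(l, "structure"))) {
      stop("locus ", l$name, " lacks the simulator structure attribute; ",
           "build simulation loci with make_locus()")
    }
  }
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (inherits(components, "sim_component")) components <- list(components)
  stopifnot(all(vapply(components, inherits, logical(1), "sim_component")))
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) stop("component weights must sum to 1 (got ", sum(w), ")")
  for (comp in components) {
    missing <- setdiff(names(loci), names(comp$genotype))
    if (length(missing)) {
      stop("component genotype missing locus/loci: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(loci = loci, components = components,
                 reads_per_locus = as.integer(reads_per_locus),
                 stutter = stutter, read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Apply per-read substitution counts, vectorised: one pass per remaining
# substitution. Positions are drawn independently per pass, so a read can
# (rarely) be hit twice at the same position; the replacement base is always
# different from the current one.
apply_substitutions <- function(reads, nsub) {
  k <- 1L
  repeat {
    sel <- which(nsub >= k)
    if (!length(sel)) break
    len <- nchar(reads[sel])
    pos <- floor(stats::runif(length(sel)) * len) + 1L
    cur <- substring(reads[sel], pos, pos)
    new <- .BASES[(match(cur, .BASES) + sample.int(3L, length(sel),
                                                   replace = TRUE) - 1L) %% 4L + 1L]
    substring(reads[sel], pos, pos) <- new
    k <- k + 1L
  }
  reads
}

#' Simulate amplicon reads with truth
#'
#' Generates `reads_per_locus` reads per locus. For each read: a component is
#' drawn by mixing weight, an allele by copy-number fraction within that
#' component's genotype, a stutter shift is applied with probability
#' `stutter_prob` (-1 repeat with weight `minus_one_weight`, else +1/-2
#' equally), a partial-repeat artifact with probability `partial_noise_prob`
#' (insertion or deletion of 1..repeat_size-1 bp, equally likely), and
#' per-base substitutions at `substitution_rate`. The read is the amplicon
#' (left flank + repeat region + right flank) truncated to `read_length`,
#' with uniform Phred-30 qualities in FASTQ output.
#'
#' Fully reproducible: the same `sim_spec` yields byte-identical reads and
#' truth.
#'
#' @param spec a [sim_spec()].
#' @param fastq optional path; when given, reads are written as FASTQ (add
#'   `.gz` for gzip).
#' @param truth optional path for the truth table (CSV: read id, component,
#'   locus, true length, emitted length, event).
#' @return a list with `reads` (named character vector, names are read ids),
#'   `truth` (data.frame), and the paths written (or `NULL`).
#' @export
simulate_sample <- function(spec, fastq = NULL, truth = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  sm <- spec$stutter
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  n <- spec$reads_per_locus
  all_reads <- character(0)
  all_truth <- vector("list", length(spec$loci))

  for (li in seq_along(spec$loci)) {
    locus <- spec$loci[[li]]
    st <- attr(locus, "structure")
    size <- locus$repeat_size
    comp_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    true_bp <- integer(n)
    for (ci in seq_along(spec$components)) {
      sel <- comp_idx == ci
      if (!any(sel)) next
      g <- spec$components[[ci]]$genotype[[locus$name]]
      bp <- rl_bp(g$length, size)
      ai <- sample.int(nrow(g), sum(sel), replace = TRUE,
                       prob = g$copies / sum(g$copies))
      true_bp[sel] <- bp[ai]
    }
    emit_bp <- true_bp
    event <- rep("none", n)
    # stutter: whole-unit shifts
    is_st <- stats::runif(n) < sm$stutter_prob
    if (any(is_st)) {
      shift <- sample(c(-1L, 1L, -2L), sum(is_st), replace = TRUE,
                      prob = c(sm$minus_one_weight,
                               (1 - sm$minus_one_weight) / 2,
                               (1 - sm$minus_one_weight) / 2))
      emit_bp[is_st] <- pmax(size, emit_bp[is_st] + shift * size)
      event[is_st] <- sprintf("stutter%+d", shift)
    }
    # partial-repeat artifact: +/- 1..size-1 bp
    is_pa <- stats::runif(n) < sm$partial_noise_prob
    if (any(is_pa)) {
      delta <- sample(c(-1L, 1L), sum(is_pa), replace = TRUE) *
        sample.int(size - 1L, sum(is_pa), replace = TRUE)
      emit_bp[is_pa] <- pmax(1L, emit_bp[is_pa] + delta)
      event[is_pa] <- ifelse(event[is_pa] == "none", "partial",
                             paste0(event[is_pa], "+partial"))
    }
    # assemble reads; few distinct (component-independent) span lengths
    reads <- character(n)
    for (bp in unique(emit_bp)) {
      sel <- emit_bp == bp
      reads[sel] <- paste0(st$pre,
                           region_seq(st$motif, bp, st$insert, st$split),
                           st$post)
    }
    reads <- substr(reads, 1L, spec$read_length)
    # substitutions
    if (sm$substitution_rate > 0) {
      nsub <- stats::rbinom(n, nchar(reads), sm$substitution_rate)
      hit <- nsub > 0L
      if (any(hit)) {
        reads <- apply_substitutions(reads, nsub)
        event[hit] <- ifelse(event[hit] == "none", "substitution",
                             paste0(event[hit], "+substitution"))
      }
    }
    ids <- sprintf("sim_%s_%06d", locus$name, seq_len(n))
    names(reads) <- ids
    all_reads <- c(all_reads, reads)
    all_truth[[li]] <- data.frame(
      read_id = ids,
      component = comp_idx,
      locus = locus$name,
      true_length = rl_label(true_bp %/% size, true_bp %% size),
      emitted_length = rl_label(emit_bp %/% size, emit_bp %% size),
      event = event,
      row.names = NULL)
  }
  truth_df <- do.call(rbind, all_truth)

  if (!is.null(fastq)) {
    con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "wb") else file(fastq, "wb")
    qual <- strrep("I", nchar(all_reads))
    rec <- rbind(paste0("@", names(all_reads)), unname(all_reads), "+", qual)
    writeLines(as.vector(rec), con)
    close(con)
  }
  if (!is.null(truth)) {
    utils::write.csv(truth_df, truth, row.names = FALSE, quote = FALSE)
  }
  list(reads = all_reads, truth = truth_df, fastq = fastq, truth_path = truth)
}

#' Analytic expected repeat-length spectrum
#'
#' Closed-form expectation of the emitted repeat-length distribution at one
#' locus under a [sim_spec()]: mixing weights x copy-number fractions,
#' composed with the stutter-shift distribution and the partial-artifact
#' distribution. Substitutions do not alter length and are ignored (they thin
#' calls uniformly across lengths). The returned fractions sum to 1.
#'
#' @param spec a [sim_spec()].
#' @param locus locus name.
#' @return named numeric vector, repeat-length label -> expected fraction,
#'   sorted by repeat length.
#' @export
expected_spectrum <- function(spec, locus) {
  stopifnot(inherits(spec, "sim_spec"))
  l <- spec$loci[[locus]]
  if (is.null(l)) stop("unknown locus: ", locus)
  size <- l$repeat_size
  sm <- spec$stutter
  acc <- new.env(parent = emptyenv())
  add <- function(bp, p) {
    key <- as.character(bp)
    assign(key, (get0(key, envir = acc) %||% 0) + p, envir = acc)
  }
  shift_probs <- c(`0` = 1 - sm$stutter_prob,
                   `-1` = sm$stutter_prob * sm$minus_one_weight,
                   `1` = sm$stutter_prob * (1 - sm$minus_one_weight) / 2,
                   `-2` = sm$stutter_prob * (1 - sm$minus_one_weight) / 2)
  deltas <- if (size > 1L) c(-(1:(size - 1L)), 1:(size - 1L)) else integer(0)
  for (comp in spec$components) {
    g <- comp$genotype[[locus]]
    cf <- g$copies / sum(g$copies)
    for (ai in seq_len(nrow(g))) {
      base_bp <- rl_bp(g$length[ai], size)
      for (sh in names(shift_probs)) {
        p1 <- comp$weight * cf[ai] * shift_probs[[sh]]
        if (p1 <= 0) next
        bp1 <- max(size, base_bp + as.integer(sh) * size)
        add(bp1, p1 * (1 - sm$partial_noise_prob))
        pd <- p1 * sm$partial_noise_prob / length(deltas)
        if (length(deltas) && pd > 0) {
          for (d in deltas) add(max(1L, bp1 + d), pd)
        }
      }
    }
  }
  bp <- as.integer(ls(acc))
  frac <- vapply(as.character(bp), get, numeric(1), envir = acc)
  labels <- rl_label(bp %/% size, bp %% size)
  out <- stats::setNames(as.numeric(frac), labels)
  out <- out[out > 0]
  out[rl_sort(names(out))]
}
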