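#' Count repeat units in a single read
#'
#' Locates the two reference flanks in the read (allowing up to
#' `max_mismatch_frac` edit distance each), extracts the tract between them
#' and counts it unit by unit: a unit within one mismatch of the motif is a
#' repeat, anything else is recorded as an interruption.  Interruptions count
#' toward the total tract length (a tract of 313 motif units plus 21
#' interrupting units is reported as 334 with 21 interruptions) and are also
#' listed individually.  When only one flank is present in the read the count
#' covers the units seen before the read ends and is flagged non-spanning
#' (a lower bound); with neither flank the read yields a no-call (NA).
#'
#' @param read_sequence read bases, reference orientation
#' @param motif repeat unit (>= 2 bp)
#' @param left_flank,right_flank reference sequence immediately flanking the
#'   tract (>= 15 bp each)
#' @param max_mismatch_frac maximum edit distance when locating a flank,
#'   as a fraction of flank length; default 0.2
#' @return list: `repeat_count` (total units; NA for no-call),
#'   `interruptions` data.frame(offset_units, unit), `spanning` flag
#' @export
count_repeats_in_read <- function(read_sequence, motif, left_flank, right_flank,
                                  max_mismatch_frac = 0.2) {
  check_nucleotides(motif)
  if (nchar(motif) < 2) stop("motif must be >= 2 bp")
  if (nchar(left_flank) < 15 || nchar(right_flank) < 15)
    stop("flanks must be >= 15 bp")
  no_call <- list(repeat_count = NA_integer_,
                  interruptions = empty_interruptions(), spanning = FALSE)
  l <- find_flank(read_sequence, left_flank, max_mismatch_frac, from = 1)
  r_from <- if (is.na(l)) 1 else l + 1
  r <- find_flank(read_sequence, right_flank, max_mismatch_frac, from = r_from,
                  want = "start")
  if (is.na(l) && is.na(r)) return(no_call)
  if (!is.na(l) && !is.na(r)) {
    tract <- substr(read_sequence, l + 1, r - 1)
    res <- count_tract_units(tract, motif, from_right = FALSE)
    res$spanning <- TRUE
    return(res)
  }
  if (!is.na(l)) {
    tract <- substr(read_sequence, l + 1, nchar(read_sequence))
    res <- count_tract_units(tract, motif, from_right = FALSE)
  } else {
    tract <- substr(read_sequence, 1, r - 1)
    res <- count_tract_units(tract, motif, from_right = TRUE)
  }
  res$spanning <- FALSE
  res
}

empty_interruptions <- function() {
  data.frame(offset_units = integer(0), unit = character(0), stringsAsFactors = FALSE)
}

# last position of best match for a flank (want = "end"), or first position
# (want = "start"); NA when not found within the edit budget
find_flank <- function(seq, flank, max_mismatch_frac, from = 1, want = c("end", "start")) {
  want <- match.arg(want)
  budget <- ceiling(max_mismatch_frac * nchar(flank))
  sub <- substr(seq, from, nchar(seq))
  if (!nzchar(sub)) return(NA_integer_)
  m <- Biostrings::matchPattern(flank, Biostrings::DNAString(sub),
                                max.mismatch = budget, with.indels = TRUE)
  if (!length(m)) return(NA_integer_)
  if (want == "end") from - 1 + BiocGenerics::end(m)[1]
  else from - 1 + BiocGenerics::start(m)[1]
}

# greedy unit-by-unit scan; no indels within a unit (the design is
# transparent and oracle-checkable); trailing partial unit ignored
count_tract_units <- function(tract, motif, from_right = FALSE) {
  mlen <- nchar(motif)
  tlen <- nchar(tract)
  n_units <- tlen %/% mlen
  if (n_units == 0)
    return(list(repeat_count = 0L, interruptions = empty_interruptions()))
  offs <- if (from_right) tlen - mlen * (n_units:1) else mlen * (0:(n_units - 1))
  units <- substring(tract, offs + 1, offs + mlen)
  mm <- hamming_to(units, motif)
  is_int <- mm > 1
  ints <- if (any(is_int))
    data.frame(offset_units = which(is_int) - 1L, unit = units[is_int],
               stringsAsFactors = FALSE)
  else empty_interruptions()
  list(repeat_count = n_units, interruptions = ints)
}

hamming_to <- function(units, motif) {
  mchars <- strsplit(motif, "")[[1]]
  vapply(strsplit(units, ""), function(u) {
    if (length(u) != length(mchars)) return(length(mchars))
    sum(u != mchars)
  }, integer(1))
}

#' Repeat profile of an STR locus
#'
#' Runs [count_repeats_in_read()] on every read overlapping the locus, using
#' flanks taken from the reference around the tract.  Spanning reads carry
#' exact counts; clipped/truncated reads carry lower bounds.  Spanning counts
#' are clustered into at most two modal alleles (the largest gap splits the
#' counts when the spread warrants two modes); lower bounds never define
#' modes but do update `max_observed`.
#'
#' @param aln alignment frame
#' @param query an STR [query_str()] whose locus is the reference tract
#' @param reference reference sequences (named character, DNAStringSet,
#'   FASTA path, or a simulator genome)
#' @param th [thresholds()]
#' @param flank_len flank length in bp (default 30)
#' @param max_mismatch_frac see [count_repeats_in_read()]
#' @return list of class `lrc_repeat_profile`
#' @export
profile_str_locus <- function(aln, query, reference, th = thresholds(),
                              flank_len = 30, max_mismatch_frac = 0.2) {
  stopifnot(query$kind == "STR")
  seqs <- ref_seq_of(reference)
  if (!query$locus$chrom %in% names(seqs))
    stop("locus contig absent from reference: ", query$locus$chrom)
  chrom_seq <- seqs[[query$locus$chrom]]
  s <- query$locus$start; e <- query$locus$end
  if (e > nchar(chrom_seq)) stop("STR locus beyond end of contig")
  left_flank <- substr(chrom_seq, s - flank_len + 1, s)
  right_flank <- substr(chrom_seq, e + 1, e + flank_len)
  idx <- which(depth_eligible(aln, th) & aln$chrom == query$locus$chrom &
                 aln$start < e + flank_len & aln$end > s - flank_len &
                 !is.na(aln$seq))
  per <- lapply(idx, function(i) {
    cr <- count_repeats_in_read(aln$seq[i], query$motif, left_flank, right_flank,
                                max_mismatch_frac)
    if (is.na(cr$repeat_count)) return(NULL)
    list(read_id = aln$read_id[i], repeat_count = cr$repeat_count,
         spanning = cr$spanning, interruptions = cr$interruptions)
  })
  per <- Filter(Negate(is.null), per)
  per_read <- data.frame(
    read_id = vapply(per, `[[`, character(1), "read_id"),
    repeat_count = vapply(per, `[[`, integer(1), "repeat_count"),
    spanning = vapply(per, `[[`, logical(1), "spanning"),
    n_interruptions = vapply(per, function(p) nrow(p$interruptions), integer(1)),
    stringsAsFactors = FALSE)
  interruptions <- do.call(rbind, lapply(per, function(p) {
    if (!nrow(p$interruptions)) return(NULL)
    cbind(read_id = p$read_id, p$interruptions, stringsAsFactors = FALSE)
  }))
  if (is.null(interruptions))
    interruptions <- cbind(read_id = character(0), empty_interruptions())
  structure(list(
    locus = query$locus, motif = query$motif, per_read = per_read,
    interruptions = interruptions,
    max_observed = if (nrow(per_read)) max(per_read$repeat_count) else 0L,
    allele_summary = cluster_allele_modes(per_read$repeat_count[per_read$spanning]),
    depth = local_depth(aln, query$locus, th)),
    class = "lrc_repeat_profile")
}

# <=2 modes: split sorted spanning counts at the largest gap when the counts
# spread over more than `min_sep` units
cluster_allele_modes <- function(counts, min_sep = 6) {
  if (!length(counts))
    return(data.frame(repeat_count = numeric(0), n_reads = integer(0)))
  counts <- sort(counts)
  if (diff(range(counts)) < min_sep) {
    return(data.frame(repeat_count = round_half_up(median(counts)),
                      n_reads = length(counts)))
  }
  gaps <- diff(counts)
  cut <- which.max(gaps)
  g1 <- counts[seq_len(cut)]; g2 <- counts[(cut + 1):length(counts)]
  data.frame(repeat_count = c(round_half_up(median(g1)), round_half_up(median(g2))),
             n_reads = c(length(g1), length(g2)))
}

#' @export
print.lrc_repeat_profile <- function(x, ...) {
  cat(sprintf("<repeat profile> %s x %s:%s-%s  depth %s\n", x$motif,
              x$locus$chrom, format(x$locus$start + 1, big.mark = ","),
              format(x$locus$end, big.mark = ","), format(x$depth)))
  cat(sprintf("  %d reads counted (%d spanning), max observed %d units, %d interruption(s)\n",
              nrow(x$per_read), sum(x$per_read$spanning), x$max_observed,
              nrow(x$interruptions)))
  if (nrow(x$allele_summary)) {
    cat("  alleles: ", paste(sprintf("%d units (%d reads)",
                                     x$allele_summary$repeat_count,
                                     x$allele_summary$n_reads), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Decide an STR query from its repeat profile
#'
#' Depth below `min_genomic_depth` gives `insufficient_coverage`.  Otherwise
#' the expansion is `confirmed` when any per-read count -- spanning or a
#' clipped-read lower bound -- reaches the reportable pathogenic threshold
#' (comparison is >= by default; set `str_count_ge = FALSE` in
#' [thresholds()] for strict >).  The mosaic range summarizes length
#' variability among expanded reads.
#'
#' @param profile from [profile_str_locus()]
#' @param query the matching STR query
#' @param th [thresholds()]
#' @return list: `result` ([confirmation_result()]) and `decision`
#'   (class `lrc_str_decision`)
#' @export
decide_str <- function(profile, query, th = thresholds()) {
  stopifnot(query$kind == "STR")
  if (!identical(profile$motif, query$motif))
    stop("profile motif ", profile$motif, " does not match query motif ", query$motif)
  thr <- query$pathogenic_threshold
  hit <- if (isTRUE(th$str_count_ge)) profile$per_read$repeat_count >= thr
         else profile$per_read$repeat_count > thr
  expanded <- profile$per_read$repeat_count[hit]
  decision <- structure(list(
    status = NA_character_, pathogenic_threshold = thr,
    expanded_reads = length(expanded),
    mosaic_range = if (length(expanded)) range(expanded) else c(NA_real_, NA_real_)),
    class = "lrc_str_decision")
  if (profile$depth < th$min_genomic_depth) {
    decision$status <- "insufficient_coverage"
    return(list(result = confirmation_result(query$query_id, "STR",
                                             "insufficient_coverage", profile$depth,
                                             evidence = list(),
                                             notes = sprintf("local depth %s < %d",
                                                             format(profile$depth),
                                                             th$min_genomic_depth)),
                decision = decision))
  }
  decision$status <- if (length(expanded)) "confirmed" else "not_confirmed"
  ev <- list(max_observed = profile$max_observed,
             expanded_reads = length(expanded),
             spanning_reads = sum(profile$per_read$spanning),
             n_interruption_reads = length(unique(profile$interruptions$read_id)),
             alleles = profile$allele_summary)
  list(result = confirmation_result(query$query_id, "STR", decision$status,
                                    profile$depth, evidence = ev),
       decision = decision)
}

#' Bundled STR locus catalog
#'
#' Reportable short-tandem-repeat loci with motif, a typical normal-range
#' repeat count and the reportable pathogenic threshold, as used in clinical
#' confirmation of repeat expansions.
#'
#' @return data.frame: gene, motif, normal_count, threshold
#' @export
str_catalog <- function() {
  read.delim(system.file("extdata", "str_catalog.tsv", package = "lrconfirm"),
             stringsAsFactors = FALSE, comment.char = "#")
}
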