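#' Split/clipped-read support at a breakpoint
#'
#' Counts reads presenting a clip boundary (soft or hard clip of at least
#' `min_clip_len` bp) within `window` bp of the queried breakpoint.  When a
#' `partner` breakpoint is supplied, each supporting read is annotated with
#' whether another of its segments (a primary/supplementary split) maps at
#' the partner and on which strand -- the signature that distinguishes
#' deletions, tandem duplications and inversions.
#'
#' @param aln alignment frame
#' @param breakpoint a [gi()] (typically 1 bp)
#' @param window bp window around the breakpoint; default 500
#' @param min_clip_len minimum clip length; default 200
#' @param partner optional partner breakpoint [gi()]
#' @return list of class `lrc_bp_support`: breakpoint, split_reads,
#'   orientations (data.frame)
#' @export
breakpoint_support <- function(aln, breakpoint, window = 500, min_clip_len = 200,
                               partner = NULL) {
  stopifnot(window >= 0)
  reg <- gi(breakpoint$chrom, max(0, breakpoint$start - window), breakpoint$end + window)
  clips <- clipped_reads(aln, reg, min_clip_len)
  ids <- unique(clips$read_id)
  orientations <- lapply(ids, function(id) {
    here <- clips[clips$read_id == id, , drop = FALSE]
    partner_present <- FALSE; partner_strand <- NA_character_
    if (!is.null(partner)) {
      others <- aln[aln$read_id == id & aln$role != "secondary", , drop = FALSE]
      near <- others$chrom == partner$chrom &
        (abs(others$start - partner$start) <= window |
           abs(others$end - partner$end) <= window)
      # the partner segment must be a different record than the one clipped here
      near <- near & !(others$start %in% (here$clip_pos) | others$end %in% (here$clip_pos))
      hit <- others[near, , drop = FALSE]
      if (nrow(hit)) { partner_present <- TRUE; partner_strand <- hit$strand[1] }
    }
    data.frame(read_id = id, strand_here = here$strand[1],
               partner_breakpoint_present = partner_present,
               partner_strand = partner_strand, stringsAsFactors = FALSE)
  })
  orientations <- if (length(orientations)) do.call(rbind, orientations) else
    data.frame(read_id = character(0), strand_here = character(0),
               partner_breakpoint_present = logical(0),
               partner_strand = character(0), stringsAsFactors = FALSE)
  structure(list(breakpoint = breakpoint, split_reads = length(ids),
                 orientations = orientations),
            class = "lrc_bp_support")
}

#' @export
print.lrc_bp_support <- function(x, ...) {
  cat(sprintf("<breakpoint support> %s:%s  %d split/clipped read(s)\n",
              x$breakpoint$chrom, format(x$breakpoint$start + 1, big.mark = ","),
              x$split_reads))
  invisible(x)
}

# segments of each split read near each of two breakpoints; used by the
# orientation-aware confirmers.  Returns per-read segment table.
split_segments_near <- function(aln, bp1, bp2, window) {
  recs <- aln[aln$role != "secondary" & aln$chrom == bp1$chrom, , drop = FALSE]
  near1_end <- abs(recs$end - bp1$start) <= window
  near1_start <- abs(recs$start - bp1$start) <= window
  near2_end <- abs(recs$end - bp2$start) <= window
  near2_start <- abs(recs$start - bp2$start) <= window
  cbind(recs, near1_end = near1_end, near1_start = near1_start,
        near2_end = near2_end, near2_start = near2_start)
}

# local coverage at the two breakpoints, measured in the flanks pointing
# away from the event (the event interior of a deletion is legitimately
# depleted and must not mask adequate junction coverage)
sv_depth <- function(aln, bps, th, pad = 2000) {
  left <- gi(bps[[1]]$chrom, max(0, bps[[1]]$start - pad), max(bps[[1]]$start, 1))
  right <- gi(bps[[2]]$chrom, bps[[2]]$end, bps[[2]]$end + pad)
  d <- vapply(list(left, right), function(w)
    local_depth(aln, w, th, include_supplementary = TRUE), numeric(1))
  min(d)
}

#' Confirm an insertion (including mobile elements)
#'
#' Confirmed when at least `min_support_reads` spanning reads carry an
#' insertion within +/- `ins_len_tol_frac` (default 30%) of the expected
#' length near the queried position.  Clip-only evidence is reported in the
#' notes but is not sufficient alone.  A consensus inserted sequence (from
#' the read whose insertion length is the median) is emitted so the element
#' family can be classified externally, e.g. by BLAST.
#'
#' @param query an SV_INS [query_sv()] with `expected_length`
#' @param aln alignment frame
#' @param th [thresholds()]
#' @return an [confirmation_result()]
#' @export
confirm_insertion <- function(query, aln, th = thresholds()) {
  stopifnot(query$kind == "SV_INS", !is.null(query$expected_length))
  pos <- query$locus$start
  depth <- local_depth(aln, gi(query$locus$chrom, max(0, pos - 1000), pos + 1000), th,
                       include_supplementary = TRUE)
  if (depth < th$min_genomic_depth)
    return(confirmation_result(query$query_id, query$kind, "insufficient_coverage",
                               depth, evidence = list(),
                               notes = sprintf("local depth %s < %d", format(depth),
                                               th$min_genomic_depth)))
  reg <- gi(query$locus$chrom, max(0, pos - th$breakpoint_window),
            pos + th$breakpoint_window)
  min_len <- max(10, floor(query$expected_length * (1 - th$ins_len_tol_frac)))
  obs <- spanning_insertions(aln, reg, min_len = 10)
  ok <- obs$length >= query$expected_length * (1 - th$ins_len_tol_frac) &
    obs$length <= query$expected_length * (1 + th$ins_len_tol_frac)
  support <- obs[ok, , drop = FALSE]
  n_support <- length(unique(support$read_id))
  clips <- clipped_reads(aln, reg, th$min_clip_len)
  consensus <- if (nrow(support)) {
    support$inserted_sequence[which.min(abs(support$length - median(support$length)))]
  } else NA_character_
  status <- if (n_support >= th$min_support_reads) "confirmed" else "not_confirmed"
  confirmation_result(query$query_id, query$kind, status, depth,
                      evidence = list(supporting_reads = n_support,
                                      observed_lengths = support$length,
                                      expected_length = query$expected_length,
                                      consensus_insert = consensus,
                                      clip_only_reads = length(unique(clips$read_id))),
                      notes = if (!n_support && nrow(clips))
                        "clip-only evidence present (not sufficient alone)" else "")
}

#' Confirm an inversion via split-read orientation
#'
#' An inversion is supported by reads mapping partially at one breakpoint as
#' a primary alignment and partially at the other breakpoint as a
#' supplementary alignment in the opposite orientation.  Confirmed when at
#' least `min_support_reads` reads each have two segments, one within the
#' window of each breakpoint, on opposite strands; same-strand split reads
#' (the deletion signature) never count.
#'
#' @param query an SV_INV [query_sv()]
#' @param aln alignment frame
#' @param th [thresholds()]
#' @return an [confirmation_result()]
#' @export
confirm_inversion <- function(query, aln, th = thresholds()) {
  stopifnot(query$kind == "SV_INV")
  bp1 <- query$breakpoints[[1]]; bp2 <- query$breakpoints[[2]]
  if (bp1$chrom != bp2$chrom)
    stop("inversion breakpoints must be on one chromosome (intrachromosomal)")
  depth <- sv_depth(aln, list(bp1, bp2), th)
  if (depth < th$min_genomic_depth)
    return(confirmation_result(query$query_id, query$kind, "insufficient_coverage",
                               depth, evidence = list(),
                               notes = sprintf("local depth %s < %d", format(depth),
                                               th$min_genomic_depth)))
  w <- th$breakpoint_window
  segs <- split_segments_near(aln, bp1, bp2, w)
  support <- 0L; same_strand <- 0L; ids <- character(0)
  for (id in unique(segs$read_id)) {
    rr <- segs[segs$read_id == id, , drop = FALSE]
    at1 <- rr[rr$near1_end | rr$near1_start, , drop = FALSE]
    at2 <- rr[rr$near2_end | rr$near2_start, , drop = FALSE]
    if (!nrow(at1) || !nrow(at2)) next
    pairs <- expand.grid(i = seq_len(nrow(at1)), j = seq_len(nrow(at2)))
    # two *distinct* segments, one per breakpoint
    distinct <- which(at1$start[pairs$i] != at2$start[pairs$j] |
                        at1$end[pairs$i] != at2$end[pairs$j])
    if (!length(distinct)) next
    opp <- any(at1$strand[pairs$i[distinct]] != at2$strand[pairs$j[distinct]])
    if (opp) { support <- support + 1L; ids <- c(ids, id) } else same_strand <- same_strand + 1L
  }
  bs1 <- breakpoint_support(aln, bp1, w, th$min_clip_len, partner = bp2)
  bs2 <- breakpoint_support(aln, bp2, w, th$min_clip_len, partner = bp1)
  status <- if (support >= th$min_support_reads) "confirmed" else "not_confirmed"
  confirmation_result(query$query_id, query$kind, status, depth,
                      evidence = list(opposite_strand_split_reads = support,
                                      same_strand_split_reads = same_strand,
                                      supporting_read_ids = ids,
                                      breakpoint1 = unclass_bp(bs1),
                                      breakpoint2 = unclass_bp(bs2)))
}

unclass_bp <- function(bs) list(chrom = bs$breakpoint$chrom,
                                pos = bs$breakpoint$start,
                                split_reads = bs$split_reads)

#' Confirm a deletion or duplication
#'
#' Events no larger than `max_inread_sv` (default 1 kb) are sought inside
#' single read alignments: a deletion as deletion CIGAR operations of
#' approximately the expected size, a tandem duplication as an insertion of
#' approximately the event size at the junction.  Larger events are
#' confirmed by split reads whose two same-strand segments flank the
#' junction consistently: for a deletion one segment ends at the left
#' breakpoint and its partner resumes at the right breakpoint; for a tandem
#' duplication the junction wraps backwards (a segment ends at the right
#' breakpoint while its partner starts at the left).  Depth-based
#' corroboration of large events belongs to [confirm_cnv()].
#'
#' @param query an SV_DEL or SV_DUP [query_sv()]
#' @param aln alignment frame
#' @param th [thresholds()]
#' @return an [confirmation_result()]
#' @export
confirm_del_dup <- function(query, aln, th = thresholds()) {
  stopifnot(query$kind %in% c("SV_DEL", "SV_DUP"))
  bp1 <- query$breakpoints[[1]]; bp2 <- query$breakpoints[[2]]
  size <- bp2$end - bp1$start
  depth <- sv_depth(aln, list(bp1, bp2), th)
  if (depth < th$min_genomic_depth)
    return(confirmation_result(query$query_id, query$kind, "insufficient_coverage",
                               depth, evidence = list(),
                               notes = sprintf("local depth %s < %d", format(depth),
                                               th$min_genomic_depth)))
  w <- th$breakpoint_window
  if (size <= th$max_inread_sv) {
    reg <- gi(bp1$chrom, max(0, bp1$start - w), bp2$end + w)
    obs <- if (query$kind == "SV_DEL")
      spanning_deletions(aln, reg, min_len = max(10, floor(size * (1 - th$sv_len_tol_frac))))
    else spanning_insertions(aln, reg, min_len = max(10, floor(size * (1 - th$sv_len_tol_frac))))
    ok <- obs$length <= size * (1 + th$sv_len_tol_frac)
    n_support <- length(unique(obs$read_id[ok]))
    status <- if (n_support >= th$min_support_reads) "confirmed" else "not_confirmed"
    return(confirmation_result(query$query_id, query$kind, status, depth,
                               evidence = list(mode = "in-read",
                                               supporting_reads = n_support,
                                               observed_lengths = obs$length[ok],
                                               event_size = size)))
  }
  segs <- split_segments_near(aln, bp1, bp2, w)
  support <- 0L; inconsistent <- 0L
  for (id in unique(segs$read_id)) {
    rr <- segs[segs$read_id == id, , drop = FALSE]
    if (nrow(rr) < 2) next
    hit <- FALSE
    for (i in seq_len(nrow(rr))) for (j in seq_len(nrow(rr))) {
      if (i == j || rr$strand[i] != rr$strand[j]) next
      if (query$kind == "SV_DEL") {
        if (rr$near1_end[i] && rr$near2_start[j]) hit <- TRUE
      } else {
        if (rr$near2_end[i] && rr$near1_start[j]) hit <- TRUE
      }
    }
    if (hit) support <- support + 1L
    else if (any(rr$near1_end | rr$near1_start | rr$near2_end | rr$near2_start))
      inconsistent <- inconsistent + 1L
  }
  bs1 <- breakpoint_support(aln, bp1, w, th$min_clip_len, partner = bp2)
  bs2 <- breakpoint_support(aln, bp2, w, th$min_clip_len, partner = bp1)
  status <- if (support >= th$min_support_reads) "confirmed" else "not_confirmed"
  confirmation_result(query$query_id, query$kind, status, depth,
                      evidence = list(mode = "split-read",
                                      junction_reads = support,
                                      inconsistent_reads = inconsistent,
                                      event_size = size,
                                      breakpoint1 = unclass_bp(bs1),
                                      breakpoint2 = unclass_bp(bs2)))
}
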