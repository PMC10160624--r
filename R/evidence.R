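#' Local depth over an interval
#'
#' Median per-base count of depth-eligible reads (primary alignments; mapq-0
#' excluded by default) covering each base of the interval.  Median rather
#' than mean keeps the statistic robust to edge effects at the interval
#' boundaries.
#'
#' @param aln an `lrc_alignments` frame
#' @param interval a [gi()]
#' @param th [thresholds()]
#' @param reference optional reference (named lengths/sequences); when given,
#'   an interval outside the reference raises an error naming the contig
#' @param include_supplementary also count supplementary segments (used by
#'   the structural-variant logic, where a split read's segments are the
#'   read's presence at the locus); default FALSE
#' @return numeric median depth (0 when uncovered)
#' @export
local_depth <- function(aln, interval, th = thresholds(), reference = NULL,
                        include_supplementary = FALSE) {
  if (gi_width(interval) < 1) stop("interval must be nonempty")
  if (!is.null(reference)) {
    lens <- ref_lengths_of(reference)
    if (!interval$chrom %in% names(lens))
      stop("contig not in reference: ", interval$chrom)
    if (interval$end > lens[[interval$chrom]])
      stop("interval beyond end of contig ", interval$chrom)
  }
  elig <- depth_eligible(aln, th)
  if (include_supplementary)
    elig <- elig | (aln$role == "supplementary" &
                      (isTRUE(th$include_mapq0) | aln$mapq > 0))
  keep <- elig & aln$chrom == interval$chrom &
    aln$start < interval$end & aln$end > interval$start
  if (!any(keep)) return(0)
  cov <- IRanges::coverage(IRanges::IRanges(start = aln$start[keep] + 1,
                                            end = aln$end[keep]))
  v <- as.integer(S4Vectors::window(
    c(cov, S4Vectors::Rle(0L, max(0, interval$end - length(cov)))),
    start = interval$start + 1, end = interval$end))
  median(v)
}

#' Allele pileup at a small-variant locus
#'
#' Classifies every depth-eligible read spanning the VCF-style allele window
#' as `ref`, `alt` or `other` by comparing its aligned bases (insertions and
#' deletions included) against the two alleles.  For indels of >= 5 bp a
#' +/- `indel_len_tol` bp length mismatch still matches the nearer allele
#' (homopolymer noise in nanopore reads); the `other` class is reported but
#' never counts toward confirmation.
#'
#' @param aln alignment frame
#' @param query an SSC/MITO_SSC [query_ssc()]
#' @param th [thresholds()]
#' @return list of class `lrc_pileup`: depth, ref_count, alt_count, other_count
#' @export
allele_pileup <- function(aln, query, th = thresholds()) {
  stopifnot(query$kind %in% c("SSC", "MITO_SSC"))
  check_nucleotides(query$ref_allele); check_nucleotides(query$alt_allele)
  ws <- query$locus$start; we <- query$locus$end
  keep <- which(depth_eligible(aln, th) & aln$chrom == query$locus$chrom &
                  aln$start <= ws & aln$end >= we & !is.na(aln$seq))
  ref_n <- 0L; alt_n <- 0L; other_n <- 0L
  for (i in keep) {
    obs <- aligned_window_seq(aln$start[i], aln$cigar[i], aln$seq[i], ws, we)
    cls <- classify_allele_obs(obs, query$ref_allele, query$alt_allele, th$indel_len_tol)
    if (cls == "ref") ref_n <- ref_n + 1L
    else if (cls == "alt") alt_n <- alt_n + 1L
    else other_n <- other_n + 1L
  }
  structure(list(depth = length(keep), ref_count = ref_n, alt_count = alt_n,
                 other_count = other_n),
            class = "lrc_pileup")
}

classify_allele_obs <- function(obs, ref, alt, tol = 1) {
  if (is.na(obs)) return("other")
  if (identical(obs, ref)) return("ref")
  if (identical(obs, alt)) return("alt")
  event <- abs(nchar(ref) - nchar(alt))
  if (nchar(ref) != nchar(alt) && event >= 5 && tol > 0) {
    dr <- abs(nchar(obs) - nchar(ref)); da <- abs(nchar(obs) - nchar(alt))
    if (da <= tol && dr > tol) return("alt")
    if (dr <= tol && da > tol) return("ref")
  }
  "other"
}

#' @export
print.lrc_pileup <- function(x, ...) {
  cat(sprintf("<pileup> depth %d: ref %d, alt %d, other %d (alt fraction %.4f)\n",
              x$depth, x$ref_count, x$alt_count, x$other_count,
              if (x$depth > 0) x$alt_count / x$depth else NA_real_))
  invisible(x)
}

#' Clipped reads around an interval
#'
#' Every soft/hard-clipped alignment (primary or supplementary) whose clip
#' boundary lies within the interval and whose clip is at least
#' `min_clip_len` bp.  Clusters of such clips mark structural-variant
#' breakpoints.
#'
#' @param aln alignment frame
#' @param interval [gi()]
#' @param min_clip_len minimum clip length in bp (>= 1)
#' @return data.frame: read_id, clip_side, clip_len, clip_pos, strand, role
#' @export
clipped_reads <- function(aln, interval, min_clip_len = 200) {
  stopifnot(min_clip_len >= 1)
  out <- list()
  idx <- which(aln$chrom == interval$chrom & aln$role != "secondary")
  for (i in idx) {
    cl <- cigar_clips(aln$cigar[i])
    if (cl["left"] >= min_clip_len &&
        aln$start[i] >= interval$start && aln$start[i] < interval$end)
      out[[length(out) + 1L]] <- data.frame(
        read_id = aln$read_id[i], clip_side = "left", clip_len = unname(cl["left"]),
        clip_pos = aln$start[i], strand = aln$strand[i], role = aln$role[i],
        stringsAsFactors = FALSE)
    if (cl["right"] >= min_clip_len &&
        aln$end[i] >= interval$start && aln$end[i] < interval$end)
      out[[length(out) + 1L]] <- data.frame(
        read_id = aln$read_id[i], clip_side = "right", clip_len = unname(cl["right"]),
        clip_pos = aln$end[i], strand = aln$strand[i], role = aln$role[i],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_id = character(0), clip_side = character(0),
                      clip_len = numeric(0), clip_pos = numeric(0),
                      strand = character(0), role = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Insertion operations observed within an interval
#'
#' One observation per read per insertion CIGAR operation of at least
#' `min_len` bp anchored in the interval, with the inserted sequence
#' extracted from the read.  Repeat expansions and mobile-element insertions
#' surface here as insertions of the appropriate length.
#'
#' @param aln alignment frame
#' @param interval [gi()]
#' @param min_len minimum insertion length (bp, >= 1)
#' @return data.frame: read_id, position, length, inserted_sequence
#' @export
spanning_insertions <- function(aln, interval, min_len = 30) {
  stopifnot(min_len >= 1)
  idx <- which(aln$chrom == interval$chrom & aln$role != "secondary" &
                 aln$start <= interval$end & aln$end >= interval$start &
                 !is.na(aln$seq))
  out <- lapply(idx, function(i) {
    d <- record_insertions(aln$start[i], aln$cigar[i], aln$seq[i],
                           interval$start, interval$end, min_len)
    if (nrow(d)) cbind(read_id = aln$read_id[i], d, stringsAsFactors = FALSE) else NULL
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(read_id = character(0), position = numeric(0),
                      length = numeric(0), inserted_sequence = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Deletion operations observed within an interval
#'
#' Companion to [spanning_insertions()]: deletion CIGAR operations of at
#' least `min_len` bp overlapping the interval, one row per read per event.
#'
#' @inheritParams spanning_insertions
#' @return data.frame: read_id, position, length
#' @export
spanning_deletions <- function(aln, interval, min_len = 30) {
  stopifnot(min_len >= 1)
  idx <- which(aln$chrom == interval$chrom & aln$role != "secondary" &
                 aln$start < interval$end & aln$end > interval$start)
  out <- lapply(idx, function(i) {
    d <- record_deletions(aln$start[i], aln$cigar[i],
                          interval$start, interval$end, min_len)
    if (nrow(d)) cbind(read_id = aln$read_id[i], d, stringsAsFactors = FALSE) else NULL
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(read_id = character(0), position = numeric(0),
                      length = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

# normalize the various reference representations to named lengths
ref_lengths_of <- function(reference) {
  if (is.numeric(reference)) return(reference)
  if (inherits(reference, "DNAStringSet"))
    return(setNames(Biostrings::width(reference), names(reference)))
  if (is.character(reference) && !is.null(names(reference)))
    return(vapply(reference, nchar, numeric(1)))
  if (is.list(reference) && !is.null(reference$seq))
    return(vapply(reference$seq, nchar, numeric(1)))
  stop("cannot interpret reference; give named sequences or named lengths")
}

# normalize to named character sequences
ref_seq_of <- function(reference) {
  if (inherits(reference, "DNAStringSet"))
    return(setNames(as.character(reference), names(reference)))
  if (is.list(reference) && !is.null(reference$seq)) return(reference$seq)
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    return(setNames(as.character(Biostrings::readDNAStringSet(reference)),
                    sub("\\s.*", "", names(Biostrings::readDNAStringSet(reference)))))
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop("cannot interpret reference; give named sequences or a FASTA path")
}
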