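#' Alignment records as a data frame
#'
#' The package-internal representation of aligned long reads is a plain
#' data.frame (class `lrc_alignments`) with one row per alignment record
#' (a read split across a structural-variant junction contributes one
#' primary and one or more supplementary rows).  Columns:
#' \describe{
#'   \item{read_id}{read name}
#'   \item{chrom}{reference contig}
#'   \item{start,end}{0-based half-open reference span of the aligned part}
#'   \item{strand}{"+" or "-"}
#'   \item{cigar}{CIGAR string; `seq` is stored in reference orientation,
#'     soft clips included, so the query-consuming CIGAR length equals
#'     `nchar(seq)`}
#'   \item{mapq}{mapping quality 0-60}
#'   \item{role}{"primary", "supplementary" or "secondary"}
#'   \item{seq}{read sequence as aligned (may be NA)}
#'   \item{mean_quality}{mean base quality of the read (may be NA)}
#' }
#'
#' @param df a data.frame with the columns above
#' @return validated `lrc_alignments` data.frame
#' @export
alignment_frame <- function(df) {
  need <- c("read_id", "chrom", "start", "end", "strand", "cigar", "mapq",
            "role", "seq", "mean_quality")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment frame missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  if (nrow(df)) {
    bad_role <- !df$role %in% c("primary", "supplementary", "secondary")
    if (any(bad_role)) stop("bad role in record(s): ", paste(df$read_id[bad_role][1], collapse = ","))
    for (i in seq_len(nrow(df))) {
      if (!is.na(df$seq[i]) && nzchar(df$cigar[i])) {
        ql <- cigar_query_len(df$cigar[i])
        if (ql != nchar(df$seq[i]))
          stop("record ", df$read_id[i], ": CIGAR query length ", ql,
               " != sequence length ", nchar(df$seq[i]))
      }
    }
  }
  class(df) <- c("lrc_alignments", "data.frame")
  df
}

empty_alignment_frame <- function() {
  alignment_frame(data.frame(read_id = character(0), chrom = character(0),
                             start = numeric(0), end = numeric(0),
                             strand = character(0), cigar = character(0),
                             mapq = integer(0), role = character(0),
                             seq = character(0), mean_quality = numeric(0),
                             stringsAsFactors = FALSE))
}

# rows eligible for depth and pileup evidence: primary alignments, and
# (by default) mapq > 0
depth_eligible <- function(aln, th = thresholds()) {
  aln$role == "primary" & (isTRUE(th$include_mapq0) | aln$mapq > 0)
}

#' Read alignments from a SAM/BAM file
#'
#' Reads a coordinate-sorted alignment file into the package's alignment
#' frame.  SAM input is converted (and indexed) through Rsamtools.  With a
#' `region`, only records overlapping it are returned; this requires an
#' index (a missing `.bai` raises an error).
#'
#' @param path SAM or BAM file
#' @param region optional [gi()] restricting the query
#' @return an `lrc_alignments` data.frame
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else bam <- path
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq", "qual")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what)
  } else {
    if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("region query requires a BAM index (.bai) for ", bam)
    header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!region$chrom %in% names(header)) return(empty_alignment_frame())
    gr <- GenomicRanges::GRanges(region$chrom,
                                 IRanges::IRanges(region$start + 1, max(region$end, region$start + 1)))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  pieces <- lapply(res, function(x) {
    n <- length(x$qname)
    if (!n) return(NULL)
    role <- ifelse(bitwAnd(x$flag, 2048L) > 0L, "supplementary",
                   ifelse(bitwAnd(x$flag, 256L) > 0L, "secondary", "primary"))
    seqs <- as.character(x$seq)
    seqs[!nzchar(seqs)] <- NA_character_
    quals <- as.character(x$qual)
    mq <- vapply(quals, function(q) {
      if (is.na(q) || q == "*" || !nzchar(q)) return(NA_real_)
      mean(as.integer(charToRaw(q)) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(read_id = x$qname, chrom = as.character(x$rname),
               start = x$pos - 1,
               end = x$pos - 1 + vapply(x$cigar, cigar_ref_len, numeric(1), USE.NAMES = FALSE),
               strand = as.character(x$strand), cigar = x$cigar,
               mapq = x$mapq, role = role, seq = seqs, mean_quality = mq,
               stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(empty_alignment_frame())
  out <- do.call(rbind, pieces)
  if (!is.null(region)) {
    keep <- out$chrom == region$chrom & out$start < region$end & out$end > region$start
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  alignment_frame(out)
}

#' Write an alignment frame to a SAM file
#'
#' @param aln an `lrc_alignments` data.frame
#' @param ref_lengths named vector of contig lengths
#' @param path output path (plain-text SAM)
#' @return `path`, invisibly
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(ref_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(ref_lengths[[chrom]])), con)
  if (nrow(aln)) {
    ord <- order(match(aln$chrom, names(ref_lengths)), aln$start)
    aln <- aln[ord, , drop = FALSE]
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(aln$role == "supplementary", 2048L, ifelse(aln$role == "secondary", 256L, 0L))
    seq <- ifelse(is.na(aln$seq), "*", aln$seq)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     aln$read_id, flag, aln$chrom, as.integer(aln$start + 1),
                     as.integer(aln$mapq), aln$cigar, seq)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @export
print.lrc_alignments <- function(x, ...) {
  cat(sprintf("<alignments> %d records, %d reads, %d contig(s)\n",
              nrow(x), length(unique(x$read_id)), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x)[, c("read_id", "chrom", "start", "end", "strand", "mapq", "role")], 6))
  invisible(x)
}
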