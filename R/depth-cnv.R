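#' Depth-normalized copy-number track
#'
#' Per-window mean depth divided by the genome-wide expectation (the median
#' over autosomal windows), scaled so that the diploid state sits at 1.0 --
#' a heterozygous deletion drops to ~0.5, a heterozygous duplication rises
#' to ~1.5.  The median normalizer makes the track invariant under any
#' global scaling of coverage (no GC correction is applied in this
#' implementation).
#'
#' @param aln alignment frame
#' @param reference reference (named lengths, sequences, or simulator genome)
#' @param window_size window width in bp (>= 1000); default 100 kb --
#'   depth-only evidence is most reliable for events of ~300 kb and larger,
#'   i.e. at least three windows
#' @param th [thresholds()]
#' @return data.frame of class `lrc_copytrack`: chrom, start, end,
#'   raw_depth, normalized_copy
#' @export
copy_track <- function(aln, reference, window_size = 1e5, th = thresholds()) {
  if (window_size < 1000) stop("window_size must be >= 1 kb")
  lens <- ref_lengths_of(reference)
  el <- depth_eligible(aln, th)
  rows <- list()
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    starts <- seq(0, max(0, L - 1), by = window_size)
    ends <- pmin(starts + window_size, L)
    keep <- el & aln$chrom == chrom
    if (any(keep)) {
      cov <- IRanges::coverage(IRanges::IRanges(aln$start[keep] + 1, aln$end[keep]),
                               width = L)
      vm <- IRanges::viewMeans(IRanges::Views(cov, start = starts + 1, end = ends))
    } else vm <- rep(0, length(starts))
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                raw_depth = as.numeric(vm), stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, rows); rownames(track) <- NULL
  auto <- is_autosome(track$chrom)
  if (!any(auto) || all(track$raw_depth[auto] == 0))
    stop("no autosomal coverage: cannot normalize the copy track")
  norm <- median(track$raw_depth[auto])
  track$normalized_copy <- track$raw_depth / norm
  structure(track, class = c("lrc_copytrack", "data.frame"),
            window_size = window_size)
}

#' Export a copy track as a BED-graph-style TSV
#'
#' @param track from [copy_track()]
#' @param path output file
#' @export
write_copy_track <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "normalized_copy")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Confirm a copy-number variant from the copy track
#'
#' The mean normalized copy over the queried region (windows weighted by
#' overlap) is compared against `expected_copy / 2`: within `cnv_tol`
#' (default 0.2) the CNV is confirmed; within `cnv_tol` of 1.0 the region
#' looks diploid and the CNV is not confirmed; anything else is
#' `not_confirmed` with a discordant-copy note.  Regions under 300 kb are
#' flagged low-confidence for depth-only evidence.
#'
#' @param query a CNV [query_cnv()]
#' @param track from [copy_track()]
#' @param th [thresholds()]
#' @return an [confirmation_result()]
#' @export
confirm_cnv <- function(query, track, th = thresholds()) {
  stopifnot(query$kind == "CNV")
  reg <- query$locus
  sel <- track$chrom == reg$chrom & track$start < reg$end & track$end > reg$start
  if (!any(sel)) stop("query region not covered by the copy track: ", reg$chrom)
  tw <- track[sel, , drop = FALSE]
  wts <- pmin(tw$end, reg$end) - pmax(tw$start, reg$start)
  mean_copy <- sum(tw$normalized_copy * wts) / sum(wts)
  expected <- query$expected_copy / 2
  notes <- character(0)
  if (nrow(tw) < 3) notes <- c(notes, sprintf("only %d window(s) over region", nrow(tw)))
  if (gi_width(reg) < 3e5)
    notes <- c(notes, "region < 300 kb: low confidence for depth-only evidence")
  status <-
    if (abs(mean_copy - expected) <= th$cnv_tol) "confirmed"
    else if (abs(mean_copy - 1) <= th$cnv_tol) "not_confirmed"
    else { notes <- c(notes, sprintf("discordant copy state: observed %.2f, expected %.2f",
                                     mean_copy, expected)); "not_confirmed" }
  confirmation_result(query$query_id, "CNV", status,
                      depth = round(mean(tw$raw_depth)),
                      evidence = list(mean_normalized_copy = mean_copy,
                                      expected_normalized = expected,
                                      n_windows = nrow(tw)),
                      notes = paste(notes, collapse = "; "))
}

#' Per-chromosome ploidy table
#'
#' Per-chromosome per-base coverage divided by the autosomal median and
#' scaled by 2, so an ordinary autosome reads ~2.0, a trisomy ~3.0, and a
#' present sex chromosome ~1.0 per copy.  `predicted_ploidy` is the nearest
#' integer.
#'
#' @param aln alignment frame
#' @param reference reference (named lengths acceptable)
#' @param th [thresholds()]
#' @return data.frame of class `lrc_ploidy`: chrom, predicted_ploidy,
#'   normalized_ploidy, read_coverage
#' @export
chromosome_ploidy <- function(aln, reference, th = thresholds()) {
  lens <- ref_lengths_of(reference)
  if (any(lens <= 0)) stop("zero-length chromosome in reference: ",
                           paste(names(lens)[lens <= 0], collapse = ","))
  el <- depth_eligible(aln, th)
  cov <- vapply(names(lens), function(chrom) {
    keep <- el & aln$chrom == chrom
    sum(aln$end[keep] - aln$start[keep]) / lens[[chrom]]
  }, numeric(1))
  auto <- is_autosome(names(lens))
  if (!any(auto) || all(cov[auto] == 0))
    stop("no autosomal coverage: cannot normalize ploidy")
  np <- cov / median(cov[auto]) * 2
  structure(data.frame(chrom = names(lens),
                       predicted_ploidy = as.integer(round(np)),
                       normalized_ploidy = np,
                       read_coverage = cov,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("lrc_ploidy", "data.frame"))
}

#' Confirm an aneuploidy claim against the ploidy table
#'
#' Confirmed when every queried chromosome's normalized ploidy is within
#' `aneuploidy_tol` (default 0.3) of the expected copy number.
#'
#' @param query an ANEUPLOIDY [query_aneuploidy()]
#' @param ploidy_table from [chromosome_ploidy()]
#' @return an [confirmation_result()]
#' @param th [thresholds()]
#' @export
confirm_aneuploidy <- function(query, ploidy_table, th = thresholds()) {
  stopifnot(query$kind == "ANEUPLOIDY")
  chroms <- query$chroms
  miss <- setdiff(chroms, ploidy_table$chrom)
  if (length(miss)) stop("chromosome absent from ploidy table: ",
                         paste(miss, collapse = ","))
  rows <- ploidy_table[match(chroms, ploidy_table$chrom), , drop = FALSE]
  dev <- abs(rows$normalized_ploidy - query$expected_copy)
  status <- if (all(dev <= th$aneuploidy_tol)) "confirmed" else "not_confirmed"
  confirmation_result(query$query_id, "ANEUPLOIDY", status,
                      depth = round(median(rows$read_coverage)),
                      evidence = list(chrom = rows$chrom,
                                      normalized_ploidy = rows$normalized_ploidy,
                                      expected_copy = query$expected_copy))
}
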