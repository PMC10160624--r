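#' Confirm a small sequence change (SNV / indel < 50 bp)
#'
#' Decision rule: local depth below `min_genomic_depth` (default 12) gives
#' `insufficient_coverage`; otherwise the variant is `confirmed` when at
#' least `min_support_reads` reads carry the alternate allele AND the
#' alternate fraction reaches `min_support_fraction` of the local depth;
#' otherwise `not_confirmed` (the expected variant was inspectable but not
#' observed -- in a validation setting, a false negative of the upstream
#' caller).
#'
#' @param query an SSC [query_ssc()]
#' @param aln alignment frame
#' @param th [thresholds()]
#' @param reference optional, for bounds checking
#' @return an [confirmation_result()]
#' @export
confirm_ssc <- function(query, aln, th = thresholds(), reference = NULL) {
  stopifnot(query$kind == "SSC")
  if (!is.null(reference)) local_depth(aln, query$locus, th, reference) # bounds check
  p <- allele_pileup(aln, query, th)
  if (p$depth < th$min_genomic_depth)
    return(confirmation_result(query$query_id, query$kind, "insufficient_coverage",
                               p$depth, evidence = list(),
                               notes = sprintf("local depth %d < %d", p$depth,
                                               th$min_genomic_depth)))
  ok <- p$alt_count >= th$min_support_reads &&
    p$alt_count / p$depth >= th$min_support_fraction
  confirmation_result(query$query_id, query$kind,
                      if (ok) "confirmed" else "not_confirmed",
                      p$depth, evidence = unclass(p))
}

#' Mitochondrial variant confirmation with heteroplasmy estimate
#'
#' The heteroplasmy fraction is estimated as alt reads over total depth at
#' the locus; the rounded percent uses half-away-from-zero rounding.  Depth
#' below `min_mito_depth` (default 1000) gives `insufficient_coverage`;
#' otherwise the variant is confirmed when at least `min_support_reads`
#' reads carry the alternate allele (no minimum fraction: heteroplasmy down
#' to a few percent is reportable at 1000x+).
#'
#' @param query a MITO_SSC [query_ssc()]
#' @param aln alignment frame
#' @param th [thresholds()]
#' @return list: `result` ([confirmation_result()]) and `estimate`
#'   (class `lrc_heteroplasmy`: alt_count, depth, fraction, percent_rounded)
#' @export
heteroplasmy <- function(query, aln, th = thresholds()) {
  stopifnot(query$kind == "MITO_SSC")
  if (!is_mito_chrom(query$locus$chrom))
    warning("heteroplasmy() on non-mitochondrial contig ", query$locus$chrom)
  p <- allele_pileup(aln, query, th)
  est <- heteroplasmy_estimate(p$alt_count, p$depth)
  if (p$depth < th$min_mito_depth)
    return(list(result = confirmation_result(query$query_id, query$kind,
                                             "insufficient_coverage", p$depth,
                                             evidence = list(),
                                             notes = sprintf("local depth %d < %d",
                                                             p$depth, th$min_mito_depth)),
                estimate = est))
  ok <- p$alt_count >= th$min_support_reads
  list(result = confirmation_result(query$query_id, query$kind,
                                    if (ok) "confirmed" else "not_confirmed",
                                    p$depth,
                                    evidence = c(unclass(p),
                                                 list(fraction = est$fraction,
                                                      percent = est$percent_rounded))),
       estimate = est)
}

#' @rdname heteroplasmy
#' @param alt_count,depth confusion-free counts (alt reads / total reads)
#' @export
heteroplasmy_estimate <- function(alt_count, depth) {
  stopifnot(alt_count >= 0, depth >= 0, alt_count <= depth || depth == 0)
  fraction <- if (depth > 0) alt_count / depth else NA_real_
  structure(list(alt_count = alt_count, depth = depth, fraction = fraction,
                 percent_rounded = if (depth > 0) round_half_up(fraction * 100) else NA_integer_),
            class = "lrc_heteroplasmy")
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.lrc_heteroplasmy <- function(x, ...) {
  cat(sprintf("<heteroplasmy> ~%d%% (%dalt/%sX)\n", x$percent_rounded,
              x$alt_count, format(x$depth, big.mark = ",")))
  invisible(x)
}

#' Read-backed phasing of two small variants
#'
#' Reads spanning both loci are classified into the four joint allele
#' categories.  The pair is called `trans` (alternate alleles on opposite
#' haplotypes) when each single-alt class has at least `min_support_reads`
#' and at most `phase_noise_frac` of double-spanning reads carry both
#' alternates; `cis` symmetrically; otherwise `unphased`.
#'
#' @param q1,q2 two SSC queries on the same chromosome
#' @param aln alignment frame
#' @param th [thresholds()]
#' @return list of class `lrc_phase`: relationship, reads_both,
#'   reads_v1_only, reads_v2_only, reads_neither
#' @export
phase_pair <- function(q1, q2, aln, th = thresholds()) {
  stopifnot(q1$kind %in% c("SSC", "MITO_SSC"), q2$kind %in% c("SSC", "MITO_SSC"))
  if (q1$locus$chrom != q2$locus$chrom)
    stop("phase_pair requires both variants on the same chromosome")
  w1 <- q1$locus; w2 <- q2$locus
  keep <- which(depth_eligible(aln, th) & aln$chrom == w1$chrom &
                  aln$start <= min(w1$start, w2$start) &
                  aln$end >= max(w1$end, w2$end) & !is.na(aln$seq))
  both <- v1 <- v2 <- neither <- 0L
  for (i in keep) {
    o1 <- classify_allele_obs(
      aligned_window_seq(aln$start[i], aln$cigar[i], aln$seq[i], w1$start, w1$end),
      q1$ref_allele, q1$alt_allele, th$indel_len_tol)
    o2 <- classify_allele_obs(
      aligned_window_seq(aln$start[i], aln$cigar[i], aln$seq[i], w2$start, w2$end),
      q2$ref_allele, q2$alt_allele, th$indel_len_tol)
    if (o1 == "other" || o2 == "other") next
    if (o1 == "alt" && o2 == "alt") both <- both + 1L
    else if (o1 == "alt") v1 <- v1 + 1L
    else if (o2 == "alt") v2 <- v2 + 1L
    else neither <- neither + 1L
  }
  n_span <- both + v1 + v2 + neither
  tol <- th$phase_noise_frac * n_span
  k <- th$min_support_reads
  relationship <-
    if (n_span == 0) "unphased"
    else if (v1 >= k && v2 >= k && both <= tol) "trans"
    else if (both >= k && v1 <= tol && v2 <= tol) "cis"
    else "unphased"
  structure(list(pair = c(q1$query_id, q2$query_id), relationship = relationship,
                 reads_both = both, reads_v1_only = v1, reads_v2_only = v2,
                 reads_neither = neither),
            class = "lrc_phase")
}

#' @export
print.lrc_phase <- function(x, ...) {
  cat(sprintf("<phase %s ~ %s> %s (both %d, v1-only %d, v2-only %d, neither %d)\n",
              x$pair[1], x$pair[2], x$relationship, x$reads_both,
              x$reads_v1_only, x$reads_v2_only, x$reads_neither))
  invisible(x)
}
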