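#' Decision thresholds for variant confirmation
#'
#' Bundles every tunable cutoff used by the confirmers.  The two depth floors
#' follow the validated operating procedure for low-pass long-read
#' confirmation: 12x local depth for genomic variants and 1000x for
#' mitochondrial variants; below the floor a query is reported as
#' `insufficient_coverage` rather than refuted.  The remaining knobs
#' operationalize what a reviewer would otherwise judge by eye and are
#' deliberately configurable.
#'
#' @param min_genomic_depth minimum local depth (reads) for nuclear variants; default 12
#' @param min_mito_depth minimum local depth for mitochondrial variants; default 1000
#' @param min_support_reads minimum reads carrying the expected allele/junction; default 3
#' @param min_support_fraction minimum supporting fraction of local depth for
#'   heterozygous small-variant confirmation; default 0.2
#' @param breakpoint_window bp window around a queried breakpoint within which
#'   clip/split evidence counts; default 500 (long-read alignment jitter)
#' @param min_clip_len minimum soft/hard clip length (bp) to count as
#'   breakpoint evidence; default 200
#' @param include_mapq0 count mapq-0 reads in depth and evidence? default FALSE
#'   (multimapping artifacts otherwise inflate depth-based calls)
#' @param indel_len_tol bp tolerance when matching an observed indel of >= 5 bp
#'   against the expected allele (homopolymer noise); default 1; 0 = strict
#' @param phase_noise_frac fraction of double-spanning reads allowed to
#'   contradict a phase call; default 0.1
#' @param ins_len_tol_frac relative tolerance on insertion length; default 0.3
#' @param sv_len_tol_frac relative tolerance on in-read deletion/duplication
#'   length; default 0.3
#' @param max_inread_sv events up to this size (bp) are sought inside single
#'   read alignments (CIGAR-level); larger events use split reads; default 1000
#' @param cnv_tol tolerance on normalized copy (1.0 = diploid); default 0.2
#' @param aneuploidy_tol tolerance on normalized chromosome ploidy; default 0.3
#' @param upd_alt_min_reads,upd_alt_min_frac a UPD locus counts as `alt_seen`
#'   only with at least this many alt reads and alt fraction (single
#'   long-read errors must not overturn a UPD call); defaults 2 and 0.1
#' @param str_count_ge if TRUE (default) an STR count equal to the reportable
#'   threshold confirms (comparison is >=)
#' @return a list of class `lrc_thresholds`
#' @export
thresholds <- function(min_genomic_depth = 12, min_mito_depth = 1000,
                       min_support_reads = 3, min_support_fraction = 0.2,
                       breakpoint_window = 500, min_clip_len = 200,
                       include_mapq0 = FALSE, indel_len_tol = 1,
                       phase_noise_frac = 0.1, ins_len_tol_frac = 0.3,
                       sv_len_tol_frac = 0.3, max_inread_sv = 1000,
                       cnv_tol = 0.2, aneuploidy_tol = 0.3,
                       upd_alt_min_reads = 2, upd_alt_min_frac = 0.1,
                       str_count_ge = TRUE) {
  th <- list(min_genomic_depth = min_genomic_depth, min_mito_depth = min_mito_depth,
             min_support_reads = min_support_reads, min_support_fraction = min_support_fraction,
             breakpoint_window = breakpoint_window, min_clip_len = min_clip_len,
             include_mapq0 = include_mapq0, indel_len_tol = indel_len_tol,
             phase_noise_frac = phase_noise_frac, ins_len_tol_frac = ins_len_tol_frac,
             sv_len_tol_frac = sv_len_tol_frac, max_inread_sv = max_inread_sv,
             cnv_tol = cnv_tol, aneuploidy_tol = aneuploidy_tol,
             upd_alt_min_reads = upd_alt_min_reads, upd_alt_min_frac = upd_alt_min_frac,
             str_count_ge = str_count_ge)
  num <- vapply(th[setdiff(names(th), c("include_mapq0", "str_count_ge"))], identity, numeric(1))
  if (any(num < 0)) stop("all thresholds must be >= 0")
  if (th$min_support_fraction > 1) stop("min_support_fraction must be in [0, 1]")
  structure(th, class = "lrc_thresholds")
}

#' @export
print.lrc_thresholds <- function(x, ...) {
  cat("<lrconfirm thresholds>\n")
  for (n in names(x)) cat(sprintf("  %-22s %s\n", n, format(x[[n]])))
  invisible(x)
}
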