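#' Confirm a batch of variant queries
#'
#' Routes each query to its confirmer: small sequence changes to
#' [confirm_ssc()] (mitochondrial ones to [heteroplasmy()]), STR expansions
#' to [profile_str_locus()] + [decide_str()], structural variants to the
#' split-read confirmers, copy-number and aneuploidy queries to the
#' depth-normalized track and ploidy table (computed once and shared), and
#' UPD queries to [confirm_upd()].  A query whose confirmer raises an error
#' is reported as `not_confirmed` with the error in the notes rather than
#' aborting the batch.
#'
#' @param aln alignment frame (or path to SAM/BAM, read via
#'   [read_alignments()])
#' @param reference reference sequences (named character, DNAStringSet,
#'   FASTA path, or simulator genome)
#' @param queries list of queries from [read_queries()] or the `query_*()`
#'   constructors
#' @param th [thresholds()]
#' @param parental optional parental genotype data.frame for UPD queries
#'   (otherwise read from each query's `parental_vcf`)
#' @param window_size copy-track window (bp)
#' @return list of [confirmation_result()] objects
#' @export
confirm_variants <- function(aln, reference, queries, th = thresholds(),
                             parental = NULL, window_size = 1e5) {
  if (is.character(aln)) aln <- read_alignments(aln)
  kinds <- vapply(queries, `[[`, character(1), "kind")
  track <- NULL; ploidy <- NULL
  if (any(kinds %in% c("CNV", "UPD")))
    track <- copy_track(aln, reference, window_size = window_size, th = th)
  if (any(kinds == "ANEUPLOIDY"))
    ploidy <- chromosome_ploidy(aln, reference, th = th)
  lapply(queries, function(q) {
    tryCatch(switch(q$kind,
      SSC = confirm_ssc(q, aln, th),
      MITO_SSC = heteroplasmy(q, aln, th)$result,
      STR = decide_str(profile_str_locus(aln, q, reference, th), q, th)$result,
      SV_INS = confirm_insertion(q, aln, th),
      SV_INV = confirm_inversion(q, aln, th),
      SV_DEL = confirm_del_dup(q, aln, th),
      SV_DUP = confirm_del_dup(q, aln, th),
      CNV = confirm_cnv(q, track, th),
      ANEUPLOIDY = confirm_aneuploidy(q, ploidy, th),
      UPD = {
        par <- parental
        if (is.null(par) && !is.null(q$parental_vcf))
          par <- read_parental_vcf(q$parental_vcf)
        if (is.null(par)) stop("UPD query requires parental genotypes")
        loci <- select_informative_loci(par, q$locus,
                                        source_parent = q$source_parent)
        confirm_upd(q, aln, loci, th, track)
      },
      stop("no confirmer for kind ", q$kind)),
      error = function(e)
        confirmation_result(q$query_id, q$kind, "not_confirmed", 0,
                            evidence = list(),
                            notes = paste("error:", conditionMessage(e))))
  })
}
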