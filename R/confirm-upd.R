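#' Select informative loci for UPD confirmation
#'
#' An informative locus for uniparental disomy has the non-transmitting
#' parent homozygous-alternate and the UPD-source parent homozygous-
#' reference: under normal biparental inheritance the proband must carry the
#' absent parent's allele at every such locus, so its absence across many
#' loci confirms the UPD.  At least `n_target` loci (default 20, well beyond
#' the historical minimum of two) are drawn spread across the region: the
#' region is split into `n_target` equal bins, one locus per non-empty bin
#' (seeded), topped up from the remainder.
#'
#' @param parental data.frame with columns chrom, pos (0-based), ref, alt,
#'   father_gt, mother_gt (each "ref_hom"/"het"/"alt_hom"/"missing"),
#'   e.g. from [read_parental_vcf()]
#' @param region the UPD region, a [gi()]
#' @param n_target number of loci to select (>= 20 by standard procedure)
#' @param source_parent the parent that contributed both homologs
#' @param seed RNG seed for the within-bin draws
#' @return data.frame of selected loci with a `bin` column
#' @export
select_informative_loci <- function(parental, region, n_target = 20,
                                    source_parent = c("mother", "father"),
                                    seed = 1L) {
  source_parent <- match.arg(source_parent)
  stopifnot(n_target >= 1)
  inreg <- parental$chrom == region$chrom & parental$pos >= region$start &
    parental$pos < region$end
  absent_gt <- if (source_parent == "mother") parental$father_gt else parental$mother_gt
  source_gt <- if (source_parent == "mother") parental$mother_gt else parental$father_gt
  cand <- parental[inreg & absent_gt == "alt_hom" & source_gt == "ref_hom", , drop = FALSE]
  if (nrow(cand) < n_target)
    stop(sprintf(paste0("only %d informative loci available in region, %d required ",
                        "(historical minimum is 2, but the standard procedure asks for %d)"),
                 nrow(cand), n_target, n_target))
  bin_w <- gi_width(region) / n_target
  cand$bin <- pmin(floor((cand$pos - region$start) / bin_w) + 1, n_target)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  picked <- integer(0)
  for (b in sort(unique(cand$bin))) {
    rows <- which(cand$bin == b)
    picked <- c(picked, if (length(rows) == 1) rows else sample(rows, 1))
  }
  left <- setdiff(seq_len(nrow(cand)), picked)
  if (length(picked) < n_target && length(left)) {
    extra <- if (length(left) == 1) left else
      sample(left, min(n_target - length(picked), length(left)))
    picked <- c(picked, extra)
  }
  out <- cand[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parental genotypes from a trio VCF
#'
#' Reads father/mother genotype columns into the categorical form consumed
#' by [select_informative_loci()].
#'
#' @param path VCF with (at least) the two parental sample columns
#' @param father,mother sample column names; defaults "FATHER"/"MOTHER"
#' @return data.frame: chrom, pos (0-based), ref, alt, father_gt, mother_gt
#' @export
read_parental_vcf <- function(path, father = "FATHER", mother = "MOTHER") {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  for (s in c(father, mother))
    if (!s %in% colnames(gt)) stop("sample column missing from VCF: ", s)
  cat_gt <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), "missing",
           ifelse(g == "0/0", "ref_hom",
                  ifelse(g == "1/1", "alt_hom",
                         ifelse(g %in% c("0/1", "1/0"), "het", "missing"))))
  }
  data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS) - 1,
             ref = fix$REF, alt = fix$ALT,
             father_gt = cat_gt(gt[, father]), mother_gt = cat_gt(gt[, mother]),
             stringsAsFactors = FALSE)
}

#' Confirm uniparental disomy
#'
#' Each informative locus is evaluated by allele pileup in the proband's
#' long reads.  A locus reads `alt_seen` only when the absent parent's
#' allele is carried by at least `upd_alt_min_reads` reads and
#' `upd_alt_min_frac` of depth (single long-read errors must not overturn
#' the call); `no_call` when local depth is below `min_genomic_depth`.  The
#' UPD is confirmed when every evaluable locus is `ref_only` AND the
#' regional normalized copy is within `cnv_tol` of 1.0 (ruling out a
#' heterozygous deletion mimicking absence of the alleles).  Any `alt_seen`
#' locus refutes; more than 20% `no_call` loci give `insufficient_coverage`.
#'
#' Under biparental inheritance every informative locus is heterozygous in
#' the proband, so the chance that `n` clean loci all read `ref_only` is
#' essentially zero once n is large (with per-locus dropout rate d it is
#' bounded by d^n); this is the transparency argument behind the 20-locus
#' standard.
#'
#' @param query a UPD [query_upd()]
#' @param aln proband alignment frame
#' @param loci from [select_informative_loci()]
#' @param th [thresholds()]
#' @param track regional [copy_track()] for the deletion rule-out
#' @return an [confirmation_result()]
#' @export
confirm_upd <- function(query, aln, loci, th = thresholds(), track = NULL) {
  stopifnot(query$kind == "UPD")
  reg <- query$locus
  if (any(loci$chrom != reg$chrom | loci$pos < reg$start | loci$pos >= reg$end))
    stop("informative loci outside the UPD query region")
  obs <- character(nrow(loci)); depths <- numeric(nrow(loci)); altc <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    q <- query_ssc(sprintf("%s_locus%d", query$query_id, i), loci$chrom[i],
                   loci$pos[i], loci$ref[i], loci$alt[i], mito = FALSE)
    p <- allele_pileup(aln, q, th)
    depths[i] <- p$depth; altc[i] <- p$alt_count
    obs[i] <- if (p$depth < th$min_genomic_depth) "no_call"
    else if (p$alt_count >= th$upd_alt_min_reads &&
             p$alt_count / p$depth >= th$upd_alt_min_frac) "alt_seen"
    else "ref_only"
  }
  locus_table <- cbind(loci[, c("chrom", "pos", "ref", "alt")],
                       proband_observation = obs, proband_depth = depths,
                       alt_reads = altc, stringsAsFactors = FALSE)
  ev <- list(n_loci = nrow(loci),
             n_ref_only = sum(obs == "ref_only"),
             n_alt_seen = sum(obs == "alt_seen"),
             n_no_call = sum(obs == "no_call"),
             loci = locus_table)
  med_depth <- median(depths)
  if (mean(obs == "no_call") > 0.2)
    return(confirmation_result(query$query_id, "UPD", "insufficient_coverage",
                               med_depth, evidence = list(),
                               notes = sprintf("%d/%d loci below %dx",
                                               sum(obs == "no_call"), length(obs),
                                               th$min_genomic_depth)))
  if (any(obs == "alt_seen"))
    return(confirmation_result(query$query_id, "UPD", "not_confirmed", med_depth,
                               evidence = ev,
                               notes = "absent parent's allele observed: biparental inheritance"))
  copy_ok <- TRUE; copy_note <- "no copy track supplied: deletion not ruled out"
  mean_copy <- NA_real_
  if (!is.null(track)) {
    sel <- track$chrom == reg$chrom & track$start < reg$end & track$end > reg$start
    tw <- track[sel, , drop = FALSE]
    wts <- pmin(tw$end, reg$end) - pmax(tw$start, reg$start)
    mean_copy <- sum(tw$normalized_copy * wts) / sum(wts)
    copy_ok <- abs(mean_copy - 1) <= th$cnv_tol
    copy_note <- if (copy_ok) "" else
      sprintf("regional copy %.2f: deletion not ruled out", mean_copy)
  }
  ev$regional_normalized_copy <- mean_copy
  if (!copy_ok || is.null(track))
    return(confirmation_result(query$query_id, "UPD",
                               if (copy_ok) "confirmed" else "not_confirmed",
                               med_depth, evidence = ev, notes = copy_note))
  confirmation_result(query$query_id, "UPD", "confirmed", med_depth, evidence = ev)
}
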