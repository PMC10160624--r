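#' Variant queries
#'
#' A variant query is a typed candidate variant to confirm against long-read
#' alignments.  Constructors exist per kind; [read_queries()] builds them
#' from a VCF (small variants, mitochondrial variants and SVs) plus an
#' optional sidecar TSV (STR / CNV / ANEUPLOIDY / UPD rows).  All query
#' coordinates are stored 0-based half-open.
#'
#' @param query_id identifier
#' @param chrom contig name
#' @param pos 0-based position of the VCF-style anchor base
#' @param ref,alt reference and alternate alleles (VCF minimal representation,
#'   anchor base included for indels)
#' @param mito force mitochondrial handling; default: inferred from `chrom`
#' @return a list of class `lrc_query`
#' @export
query_ssc <- function(query_id, chrom, pos, ref, alt, mito = is_mito_chrom(chrom)) {
  check_nucleotides(ref); check_nucleotides(alt)
  new_query(query_id, if (mito) "MITO_SSC" else "SSC",
            locus = gi(chrom, pos, pos + nchar(ref)),
            ref_allele = toupper(ref), alt_allele = toupper(alt))
}

#' @rdname query_ssc
#' @param start,end 0-based half-open reference repeat tract
#' @param motif repeat unit (2-6 bp typical)
#' @param pathogenic_threshold reportable repeat-count threshold (> 0)
#' @export
query_str <- function(query_id, chrom, start, end, motif, pathogenic_threshold) {
  check_nucleotides(motif)
  if (nchar(motif) < 2) stop("STR motif must be >= 2 bp")
  if (!is.finite(pathogenic_threshold) || pathogenic_threshold <= 0)
    stop("pathogenic_threshold must be > 0")
  new_query(query_id, "STR", locus = gi(chrom, start, end),
            motif = toupper(motif), pathogenic_threshold = pathogenic_threshold)
}

#' @rdname query_ssc
#' @param type one of "DEL", "DUP", "INS", "INV"
#' @param expected_length expected inserted length in bp (INS only)
#' @export
query_sv <- function(query_id, type, chrom, start, end, expected_length = NULL) {
  type <- match.arg(type, c("DEL", "DUP", "INS", "INV"))
  kind <- paste0("SV_", type)
  if (type == "INS") {
    if (is.null(expected_length)) stop("SV_INS requires expected_length")
    new_query(query_id, kind, locus = gi(chrom, start, max(end, start + 1)),
              expected_length = expected_length)
  } else {
    new_query(query_id, kind, locus = gi(chrom, start, end),
              breakpoints = list(gi(chrom, start, start + 1), gi(chrom, end - 1, end)))
  }
}

#' @rdname query_ssc
#' @param expected_copy expected integer copy number (CNV / aneuploidy)
#' @export
query_cnv <- function(query_id, chrom, start, end, expected_copy) {
  new_query(query_id, "CNV", locus = gi(chrom, start, end),
            expected_copy = as.integer(expected_copy))
}

#' @rdname query_ssc
#' @param chroms one or more chromosome names the ploidy claim covers
#' @export
query_aneuploidy <- function(query_id, chroms, expected_copy) {
  q <- new_query(query_id, "ANEUPLOIDY", locus = gi(chroms[1], 0, 1),
                 expected_copy = as.integer(expected_copy))
  q$chroms <- chroms
  q
}

#' @rdname query_ssc
#' @param source_parent which parent contributed both homologs ("mother"/"father")
#' @param parental_vcf path to the trio genotype VCF (father + mother samples)
#' @export
query_upd <- function(query_id, chrom, start, end,
                      source_parent = c("mother", "father"), parental_vcf = NULL) {
  q <- new_query(query_id, "UPD", locus = gi(chrom, start, end))
  q$source_parent <- match.arg(source_parent)
  q$parental_vcf <- parental_vcf
  q
}

new_query <- function(query_id, kind, locus, ...) {
  structure(c(list(query_id = as.character(query_id), kind = kind, locus = locus),
              list(...)),
            class = "lrc_query")
}

check_nucleotides <- function(x) {
  if (!is.character(x) || length(x) != 1 || !grepl("^[ACGTacgt]+$", x))
    stop("allele/motif must be a nonempty A/C/G/T string, got: ", deparse(x))
  invisible(x)
}

#' @export
print.lrc_query <- function(x, ...) {
  cat(sprintf("<query %s> %s %s:%s-%s\n", x$query_id, x$kind, x$locus$chrom,
              format(x$locus$start + 1, big.mark = ","), format(x$locus$end, big.mark = ",")))
  invisible(x)
}

#' Read variant queries from VCF (+ optional sidecar TSV)
#'
#' The VCF carries small sequence changes (nuclear and mitochondrial, routed
#' by contig name) and SVs (INFO keys `SVTYPE` in DEL/DUP/INS/INV, `END`,
#' `SVLEN`).  The sidecar TSV carries the kinds VCF does not express well,
#' with columns `query_id, kind, chrom, start_1based, end_1based, motif,
#' pathogenic_threshold, expected_copy, expected_length, parental_vcf`.
#' Parsing is total: every input row becomes either a query or a rejected row
#' with a reason (attribute `"rejected"` on the result).
#'
#' @param vcf_path VCF 4.x file (may be NULL if only a sidecar is given)
#' @param sidecar_path optional sidecar TSV
#' @return list of `lrc_query` (class `lrc_queries`), with attribute
#'   `rejected`: data.frame(source, row, reason)
#' @export
read_queries <- function(vcf_path = NULL, sidecar_path = NULL) {
  queries <- list()
  rejected <- data.frame(source = character(0), row = integer(0),
                         reason = character(0), stringsAsFactors = FALSE)
  reject <- function(src, i, why) {
    rejected[nrow(rejected) + 1L, ] <<- list(src, i, why)
  }
  if (!is.null(vcf_path)) {
    v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    if (nrow(fix)) {
      svtype <- vcfR::extract.info(v, "SVTYPE")
      svend <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
      svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
      for (i in seq_len(nrow(fix))) {
        pos1 <- suppressWarnings(as.numeric(fix$POS[i]))
        id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else
          sprintf("%s_%s", fix$CHROM[i], fix$POS[i])
        q <- tryCatch({
          if (!is.na(svtype[i]) && nzchar(svtype[i])) {
            type <- svtype[i]
            if (!type %in% c("DEL", "DUP", "INS", "INV")) stop("unknown SVTYPE: ", type)
            end0 <- if (!is.na(svend[i])) svend[i] else if (!is.na(svlen[i]))
              pos1 - 1 + abs(svlen[i]) else stop("SV row lacks END and SVLEN")
            query_sv(id, type, fix$CHROM[i], pos1 - 1, end0,
                     expected_length = if (type == "INS") abs(svlen[i]) else NULL)
          } else {
            if (nchar(fix$REF[i]) >= 50 || nchar(fix$ALT[i]) >= 50)
              stop("allele >= 50 bp: not a small sequence change")
            query_ssc(id, fix$CHROM[i], pos1 - 1, fix$REF[i], fix$ALT[i])
          }
        }, error = function(e) conditionMessage(e))
        if (is.character(q)) reject("vcf", i, q) else queries[[length(queries) + 1L]] <- q
      }
    }
  }
  if (!is.null(sidecar_path)) {
    sc <- read.delim(sidecar_path, stringsAsFactors = FALSE,
                     colClasses = "character", comment.char = "#")
    for (i in seq_len(nrow(sc))) {
      q <- tryCatch({
        kind <- toupper(sc$kind[i])
        s0 <- as.numeric(sc$start_1based[i]) - 1
        e0 <- as.numeric(sc$end_1based[i])
        id <- sc$query_id[i]
        num <- function(col) suppressWarnings(as.numeric(sc[[col]][i]))
        switch(kind,
          STR = {
            if (is.na(sc$motif[i]) || !nzchar(sc$motif[i])) stop("STR row missing motif")
            thr <- num("pathogenic_threshold")
            if (is.na(thr)) stop("STR row missing pathogenic_threshold")
            query_str(id, sc$chrom[i], s0, e0, sc$motif[i], thr)
          },
          CNV = query_cnv(id, sc$chrom[i], s0, e0, num("expected_copy")),
          ANEUPLOIDY = query_aneuploidy(id, strsplit(sc$chrom[i], ",")[[1]],
                                        num("expected_copy")),
          UPD = query_upd(id, sc$chrom[i], s0, e0,
                          parental_vcf = if (!is.null(sc$parental_vcf) &&
                                             nzchar(sc$parental_vcf[i])) sc$parental_vcf[i] else NULL),
          stop("unknown kind: ", kind))
      }, error = function(e) conditionMessage(e))
      if (is.character(q)) reject("sidecar", i, q) else queries[[length(queries) + 1L]] <- q
    }
  }
  structure(queries, class = "lrc_queries", rejected = rejected)
}

#' @export
print.lrc_queries <- function(x, ...) {
  cat(sprintf("<queries> %d accepted, %d rejected\n",
              length(x), nrow(attr(x, "rejected"))))
  invisible(x)
}
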