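#' Genomic interval (0-based, half-open)
#'
#' Internal coordinates throughout the package are 0-based half-open
#' (the arithmetic convention); user-facing text and the query formats are
#' 1-based inclusive (the VCF convention).  `gi()` builds the internal form,
#' `gi_from_1based()` / `gi_to_1based()` convert.
#'
#' @param chrom chromosome name (nonempty string)
#' @param start 0-based inclusive start (>= 0)
#' @param end 0-based exclusive end (>= start)
#' @return an object of class `lrc_gi`
#' @export
#' @examples
#' gi("chr1", 99, 100)            # the 100th base
#' gi_from_1based("chr1", 100, 100)
gi <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end < start)
    stop("invalid interval: need 0 <= start <= end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end), class = "lrc_gi")
}

#' @rdname gi
#' @param start1,end1 1-based inclusive coordinates
#' @export
gi_from_1based <- function(chrom, start1, end1 = start1) gi(chrom, start1 - 1, end1)

#' @rdname gi
#' @param x an `lrc_gi`
#' @export
gi_to_1based <- function(x) {
  stopifnot(inherits(x, "lrc_gi"))
  list(chrom = x$chrom, start1 = x$start + 1, end1 = x$end)
}

#' @export
print.lrc_gi <- function(x, ...) {
  cat(sprintf("<interval> %s:%s-%s (1-based %s..%s)\n",
              x$chrom, format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$start + 1, big.mark = ","), format(x$end, big.mark = ",")))
  invisible(x)
}

gi_width <- function(x) x$end - x$start

# is a contig name mitochondrial / an autosome (by conventional naming)
is_mito_chrom <- function(chrom) grepl("^(chr)?M(T)?$", chrom, ignore.case = TRUE)
is_autosome <- function(chrom) !grepl("^(chr)?(X|Y|M|MT|W|Z)$", chrom, ignore.case = TRUE)
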