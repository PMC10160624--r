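#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles, with the closed forms at the
#' boundaries: for 0 successes the lower bound is 0 and the upper bound
#' 1 - (alpha/2)^(1/n); for n successes the lower bound is (alpha/2)^(1/n)
#' and the upper bound 1.  The exact interval is conservative: empirical
#' coverage is at least the nominal level.
#'
#' @param successes number of successes (0..trials)
#' @param trials number of trials (>= 1)
#' @param confidence confidence level in (0, 1); default 0.95
#' @return numeric c(low, high)
#' @export
#' @examples
#' clopper_pearson(168, 168)   # lower bound (0.025)^(1/168) = 0.9783
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) stop("need 0 <= successes <= trials")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  alpha <- 1 - confidence
  low <- if (successes == 0) 0 else if (successes == trials)
    (alpha / 2)^(1 / trials) else qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else if (successes == 0)
    1 - (alpha / 2)^(1 / trials) else qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts
#' @return list of class `lrc_confusion`
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "lrc_confusion")
}

#' Validation metrics with exact binomial intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and
#' accuracy (tp+tn)/total, each with the exact Clopper-Pearson interval on
#' its own (successes, trials) pair; PPV is reported as a point estimate
#' only.  A metric whose denominator is zero is omitted with a reason.
#'
#' @param counts a [confusion_counts()]
#' @param confidence level for the intervals; default 0.95
#' @return list of class `lrc_metrics`; each present metric is a list
#'   (point, ci_low, ci_high) -- PPV has no interval
#' @export
#' @examples
#' m <- metrics(confusion_counts(164, 0, 1, 168))
#' round(m$sensitivity$point, 5)   # 0.99394
metrics <- function(counts, confidence = 0.95) {
  stopifnot(inherits(counts, "lrc_confusion"))
  out <- list(counts = counts, confidence = confidence, omitted = character(0))
  one <- function(s, n, with_ci = TRUE) {
    if (n < 1) return(NULL)
    m <- list(point = s / n)
    if (with_ci) {
      ci <- clopper_pearson(s, n, confidence)
      m$ci_low <- unname(ci[1]); m$ci_high <- unname(ci[2])
    }
    m
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  out$sensitivity <- one(tp, tp + fn)
  out$specificity <- one(tn, tn + fp)
  out$ppv <- one(tp, tp + fp, with_ci = FALSE)
  out$accuracy <- one(tp + tn, tp + fp + fn + tn)
  for (m in c("sensitivity", "specificity", "ppv", "accuracy"))
    if (is.null(out[[m]]))
      out$omitted <- c(out$omitted, paste0(m, ": zero denominator"))
  structure(out, class = "lrc_metrics")
}

#' @export
print.lrc_metrics <- function(x, ...) {
  cat(sprintf("<validation metrics> TP=%d FP=%d FN=%d TN=%d\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  lbl <- c(sensitivity = "Sensitivity", specificity = "Specificity",
           ppv = "PPV", accuracy = "Accuracy")
  for (m in names(lbl)) {
    v <- x[[m]]
    if (is.null(v)) next
    if (!is.null(v$ci_low))
      cat(sprintf("  %-12s %.5f (%.0f%% CI = %.4f-%.4f)\n", lbl[m], v$point,
                  100 * x$confidence, v$ci_low, v$ci_high))
    else cat(sprintf("  %-12s %.5f\n", lbl[m], v$point))
  }
  if (length(x$omitted)) cat("  omitted:", paste(x$omitted, collapse = "; "), "\n")
  invisible(x)
}

#' Genome-spread truth-set variant selection
#'
#' Partitions the genome (contigs laid end to end) into `n_buckets` equal
#' spans and takes the first `per_bucket` available variants from each
#' bucket, so the selected set is spread genome-wide.  A chromosome that has
#' truth variants but ends up unrepresented is topped up with its first
#' available variants; chromosomes with no truth variants at all are flagged
#' in the `underrepresented` attribute.
#'
#' @param truth_variants data.frame with columns chrom, pos, sorted by
#'   genome coordinate
#' @param genome_lengths named vector of contig lengths
#' @param n_buckets number of equal genome spans
#' @param per_bucket variants taken per bucket (default 1)
#' @param seed accepted for interface stability; selection is deterministic
#' @return data.frame of selected variants with a `bucket` column
#' @export
bucket_select <- function(truth_variants, genome_lengths, n_buckets,
                          per_bucket = 1, seed = NULL) {
  if (!nrow(truth_variants)) stop("empty truth set")
  stopifnot(all(truth_variants$chrom %in% names(genome_lengths)))
  offs <- c(0, cumsum(as.numeric(genome_lengths)))[seq_along(genome_lengths)]
  names(offs) <- names(genome_lengths)
  gpos <- offs[truth_variants$chrom] + truth_variants$pos
  total <- sum(as.numeric(genome_lengths))
  bucket <- pmin(floor(gpos / (total / n_buckets)), n_buckets - 1) + 1
  ord <- order(gpos)
  sel <- integer(0)
  for (b in seq_len(n_buckets)) {
    rows <- ord[bucket[ord] == b]
    sel <- c(sel, head(rows, per_bucket))
  }
  selected_chroms <- unique(truth_variants$chrom[sel])
  for (chrom in names(genome_lengths)) {
    has <- which(truth_variants$chrom == chrom)
    if (length(has) && !chrom %in% selected_chroms)
      sel <- union(sel, head(has[order(truth_variants$pos[has])], per_bucket))
  }
  out <- truth_variants[sort(sel), , drop = FALSE]
  out$bucket <- bucket[sort(sel)]
  rownames(out) <- NULL
  empty <- names(genome_lengths)[!names(genome_lengths) %in% truth_variants$chrom]
  attr(out, "underrepresented") <- empty
  out
}
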