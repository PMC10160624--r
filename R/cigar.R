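# CIGAR helpers.  Tokenizing goes through GenomicAlignments; the per-read
# walks (window extraction, insertion/deletion harvesting) are implemented
# here because the evidence they extract is the point of the package.

cigar_ops <- function(cigar) {
  data.frame(op = GenomicAlignments::explodeCigarOps(cigar)[[1]],
             len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]],
             stringsAsFactors = FALSE)
}

QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

cigar_query_len <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% QUERY_OPS])
}

cigar_ref_len <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% REF_OPS])
}

# leading / trailing clip lengths (soft or hard)
cigar_clips <- function(cigar) {
  co <- cigar_ops(cigar)
  left <- 0L; right <- 0L
  i <- 1L
  while (i <= nrow(co) && co$op[i] %in% c("S", "H")) { left <- left + co$len[i]; i <- i + 1L }
  j <- nrow(co)
  while (j >= i && co$op[j] %in% c("S", "H")) { right <- right + co$len[j]; j <- j - 1L }
  c(left = left, right = right)
}

# The read bases aligned to reference window [ws, we), including insertions
# anchored strictly inside the window.  `start` is the record's 0-based
# reference start.  Returns NA_character_ if the aligned span does not fully
# cover the window.
aligned_window_seq <- function(start, cigar, seq, ws, we) {
  co <- cigar_ops(cigar)
  rend <- start + sum(co$len[co$op %in% REF_OPS])
  if (start > ws || rend < we) return(NA_character_)
  r <- start; q <- 0L
  out <- character(0)
  for (k in seq_len(nrow(co))) {
    op <- co$op[k]; len <- co$len[k]
    if (op %in% c("M", "=", "X")) {
      a <- max(r, ws); b <- min(r + len, we)
      if (b > a) out <- c(out, substr(seq, q + (a - r) + 1, q + (b - r)))
      r <- r + len; q <- q + len
    } else if (op == "I") {
      if (r > ws && r <= we) out <- c(out, substr(seq, q + 1, q + len))
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    } # H consumes nothing
    if (r >= we && op != "I") {
      # one more insertion may still be anchored at we; peek ahead
      if (k < nrow(co) && co$op[k + 1] == "I" && r <= we) next
      break
    }
  }
  paste(out, collapse = "")
}

# All insertion operations (length >= min_len) in one record whose reference
# anchor position lies in [istart, iend]; returns data.frame.
record_insertions <- function(start, cigar, seq, istart, iend, min_len) {
  co <- cigar_ops(cigar)
  r <- start; q <- 0L
  pos <- integer(0); len_out <- integer(0); ins_seq <- character(0)
  for (k in seq_len(nrow(co))) {
    op <- co$op[k]; len <- co$len[k]
    if (op %in% c("M", "=", "X")) { r <- r + len; q <- q + len }
    else if (op == "I") {
      if (len >= min_len && r >= istart && r <= iend) {
        pos <- c(pos, r); len_out <- c(len_out, len)
        ins_seq <- c(ins_seq, substr(seq, q + 1, q + len))
      }
      q <- q + len
    } else if (op %in% c("D", "N")) r <- r + len
    else if (op == "S") q <- q + len
  }
  data.frame(position = pos, length = len_out, inserted_sequence = ins_seq,
             stringsAsFactors = FALSE)
}

# Deletion operations (length >= min_len) overlapping [istart, iend).
record_deletions <- function(start, cigar, istart, iend, min_len) {
  co <- cigar_ops(cigar)
  r <- start
  pos <- integer(0); len_out <- integer(0)
  for (k in seq_len(nrow(co))) {
    op <- co$op[k]; len <- co$len[k]
    if (op %in% c("M", "=", "X")) r <- r + len
    else if (op %in% c("D", "N")) {
      if (len >= min_len && r < iend && r + len > istart) {
        pos <- c(pos, r); len_out <- c(len_out, len)
      }
      r <- r + len
    }
  }
  data.frame(position = pos, length = len_out, stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  # plain A/C/G/T strings only (the package's internal sequences);
  # complement via chartr, reverse at the byte level
  vapply(chartr("ACGTacgt", "TGCAtgca", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}
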