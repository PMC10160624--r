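#' Simulation configuration
#'
#' Defaults emulate a low-pass long-read genome run: ~10 kb reads (log-normal
#' length, truncated at `min_read_length`), 12x genomic depth with >= 1000x on
#' mitochondrial contigs, and an indel-rich nanopore-style error profile whose
#' default rates total ~2.5 per 100 bases (mean read accuracy around Q16),
#' with indels elevated in homopolymer context.
#'
#' @param seed RNG seed; identical configurations reproduce byte-identical output
#' @param read_length_mean mean read length in bp (default 10000)
#' @param read_length_sdlog log-scale SD of the read-length distribution
#' @param min_read_length truncation floor in bp (default 500)
#' @param depth target total depth over a diploid locus (default 12)
#' @param mito_depth target total depth on mitochondrial contigs (default 1000)
#' @param error_sub,error_ins,error_del per-base error rates (each in [0, 0.2])
#' @param homopolymer_indel_multiplier indel rate multiplier after an
#'   identical base (default 2)
#' @param max_del_cigar deletions up to this size stay inside one alignment
#'   as D operations; larger ones split the read (default 1000)
#' @param max_ins_cigar insertions up to this size become I operations;
#'   larger ones are soft-clipped (default 3000)
#' @param mapq mapping quality assigned to emitted records
#' @return list of class `lrc_simconfig`
#' @export
sim_config <- function(seed = 1L, read_length_mean = 10000, read_length_sdlog = 0.35,
                       min_read_length = 500, depth = 12, mito_depth = 1000,
                       error_sub = 0.010, error_ins = 0.006, error_del = 0.009,
                       homopolymer_indel_multiplier = 2,
                       max_del_cigar = 1000, max_ins_cigar = 3000, mapq = 60L) {
  rates <- c(error_sub, error_ins, error_del)
  if (any(rates < 0) || any(rates > 0.2)) stop("error rates must be in [0, 0.2]")
  if (depth <= 0 || mito_depth <= 0) stop("depth must be > 0")
  structure(list(seed = as.integer(seed), read_length_mean = read_length_mean,
                 read_length_sdlog = read_length_sdlog,
                 min_read_length = min_read_length, depth = depth,
                 mito_depth = mito_depth, error_sub = error_sub,
                 error_ins = error_ins, error_del = error_del,
                 homopolymer_indel_multiplier = homopolymer_indel_multiplier,
                 max_del_cigar = max_del_cigar, max_ins_cigar = max_ins_cigar,
                 mapq = as.integer(mapq)),
            class = "lrc_simconfig")
}

#' Make a random reference genome with optional planted STR loci
#'
#' @param n_chroms number of contigs
#' @param chrom_length length of each contig (bp); must comfortably exceed
#'   the read length (>= 10x is sensible)
#' @param seed RNG seed
#' @param str_loci optional data.frame(chrom, pos, motif, ref_count): a pure
#'   repeat tract of `ref_count` motif units is written at `pos` (0-based)
#' @param gc GC content of the random background
#' @param chrom_names optional contig names (default chr1..chrN)
#' @return list of class `lrc_genome`: `seq` (named character),
#'   `str_loci` (data.frame with 0-based start/end of each tract)
#' @export
make_genome <- function(n_chroms = 1, chrom_length = 1e5, seed = 1L,
                        str_loci = NULL, gc = 0.42, chrom_names = NULL) {
  if (chrom_length < 5000) stop("chrom_length too small to carry reads")
  set.seed(seed)
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chroms))
  stopifnot(length(chrom_names) == n_chroms)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i)
    paste(sample(names(p), chrom_length, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(seqs) <- chrom_names
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                       motif = character(0), ref_count = integer(0),
                       stringsAsFactors = FALSE)
  if (!is.null(str_loci)) {
    for (i in seq_len(nrow(str_loci))) {
      chrom <- str_loci$chrom[i]; pos <- str_loci$pos[i]
      tract <- strrep(str_loci$motif[i], str_loci$ref_count[i])
      if (pos < 0 || pos + nchar(tract) > chrom_length)
        stop("STR locus outside contig: row ", i)
      substr(seqs[[chrom]], pos + 1, pos + nchar(tract)) <- tract
      placed[nrow(placed) + 1L, ] <- list(chrom, pos, pos + nchar(tract),
                                          toupper(str_loci$motif[i]),
                                          as.integer(str_loci$ref_count[i]))
    }
  }
  structure(list(seq = seqs, str_loci = placed), class = "lrc_genome")
}

#' Variant specifications for the simulator
#'
#' Each helper describes one variant to spike into a haplotype copy:
#' `hap` selects the copy (1-based; 0 = all copies of the chromosome).
#' Coordinates are 0-based half-open reference positions.
#'
#' @param chrom contig
#' @param pos,start,end positions
#' @param alt alternate base (SNV)
#' @param hap haplotype copy index (0 = homozygous/all copies)
#' @return a variant spec list
#' @export
var_snv <- function(chrom, pos, alt, hap = 1)
  list(kind = "snv", chrom = chrom, start = pos, end = pos + 1, alt = toupper(alt), hap = hap)

#' @rdname var_snv
#' @export
var_del <- function(chrom, start, end, hap = 1)
  list(kind = "del", chrom = chrom, start = start, end = end, hap = hap)

#' @rdname var_snv
#' @param seq inserted sequence
#' @export
var_ins <- function(chrom, pos, seq, hap = 1)
  list(kind = "ins", chrom = chrom, start = pos, end = pos, seq = toupper(seq), hap = hap)

#' @rdname var_snv
#' @export
var_dup <- function(chrom, start, end, hap = 1)
  list(kind = "dup", chrom = chrom, start = start, end = end, hap = hap)

#' @rdname var_snv
#' @export
var_inv <- function(chrom, start, end, hap = 1)
  list(kind = "inv", chrom = chrom, start = start, end = end, hap = hap)

#' @rdname var_snv
#' @param motif repeat unit
#' @param ref_count repeat units present in the reference tract
#' @param total_units target total tract length in units (motif plus
#'   interrupting units); expansion beyond `ref_count` is inserted at the
#'   tract end, a shorter allele truncates the tract
#' @param interruptions optional data.frame(offset_units, unit): non-motif
#'   units at the given offsets (in units, from tract start) within the
#'   expanded portion
#' @param mosaic_jitter somatic length variability: per spanning read the
#'   expanded portion varies by up to +/- this many units
#' @export
var_str <- function(chrom, start, end, motif, ref_count, total_units, hap = 1,
                    interruptions = NULL, mosaic_jitter = 0) {
  list(kind = "str", chrom = chrom, start = start, end = end, motif = toupper(motif),
       ref_count = ref_count, total_units = total_units,
       interruptions = interruptions, mosaic_jitter = mosaic_jitter, hap = hap)
}

seg_ref <- function(s, e, strand = "+")
  list(type = "ref", src_start = s, src_end = e, strand = strand)
seg_ins <- function(seq, mosaic_motif = NULL, mosaic_jitter = 0)
  list(type = "ins", seq = seq, mosaic_motif = mosaic_motif,
       mosaic_jitter = mosaic_jitter)

split_segs <- function(segs, p) {
  out <- list()
  for (sg in segs) {
    if (sg$type == "ref" && sg$strand == "+" && sg$src_start < p && p < sg$src_end)
      out <- c(out, list(seg_ref(sg$src_start, p), seg_ref(p, sg$src_end)))
    else out <- c(out, list(sg))
  }
  out
}

# indices of the contiguous '+' ref run covering [s, e) (after splitting)
seg_run <- function(segs, s, e) {
  idx <- which(vapply(segs, function(sg)
    sg$type == "ref" && sg$strand == "+" && sg$src_start >= s && sg$src_end <= e,
    logical(1)))
  if (!length(idx) || any(diff(idx) != 1))
    stop("variant region [", s, ",", e, ") is not a contiguous reference run; ",
         "overlapping variant specs?")
  idx
}

apply_variant_to_copy <- function(copy, v) {
  segs <- copy$segments
  if (v$kind == "snv") {
    copy$snvs <- rbind(copy$snvs, data.frame(pos = v$start, alt = v$alt,
                                             stringsAsFactors = FALSE))
    return(copy)
  }
  if (v$kind == "del") {
    segs <- split_segs(split_segs(segs, v$start), v$end)
    segs <- segs[-seg_run(segs, v$start, v$end)]
  } else if (v$kind == "ins" || v$kind == "str") {
    at <- if (v$kind == "ins") v$start else v$end
    newseg <- if (v$kind == "ins") seg_ins(v$seq) else NULL
    if (v$kind == "str") {
      mlen <- nchar(v$motif)
      ref_count <- v$ref_count
      if (v$total_units < ref_count) {
        # contraction: truncate the reference tract
        from <- v$start + v$total_units * mlen
        segs <- split_segs(split_segs(segs, from), v$end)
        segs <- segs[-seg_run(segs, from, v$end)]
        copy$segments <- segs
        return(copy)
      }
      extra_off <- seq.int(ref_count, length.out = v$total_units - ref_count)
      units <- rep(v$motif, length(extra_off))
      if (!is.null(v$interruptions) && nrow(v$interruptions)) {
        hit <- match(v$interruptions$offset_units, extra_off)
        units[hit[!is.na(hit)]] <- v$interruptions$unit[!is.na(hit)]
      }
      if (!length(units)) return(copy)
      newseg <- seg_ins(paste(units, collapse = ""), mosaic_motif = v$motif,
                        mosaic_jitter = v$mosaic_jitter)
    }
    segs <- split_segs(segs, at)
    k <- Position(function(sg) sg$type == "ref" && sg$strand == "+" &&
                    sg$src_end == at, segs)
    if (is.na(k)) {
      k0 <- Position(function(sg) sg$type == "ref" && sg$src_start == at, segs)
      if (is.na(k0)) stop("insertion point ", at, " not on a reference segment")
      segs <- append(segs, list(newseg), after = k0 - 1)
    } else segs <- append(segs, list(newseg), after = k)
  } else if (v$kind == "dup") {
    segs <- split_segs(split_segs(segs, v$start), v$end)
    run <- seg_run(segs, v$start, v$end)
    segs <- append(segs, segs[run], after = max(run))
  } else if (v$kind == "inv") {
    segs <- split_segs(split_segs(segs, v$start), v$end)
    run <- seg_run(segs, v$start, v$end)
    segs <- c(segs[seq_len(min(run) - 1)], list(seg_ref(v$start, v$end, "-")),
              if (max(run) < length(segs)) segs[(max(run) + 1):length(segs)])
  } else stop("unknown variant kind: ", v$kind)
  copy$segments <- segs
  copy
}

#' Build haplotype copies from a genome and variant specs
#'
#' Applies the variant specifications to per-chromosome haplotype copies.
#' `copy_number` sets how many copies each chromosome has (default 2;
#' e.g. `c(chrX = 2, chrY = 2)` on top of diploid autosomes emulates an
#' XXYY karyotype, `c(chrY = 0)` a female).  Structural specs must not
#' overlap on a haplotype (an error lists the collision).
#'
#' @param genome from [make_genome()]
#' @param variants list of `var_*()` specs
#' @param copy_number named vector of per-chromosome copy counts
#' @param copy_depths optional named list: chrom -> numeric vector of target
#'   depths per copy (overrides the configuration's depth split; used e.g.
#'   for mitochondrial heteroplasmy mixtures)
#' @return list of class `lrc_haplotypes`
#' @export
build_haplotypes <- function(genome, variants = list(), copy_number = NULL,
                             copy_depths = NULL) {
  lens <- vapply(genome$seq, nchar, numeric(1))
  cn <- setNames(rep(2L, length(lens)), names(lens))
  if (!is.null(copy_number)) cn[names(copy_number)] <- copy_number
  copies <- list()
  for (chrom in names(lens)) {
    for (k in seq_len(cn[[chrom]])) {
      d <- if (!is.null(copy_depths) && chrom %in% names(copy_depths))
        copy_depths[[chrom]][k] else NA_real_
      copies[[paste0(chrom, ".", k)]] <- list(
        chrom = chrom, copy = k, depth = d,
        segments = list(seg_ref(0, lens[[chrom]])),
        snvs = data.frame(pos = numeric(0), alt = character(0),
                          stringsAsFactors = FALSE))
    }
  }
  # overlap check among structural specs per (chrom, copy)
  structural <- Filter(function(v) v$kind != "snv", variants)
  keyiv <- lapply(structural, function(v) {
    haps <- if (v$hap == 0) seq_len(cn[[v$chrom]]) else v$hap
    lapply(haps, function(h) list(key = paste0(v$chrom, ".", h),
                                  s = v$start, e = max(v$end, v$start + 1)))
  })
  flat <- do.call(c, keyiv)
  if (length(flat) > 1) {
    for (i in seq_along(flat)) for (j in seq_len(i - 1)) {
      a <- flat[[i]]; b <- flat[[j]]
      if (a$key == b$key && a$s < b$e && b$s < a$e)
        stop("overlapping variant specs on ", a$key, ": [", a$s, ",", a$e,
             ") vs [", b$s, ",", b$e, ")")
    }
  }
  ord <- order(vapply(variants, `[[`, numeric(1), "start"))
  for (v in variants[ord]) {
    if (!v$chrom %in% names(lens)) stop("variant on unknown contig ", v$chrom)
    targets <- if (v$hap == 0) seq_len(cn[[v$chrom]]) else v$hap
    for (h in targets) {
      key <- paste0(v$chrom, ".", h)
      if (is.null(copies[[key]])) stop("haplotype copy ", key, " does not exist")
      copies[[key]] <- apply_variant_to_copy(copies[[key]], v)
    }
  }
  structure(list(copies = copies, genome = genome, copy_number = cn,
                 variants = variants),
            class = "lrc_haplotypes")
}

seg_len_of <- function(sg) {
  if (sg$type == "ref") sg$src_end - sg$src_start else nchar(sg$seq)
}

extract_ref_piece <- function(chrom_seq, snvs, src0, src1, strand) {
  x <- substr(chrom_seq, src0 + 1, src1)
  if (nrow(snvs)) {
    hit <- which(snvs$pos >= src0 & snvs$pos < src1)
    for (i in hit) substr(x, snvs$pos[i] - src0 + 1, snvs$pos[i] - src0 + 1) <- snvs$alt[i]
  }
  if (strand == "-") x <- revcomp(x)
  x
}

# pieces of a read covering haplotype interval [s, e)
hap_pieces <- function(copy, seg_starts, seg_lens, chrom_seq, s, e) {
  pieces <- list(); q <- 0
  for (k in seq_along(copy$segments)) {
    a <- max(s, seg_starts[k]); b <- min(e, seg_starts[k] + seg_lens[k])
    if (b <= a) next
    sg <- copy$segments[[k]]
    off0 <- a - seg_starts[k]; off1 <- b - seg_starts[k]
    if (sg$type == "ref") {
      if (sg$strand == "+") { src0 <- sg$src_start + off0; src1 <- sg$src_start + off1 }
      else { src0 <- sg$src_end - off1; src1 <- sg$src_end - off0 }
      pseq <- extract_ref_piece(chrom_seq, copy$snvs, src0, src1, sg$strand)
      pieces[[length(pieces) + 1L]] <- list(type = "ref", src0 = src0, src1 = src1,
                                            strand = sg$strand, seq = pseq,
                                            q0 = q, q1 = q + (b - a))
      q <- q + (b - a)
    } else {
      pseq <- substr(sg$seq, off0 + 1, off1)
      if (!is.null(sg$mosaic_motif) && sg$mosaic_jitter > 0 &&
          off0 == 0 && off1 == seg_lens[k]) {
        mlen <- nchar(sg$mosaic_motif)
        jit <- sample(seq(-sg$mosaic_jitter, sg$mosaic_jitter), 1)
        if (jit > 0) pseq <- paste0(pseq, strrep(sg$mosaic_motif, jit))
        else if (jit < 0 && nchar(pseq) + jit * mlen > 0)
          pseq <- substr(pseq, 1, nchar(pseq) + jit * mlen)
      }
      pieces[[length(pieces) + 1L]] <- list(type = "ins", seq = pseq,
                                            q0 = q, q1 = q + nchar(pseq))
      q <- q + nchar(pseq)
    }
  }
  pieces
}

# group read pieces into aligner-like chains -> one alignment record each
pieces_to_chains <- function(pieces, config) {
  chains <- list(); cur <- NULL; pending_ins <- 0
  flush <- function() {
    if (!is.null(cur)) chains[[length(chains) + 1L]] <<- cur
    cur <<- NULL; pending_ins <<- 0
  }
  for (p in pieces) {
    if (p$type == "ins") {
      if (is.null(cur)) next
      pending_ins <- pending_ins + (p$q1 - p$q0)
      if (pending_ins > config$max_ins_cigar) flush()
      next
    }
    plen <- p$src1 - p$src0
    if (is.null(cur)) {
      cur <- list(strand = p$strand, rs = p$src0, re = p$src1,
                  ops = "M", lens = plen, q0 = p$q0, q1 = p$q1, mlen = plen)
      pending_ins <- 0
      next
    }
    gap <- if (cur$strand == "+") p$src0 - cur$re else cur$rs - p$src1
    if (p$strand == cur$strand && gap >= 0 && gap <= config$max_del_cigar) {
      if (pending_ins > 0) { cur$ops <- c(cur$ops, "I"); cur$lens <- c(cur$lens, pending_ins) }
      if (gap > 0) { cur$ops <- c(cur$ops, "D"); cur$lens <- c(cur$lens, gap) }
      cur$ops <- c(cur$ops, "M"); cur$lens <- c(cur$lens, plen)
      cur$mlen <- cur$mlen + plen
      if (cur$strand == "+") cur$re <- p$src1 else cur$rs <- p$src0
      cur$q1 <- p$q1
      pending_ins <- 0
    } else {
      flush()
      cur <- list(strand = p$strand, rs = p$src0, re = p$src1,
                  ops = "M", lens = plen, q0 = p$q0, q1 = p$q1, mlen = plen)
    }
  }
  flush()
  chains
}

merge_ops <- function(ops, lens) {
  keep <- lens > 0
  ops <- ops[keep]; lens <- lens[keep]
  if (!length(ops)) return(list(ops = ops, lens = lens))
  r <- rle(ops)
  if (all(r$lengths == 1)) return(list(ops = ops, lens = lens))
  out_ops <- r$values
  out_lens <- vapply(seq_along(r$values), function(i) {
    j0 <- sum(r$lengths[seq_len(i - 1)]) + 1
    sum(lens[j0:(j0 + r$lengths[i] - 1)])
  }, numeric(1))
  list(ops = out_ops, lens = out_lens)
}

chain_to_record <- function(chain, read_seq, read_len, chrom, read_id, role, config) {
  if (chain$strand == "+") {
    lead <- chain$q0; trail <- read_len - chain$q1
    ops <- chain$ops; lens <- chain$lens
    seq_out <- read_seq
  } else {
    lead <- read_len - chain$q1; trail <- chain$q0
    ops <- rev(chain$ops); lens <- rev(chain$lens)
    seq_out <- revcomp(read_seq)
  }
  ops <- c(if (lead > 0) "S", ops, if (trail > 0) "S")
  lens <- c(if (lead > 0) lead, lens, if (trail > 0) trail)
  m <- merge_ops(ops, lens)
  list(read_id = read_id, chrom = chrom, start = chain$rs, end = chain$re,
       strand = chain$strand, ops = m$ops, lens = m$lens, seq = seq_out,
       role = role)
}

BASES <- c("A", "C", "G", "T")

mutate_bases <- function(b) {
  i <- match(b, BASES)
  BASES[((i - 1L + sample(3L, length(b), replace = TRUE)) %% 4L) + 1L]
}

# nanopore-style error injection into one record; returns modified
# (ops, lens, seq, start, n_err).  Works on raw bytes / integer op codes for
# speed: codes S=1, M=2, I=3 consume the query, D=5 the reference only.
OP_CODES <- c(S = 1L, M = 2L, I = 3L, H = 4L, D = 5L)
OP_NAMES <- names(OP_CODES)
BASES_RAW <- charToRaw("ACGT")

inject_record_errors <- function(ops, lens, seq, start, config) {
  if (config$error_sub + config$error_ins + config$error_del == 0)
    return(list(ops = ops, lens = lens, seq = seq, start = start, n_err = 0L))
  full <- rep(OP_CODES[ops], lens)
  qcons <- full <= 3L
  bases <- charToRaw(seq)
  b <- raw(length(full)); b[qcons] <- bases
  n_err <- 0L
  # draw per-class error counts, then positions (equivalent to independent
  # per-base Bernoulli draws, far cheaper)
  pick <- function(idx, p) {
    if (!length(idx) || p <= 0) return(integer(0))
    n <- rbinom(1, length(idx), min(p, 1))
    if (n == 0) integer(0) else idx[sample.int(length(idx), n)]
  }
  qidx <- which(qcons)
  sub_hit <- pick(qidx, config$error_sub)
  if (length(sub_hit)) {
    i <- match(b[sub_hit], BASES_RAW)
    b[sub_hit] <- BASES_RAW[((i - 1L + sample(3L, length(i), replace = TRUE)) %% 4L) + 1L]
    n_err <- n_err + length(sub_hit)
  }
  mloc <- which(full == 2L)
  if (length(mloc) > 2) {
    # homopolymer context: previous query base identical
    hp <- mloc > 1L & b[mloc] == b[pmax(mloc - 1L, 1L)] & b[pmax(mloc - 1L, 1L)] != as.raw(0)
    m <- config$homopolymer_indel_multiplier
    del_hit <- c(pick(mloc[hp], config$error_del * m), pick(mloc[!hp], config$error_del))
    ins_hit <- c(pick(mloc[hp], config$error_ins * m), pick(mloc[!hp], config$error_ins))
    ins_hit <- setdiff(ins_hit, del_hit)
    if (length(del_hit) < length(mloc)) {
      full[del_hit] <- 5L; b[del_hit] <- as.raw(0)
      n_err <- n_err + length(del_hit)
      if (length(ins_hit)) {
        ins_hit <- sort(ins_hit)
        k <- length(ins_hit); n0 <- length(full)
        # position of old element i in the widened vector, then fill gaps
        new_at <- seq_len(n0) + findInterval(seq_len(n0) - 1L, ins_hit)
        full2 <- integer(n0 + k); b2 <- raw(n0 + k)
        full2[new_at] <- full; b2[new_at] <- b
        gap <- setdiff(seq_len(n0 + k), new_at)
        full2[gap] <- 3L
        b2[gap] <- BASES_RAW[sample(4L, k, replace = TRUE)]
        full <- full2; b <- b2
        n_err <- n_err + k
      }
    }
  }
  r <- rle(full)  # full is per-base, so run lengths are op lengths
  # canonicalize the alignment ends: no D/I at the aligned boundary
  fix <- canonicalize_cigar(OP_NAMES[r$values], r$lengths, start)
  seq2 <- rawToChar(b[b != as.raw(0)])
  list(ops = fix$ops, lens = fix$lens, seq = seq2, start = fix$start, n_err = n_err)
}

canonicalize_cigar <- function(ops, lens, start) {
  repeat {
    n <- length(ops)
    first <- which(!ops %in% c("S", "H"))[1]
    if (is.na(first)) break
    if (ops[first] == "D") { start <- start + lens[first]; ops <- ops[-first]; lens <- lens[-first] }
    else if (ops[first] == "I") {
      if (first > 1 && ops[first - 1] == "S") { lens[first - 1] <- lens[first - 1] + lens[first]; ops <- ops[-first]; lens <- lens[-first] }
      else { ops[first] <- "S" }
    } else break
  }
  repeat {
    nonclip <- which(!ops %in% c("S", "H"))
    if (!length(nonclip)) break
    last <- nonclip[length(nonclip)]
    if (ops[last] == "D") { ops <- ops[-last]; lens <- lens[-last] }
    else if (ops[last] == "I") {
      if (last < length(ops) && ops[last + 1] == "S") { lens[last + 1] <- lens[last + 1] + lens[last]; ops <- ops[-last]; lens <- lens[-last] }
      else ops[last] <- "S"
    } else break
  }
  m <- merge_ops(ops, lens)
  list(ops = m$ops, lens = m$lens, start = start)
}

#' Simulate aligned long reads from haplotype copies
#'
#' Draws reads per haplotype copy to hit the target depth (each copy of a
#' diploid chromosome at half the configured depth; mitochondrial contigs at
#' the mitochondrial floor), assembles each read from its haplotype
#' segments, and emits alignment records with correct coordinates, CIGAR
#' operations and soft clips -- reads crossing a structural-variant junction
#' are split into primary + supplementary segments exactly as an aligner
#' would place them, with opposite-strand segments at inversion junctions.
#' Error injection then adds substitutions and (homopolymer-elevated)
#' 1 bp indels at the configured rates.  Deterministic per seed.
#'
#' @param haps from [build_haplotypes()]
#' @param config a [sim_config()]
#' @return list of class `lrc_sim`: `alignments` (an `lrc_alignments`
#'   frame), `truth` (reads + variants), `genome`, `ref_lengths`
#' @export
simulate_alignments <- function(haps, config = sim_config()) {
  set.seed(config$seed)
  genome <- haps$genome
  lens <- vapply(genome$seq, nchar, numeric(1))
  meanlog <- log(config$read_length_mean) - config$read_length_sdlog^2 / 2
  recs <- list(); truth_reads <- list()
  for (key in names(haps$copies)) {
    copy <- haps$copies[[key]]
    chrom_seq <- genome$seq[[copy$chrom]]
    seg_lens <- vapply(copy$segments, seg_len_of, numeric(1))
    seg_starts <- cumsum(c(0, seg_lens))[seq_along(seg_lens)]
    L <- sum(seg_lens)
    if (L == 0) next
    dcopy <- if (!is.na(copy$depth)) copy$depth
    else if (is_mito_chrom(copy$chrom)) config$mito_depth / haps$copy_number[[copy$chrom]]
    else config$depth / 2
    if (dcopy <= 0) next
    n <- rpois(1, dcopy * (L + config$read_length_mean - 1) / config$read_length_mean)
    if (n == 0) next
    rlen <- pmax(config$min_read_length, round(rlnorm(n, meanlog, config$read_length_sdlog)))
    st <- floor(runif(n, -rlen + 1, L))
    for (i in seq_len(n)) {
      s <- max(0, st[i]); e <- min(st[i] + rlen[i], L)
      if (e - s < 100) next
      read_id <- sprintf("%s_r%05d", key, i)
      pieces <- hap_pieces(copy, seg_starts, seg_lens, chrom_seq, s, e)
      read_seq <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")
      read_len <- nchar(read_seq)
      chains <- pieces_to_chains(pieces, config)
      chains <- Filter(function(ch) ch$mlen >= 50, chains)
      if (!length(chains)) next
      primary <- which.max(vapply(chains, `[[`, numeric(1), "mlen"))
      mq <- round(max(9.5, rnorm(1, 16, 2)), 1)
      nrec_for_read <- 0L
      for (ci in seq_along(chains)) {
        rec <- chain_to_record(chains[[ci]], read_seq, read_len, copy$chrom, read_id,
                               if (ci == primary) "primary" else "supplementary", config)
        er <- inject_record_errors(rec$ops, rec$lens, rec$seq, rec$start, config)
        cigar <- paste0(er$lens, er$ops, collapse = "")
        end <- er$start + sum(er$lens[er$ops %in% c("M", "D")])
        recs[[length(recs) + 1L]] <- list(
          read_id = read_id, chrom = rec$chrom, start = er$start, end = end,
          strand = rec$strand, cigar = cigar, mapq = config$mapq,
          role = rec$role, seq = er$seq, mean_quality = mq)
        nrec_for_read <- nrec_for_read + 1L
      }
      truth_reads[[length(truth_reads) + 1L]] <- list(
        read_id = read_id, chrom = copy$chrom, copy = copy$copy,
        hap_start = s, hap_end = e, n_records = nrec_for_read)
    }
  }
  aln <- if (length(recs)) alignment_frame(data.frame(
    read_id = vapply(recs, `[[`, character(1), "read_id"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    cigar = vapply(recs, `[[`, character(1), "cigar"),
    mapq = vapply(recs, `[[`, integer(1), "mapq"),
    role = vapply(recs, `[[`, character(1), "role"),
    seq = vapply(recs, `[[`, character(1), "seq"),
    mean_quality = vapply(recs, `[[`, numeric(1), "mean_quality"),
    stringsAsFactors = FALSE)) else empty_alignment_frame()
  truth <- list(
    reads = if (length(truth_reads)) data.frame(
      read_id = vapply(truth_reads, `[[`, character(1), "read_id"),
      chrom = vapply(truth_reads, `[[`, character(1), "chrom"),
      copy = vapply(truth_reads, `[[`, numeric(1), "copy"),
      hap_start = vapply(truth_reads, `[[`, numeric(1), "hap_start"),
      hap_end = vapply(truth_reads, `[[`, numeric(1), "hap_end"),
      n_records = vapply(truth_reads, `[[`, integer(1), "n_records"),
      stringsAsFactors = FALSE) else NULL,
    variants = haps$variants)
  structure(list(alignments = aln, truth = truth, genome = genome,
                 ref_lengths = lens),
            class = "lrc_sim")
}

#' @export
print.lrc_sim <- function(x, ...) {
  cat(sprintf("<simulation> %d records from %d reads over %d contig(s)\n",
              nrow(x$alignments),
              if (is.null(x$truth$reads)) 0L else nrow(x$truth$reads),
              length(x$ref_lengths)))
  invisible(x)
}

#' Simulate a trio for UPD scenarios
#'
#' Generates father/mother genotypes over a chromosome, including loci
#' informative for uniparental disomy (father homozygous-alternate, mother
#' homozygous-reference when `source = "mother"`), and the proband's variant
#' specs under the chosen inheritance: `biparental` (one haplotype carries
#' the father's alleles -- every informative locus is heterozygous),
#' `isodisomy` (two copies of one maternal homolog: informative loci read
#' reference) or `heterodisomy` (both maternal homologs: maternal
#' heterozygous positions segregate, informative loci still read reference).
#'
#' @param genome from [make_genome()]
#' @param chrom chromosome carrying the (whole-chromosome) UPD region
#' @param n_informative number of informative loci to place
#' @param n_maternal_het maternal heterozygous loci (visible under
#'   heterodisomy)
#' @param inheritance "biparental", "isodisomy" or "heterodisomy"
#' @param seed RNG seed (independent of the read-simulation seed)
#' @return list: `parental` (data.frame for [select_informative_loci()]),
#'   `proband_variants` (specs for [build_haplotypes()]), `inheritance`
#' @export
sim_trio <- function(genome, chrom, n_informative = 60, n_maternal_het = 40,
                     inheritance = c("biparental", "isodisomy", "heterodisomy"),
                     seed = 1L) {
  inheritance <- match.arg(inheritance)
  set.seed(seed)
  L <- nchar(genome$seq[[chrom]])
  n_tot <- n_informative + n_maternal_het
  pos <- sort(sample(seq(100, L - 100), n_tot))
  info <- sort(sample(seq_len(n_tot), n_informative))
  refb <- substring(genome$seq[[chrom]], pos + 1, pos + 1)
  altb <- mutate_bases(refb)
  parental <- data.frame(chrom = chrom, pos = pos, ref = refb, alt = altb,
                         father_gt = "ref_hom", mother_gt = "ref_hom",
                         stringsAsFactors = FALSE)
  parental$father_gt[info] <- "alt_hom"
  parental$mother_gt[-info] <- "het"
  proband <- list()
  if (inheritance == "biparental") {
    # haplotype 1 paternal: carries the father's alleles at informative loci
    for (i in info)
      proband[[length(proband) + 1L]] <- var_snv(chrom, pos[i], altb[i], hap = 1)
    # haplotype 2: one maternal homolog (het loci toss assigned to hap 2 half the time)
    mat <- setdiff(seq_len(n_tot), info)
    carry <- mat[runif(length(mat)) < 0.5]
    for (i in carry)
      proband[[length(proband) + 1L]] <- var_snv(chrom, pos[i], altb[i], hap = 2)
  } else if (inheritance == "isodisomy") {
    # two copies of a single maternal homolog: identical SNV set on both
    mat <- setdiff(seq_len(n_tot), info)
    carry <- mat[runif(length(mat)) < 0.5]
    for (i in carry)
      proband[[length(proband) + 1L]] <- var_snv(chrom, pos[i], altb[i], hap = 0)
  } else {
    # heterodisomy: the two distinct maternal homologs
    mat <- setdiff(seq_len(n_tot), info)
    for (i in mat) {
      h <- if (runif(1) < 0.5) 1 else 2
      proband[[length(proband) + 1L]] <- var_snv(chrom, pos[i], altb[i], hap = h)
    }
  }
  list(parental = parental, proband_variants = proband, inheritance = inheritance)
}
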