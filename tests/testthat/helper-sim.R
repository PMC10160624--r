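# shared fixture builders; everything is generated in code at test time

# deterministic "different base" (A->C->G->T->A)
other_base <- function(b) unname(c(A = "C", C = "G", G = "T", T = "A")[b])

ref_base <- function(genome, chrom, pos) substr(genome$seq[[chrom]], pos + 1, pos + 1)

errorfree_config <- function(seed, depth = 16, ...)
  sim_config(seed = seed, depth = depth, error_sub = 0, error_ins = 0,
             error_del = 0, ...)

# hand-built alignment records (seq defaults to a run of A's of the right length)
rec <- function(read_id, chrom, start, cigar, seq = NULL, strand = "+",
                mapq = 60L, role = "primary", mean_quality = 16) {
  if (is.null(seq)) seq <- strrep("A", lrconfirm:::cigar_query_len(cigar))
  data.frame(read_id = read_id, chrom = chrom, start = start,
             end = start + lrconfirm:::cigar_ref_len(cigar), strand = strand,
             cigar = cigar, mapq = mapq, role = role, seq = seq,
             mean_quality = mean_quality, stringsAsFactors = FALSE)
}

aln_of <- function(...) alignment_frame(do.call(rbind, list(...)))

# a het SNV scenario on a fresh small genome; returns sim + query
sim_het_snv <- function(pos = 30000, len = 60000, gseed = 101, sseed = 1,
                        depth = 16, ...) {
  g <- make_genome(1, len, seed = gseed)
  rb <- ref_base(g, "chr1", pos)
  ab <- other_base(rb)
  sim <- simulate_alignments(build_haplotypes(g, list(var_snv("chr1", pos, ab, hap = 1))),
                             sim_config(seed = sseed, depth = depth, ...))
  list(sim = sim, genome = g,
       query = query_ssc("snv", "chr1", pos, rb, ab))
}
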