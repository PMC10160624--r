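# hand-built records give exact expectations; the simulator provides the
# stochastic cross-checks

test_that("local depth is the median per-base count of eligible reads", {
  expect_equal(local_depth(lrconfirm:::empty_alignment_frame(), gi("chr1", 0, 100)), 0)
  a <- aln_of(rec("r1", "chr1", 0, "100M"),
              rec("r2", "chr1", 0, "100M"),
              rec("r3", "chr1", 50, "100M"),
              rec("r4", "chr1", 0, "100M", mapq = 0L),           # excluded
              rec("r5", "chr1", 0, "100M", role = "secondary"))  # excluded
  expect_equal(local_depth(a, gi("chr1", 0, 50)), 2)
  expect_equal(local_depth(a, gi("chr1", 50, 100)), 3)
  expect_equal(local_depth(a, gi("chr1", 0, 100)), 2.5)
  expect_equal(local_depth(a, gi("chr1", 200, 300)), 0)
  # mapq-0 reads count when configured in
  expect_equal(local_depth(a, gi("chr1", 0, 50), thresholds(include_mapq0 = TRUE)), 3)
  expect_error(local_depth(a, gi("chrNope", 0, 10), reference = c(chr1 = 1000)),
               "chrNope")
  expect_error(local_depth(a, gi("chr1", 900, 1100), reference = c(chr1 = 1000)),
               "beyond")
})

test_that("allele pileup classifies SNV, deletion and insertion reads", {
  # reference context: positions 0..19 = "ACGTACGTACGTACGTACGT"; SNV at pos 10 (G>T)
  ref20 <- "ACGTACGTACGTACGTACGT"
  alt20 <- ref20; substr(alt20, 11, 11) <- "T"
  q <- query_ssc("s", "chr1", 10, "G", "T", mito = FALSE)
  a <- aln_of(rec("ref1", "chr1", 0, "20M", seq = ref20),
              rec("alt1", "chr1", 0, "20M", seq = alt20),
              rec("alt2", "chr1", 0, "20M", seq = alt20),
              rec("oth1", "chr1", 0, "20M", seq = gsub("G", "C", ref20)),
              rec("nosp", "chr1", 11, "9M", seq = substr(ref20, 12, 20)))
  p <- allele_pileup(a, q)
  expect_equal(p$depth, 4)       # non-spanning read not counted
  expect_equal(p$ref_count, 1)
  expect_equal(p$alt_count, 2)
  expect_equal(p$other_count, 1)
  expect_error(allele_pileup(a, query_ssc("bad", "chr1", 10, "G", "T")), NA)
  expect_error(query_ssc("bad", "chr1", 10, "G", "N"), "A/C/G/T")

  # 6 bp deletion, VCF-style alleles (anchor + deleted bases vs anchor)
  qd <- query_ssc("d", "chr1", 2, "GTACGTA", "G", mito = FALSE)
  del_read <- paste0(substr(ref20, 1, 3), substr(ref20, 10, 20))  # bases 4..9 gone
  ad <- aln_of(rec("withdel", "chr1", 0, "3M6D11M", seq = del_read),
               rec("nodel", "chr1", 0, "20M", seq = ref20))
  pd <- allele_pileup(ad, qd)
  expect_equal(pd$alt_count, 1)
  expect_equal(pd$ref_count, 1)

  # 5 bp observed vs 6 bp expected deletion: within the +/-1 indel tolerance
  del5 <- paste0(substr(ref20, 1, 3), substr(ref20, 9, 20))
  a5 <- aln_of(rec("del5", "chr1", 0, "3M5D12M", seq = del5))
  expect_equal(allele_pileup(a5, qd)$alt_count, 1)
  expect_equal(allele_pileup(a5, qd, thresholds(indel_len_tol = 0))$alt_count, 0)

  # insertion allele: anchor T at pos 3, TAAA inserted after
  qi <- query_ssc("i", "chr1", 3, "T", "TAAA", mito = FALSE)
  ins_read <- paste0(substr(ref20, 1, 4), "AAA", substr(ref20, 5, 20))
  ai <- aln_of(rec("withins", "chr1", 0, "4M3I16M", seq = ins_read),
               rec("noins", "chr1", 0, "20M", seq = ref20))
  pi <- allele_pileup(ai, qi)
  expect_equal(pi$alt_count, 1)
  expect_equal(pi$ref_count, 1)
})

test_that("pileup counts are invariant under read order permutation", {
  s <- sim_het_snv(sseed = 3)
  p0 <- allele_pileup(s$sim$alignments, s$query)
  set.seed(9)
  for (i in 1:3) {
    shuf <- s$sim$alignments[sample(nrow(s$sim$alignments)), ]
    expect_identical(unclass(allele_pileup(alignment_frame(shuf), s$query)),
                     unclass(p0))
  }
})

test_that("on error-free reads the pileup agrees exactly with a string-compare oracle", {
  pos <- 25000
  g <- make_genome(1, 50000, seed = 31)
  rb <- ref_base(g, "chr1", pos); ab <- other_base(rb)
  sim <- simulate_alignments(build_haplotypes(g, list(var_snv("chr1", pos, ab, hap = 1))),
                             errorfree_config(4))
  q <- query_ssc("s", "chr1", pos, rb, ab)
  p <- allele_pileup(sim$alignments, q)
  # oracle: error-free reads are exact haplotype substrings, so the base at
  # the locus is read directly off the record sequence
  aln <- sim$alignments
  span <- aln[aln$role == "primary" & aln$start <= pos & aln$end >= pos + 1, ]
  obs <- vapply(seq_len(nrow(span)), function(i) {
    substr(span$seq[i], pos - span$start[i] + 1, pos - span$start[i] + 1)
  }, character(1))
  expect_equal(p$depth, nrow(span))
  expect_equal(p$alt_count, sum(obs == ab))
  expect_equal(p$ref_count, sum(obs == rb))
  expect_equal(p$other_count, 0)
})

test_that("clipped reads are harvested with side, position and length threshold", {
  a <- aln_of(rec("c1", "chr1", 1000, "250S50M", seq = strrep("A", 300)),
              rec("c2", "chr1", 900, "50M300S", seq = strrep("A", 350)),
              rec("c3", "chr1", 1000, "150S50M", seq = strrep("A", 200)),  # short clip
              rec("m1", "chr1", 950, "100M"))
  cl <- clipped_reads(a, gi("chr1", 900, 1100), min_clip_len = 200)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$read_id, c("c1", "c2"))
  expect_equal(cl$clip_side[cl$read_id == "c1"], "left")
  expect_equal(cl$clip_pos[cl$read_id == "c1"], 1000)
  expect_equal(cl$clip_side[cl$read_id == "c2"], "right")
  expect_equal(cl$clip_pos[cl$read_id == "c2"], 950)
  expect_equal(nrow(clipped_reads(aln_of(rec("m", "chr1", 0, "100M")),
                                  gi("chr1", 0, 100), 200)), 0)
})

test_that("insertion observations carry position, length and sequence per read", {
  a <- aln_of(rec("i1", "chr1", 100, "50M40I50M", seq = paste0(strrep("A", 50), strrep("G", 40), strrep("A", 50))),
              rec("i2", "chr1", 120, "30M35I70M", seq = strrep("C", 135)),
              rec("sm", "chr1", 100, "50M5I50M", seq = strrep("T", 105)))
  obs <- spanning_insertions(a, gi("chr1", 100, 260), min_len = 30)
  expect_equal(nrow(obs), 2)
  expect_setequal(obs$read_id, c("i1", "i2"))
  expect_equal(obs$length[obs$read_id == "i1"], 40)
  expect_equal(obs$position[obs$read_id == "i1"], 150)
  expect_equal(obs$inserted_sequence[obs$read_id == "i1"], strrep("G", 40))
  expect_equal(nrow(spanning_insertions(a, gi("chr1", 0, 50), 30)), 0)
  # deletions companion
  ad <- aln_of(rec("d1", "chr1", 100, "50M60D50M"))
  dl <- spanning_deletions(ad, gi("chr1", 100, 260), min_len = 50)
  expect_equal(dl$position, 150)
  expect_equal(dl$length, 60)
})

test_that("depth is additive across disjoint read sets before the median", {
  g <- make_genome(1, 40000, seed = 21)
  s1 <- simulate_alignments(build_haplotypes(g), errorfree_config(1, depth = 6))
  s2 <- simulate_alignments(build_haplotypes(g), errorfree_config(2, depth = 6))
  a2 <- s2$alignments
  a2$read_id <- paste0(a2$read_id, "_b")
  both <- alignment_frame(rbind(as.data.frame(s1$alignments), as.data.frame(a2)))
  # per-base coverage of the union equals the sum of per-base coverages
  w <- gi("chr1", 10000, 30000)
  cov_of <- function(a) {
    keep <- a$role == "primary" & a$start < w$end & a$end > w$start
    cov <- IRanges::coverage(IRanges::IRanges(a$start[keep] + 1, a$end[keep]),
                             width = 40000)
    as.integer(S4Vectors::window(cov, w$start + 1, w$end))
  }
  expect_identical(cov_of(both), cov_of(s1$alignments) + cov_of(a2))
})
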