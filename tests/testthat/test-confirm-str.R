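random_flank <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("repeat counting matches a regex oracle on error-free reads", {
  set.seed(77)
  motifs <- c("CA", "CAG", "CTG", "ATTCT", "GGGGCC", "GAA")
  for (i in seq_along(motifs)) {
    motif <- motifs[i]
    for (n in sample(5:60, 4)) {
      lf <- random_flank(30, 1000 + 10 * i + n)
      rf <- random_flank(30, 2000 + 10 * i + n)
      # flank edges must not extend the tract by a full unit
      mlast <- substr(motif, nchar(motif), nchar(motif))
      substr(lf, 30, 30) <- other_base(mlast)
      substr(rf, 1, 1) <- other_base(substr(motif, 1, 1))
      read <- paste0(lf, strrep(motif, n), rf)
      got <- count_repeats_in_read(read, motif, lf, rf)
      # oracle: longest run of full motif units anywhere in the read, by regex
      m <- regmatches(read, gregexpr(paste0("(", motif, ")+"), read))[[1]]
      oracle <- max(nchar(m)) / nchar(motif)
      expect_equal(got$repeat_count, oracle)
      expect_true(got$spanning)
      expect_equal(nrow(got$interruptions), 0)
    }
  }
})

test_that("interrupting units count toward the tract and are reported", {
  lf <- random_flank(30, 11); rf <- random_flank(30, 12)
  units <- rep("CTG", 77)
  units[c(21, 45, 60)] <- "TAA"       # 3 interrupting units among 74 CTG
  read <- paste0(lf, paste(units, collapse = ""), rf)
  got <- count_repeats_in_read(read, "CTG", lf, rf)
  expect_equal(got$repeat_count, 77)  # 74 motif + 3 interrupting
  expect_equal(nrow(got$interruptions), 3)
  expect_setequal(got$interruptions$offset_units, c(20, 44, 59))
  expect_setequal(unique(got$interruptions$unit), "TAA")
})

test_that("a read truncated inside the tract yields a non-spanning lower bound", {
  lf <- random_flank(30, 13); rf <- random_flank(30, 14)
  read <- paste0(lf, strrep("CAG", 120))             # right flank never seen
  got <- count_repeats_in_read(read, "CAG", lf, rf)
  expect_equal(got$repeat_count, 120)
  expect_false(got$spanning)
  # left flank absent: count anchored at the right flank
  read2 <- paste0(strrep("CAG", 35), rf)
  got2 <- count_repeats_in_read(read2, "CAG", lf, rf)
  expect_equal(got2$repeat_count, 35)
  expect_false(got2$spanning)
  # neither flank: no-call
  got3 <- count_repeats_in_read(strrep("CAG", 50), "CAG", lf, rf)
  expect_true(is.na(got3$repeat_count))
  expect_error(count_repeats_in_read("ACGT", "CAG", "ACGT", rf), ">= 15")
  expect_error(count_repeats_in_read("ACGT", "NN", lf, rf), "A/C/G/T")
})

test_that("counting is strand-consistent under reverse complement", {
  rc <- function(x) lrconfirm:::revcomp(x)
  for (motif in c("CAG", "GAA", "GGGGCC")) {
    lf <- random_flank(30, 21); rf <- random_flank(30, 22)
    read <- paste0(lf, strrep(motif, 41), rf)
    fwd <- count_repeats_in_read(read, motif, lf, rf)
    rev <- count_repeats_in_read(rc(read), rc(motif), rc(rf), rc(lf))
    expect_equal(rev$repeat_count, fwd$repeat_count)
    expect_equal(rev$spanning, fwd$spanning)
  }
})

test_that("a simulated 16/68 heterozygous expansion profiles as two modes and confirms", {
  g <- make_genome(1, 120000, seed = 51,
                   str_loci = data.frame(chrom = "chr1", pos = 60000,
                                         motif = "CAG", ref_count = 16))
  loc <- g$str_loci
  sim <- simulate_alignments(
    build_haplotypes(g, list(var_str("chr1", loc$start, loc$end, "CAG", 16, 68, hap = 2))),
    sim_config(seed = 52, depth = 16))
  q <- query_str("atn1", "chr1", loc$start, loc$end, "CAG", 36)
  prof <- profile_str_locus(sim$alignments, q, g)
  expect_equal(nrow(prof$allele_summary), 2)
  modes <- sort(prof$allele_summary$repeat_count)
  expect_lt(abs(modes[1] - 16), 3)
  expect_lt(abs(modes[2] - 68), 4)
  expect_gte(prof$max_observed, 36)
  out <- decide_str(prof, q)
  expect_equal(out$result$status, "confirmed")
  expect_gte(out$decision$expanded_reads, 1)

  # homozygous-reference locus: a single mode at the reference count
  sim0 <- simulate_alignments(build_haplotypes(g), sim_config(seed = 53, depth = 20))
  prof0 <- profile_str_locus(sim0$alignments, q, g)
  expect_equal(nrow(prof0$allele_summary), 1)
  expect_lt(abs(prof0$allele_summary$repeat_count[1] - 16), 3)
  expect_equal(decide_str(prof0, q)$result$status, "not_confirmed")
})

test_that("a contracted normal allele stays below threshold (30/23 vs 45)", {
  g <- make_genome(1, 100000, seed = 55,
                   str_loci = data.frame(chrom = "chr1", pos = 50000,
                                         motif = "CGG", ref_count = 30))
  loc <- g$str_loci
  sim <- simulate_alignments(
    build_haplotypes(g, list(var_str("chr1", loc$start, loc$end, "CGG", 30, 23, hap = 2))),
    sim_config(seed = 56, depth = 16))
  q <- query_str("fmr1", "chr1", loc$start, loc$end, "CGG", 45)
  out <- decide_str(profile_str_locus(sim$alignments, q, g), q)
  expect_equal(out$result$status, "not_confirmed")
  expect_equal(out$decision$expanded_reads, 0)
})

test_that("very long expansions confirm from clipped-read lower bounds", {
  # 2000-unit tract (6 kb): the insert exceeds what stays in one alignment,
  # so reads entering the tract are soft-clipped and counted as lower bounds
  g <- make_genome(1, 120000, seed = 57,
                   str_loci = data.frame(chrom = "chr1", pos = 60000,
                                         motif = "CTG", ref_count = 21))
  loc <- g$str_loci
  sim <- simulate_alignments(
    build_haplotypes(g, list(var_str("chr1", loc$start, loc$end, "CTG", 21, 2000, hap = 2))),
    sim_config(seed = 58, depth = 20))
  q <- query_str("dmpk", "chr1", loc$start, loc$end, "CTG", 36)
  prof <- profile_str_locus(sim$alignments, q, g)
  expect_true(any(!prof$per_read$spanning))
  expect_gte(prof$max_observed, 36)
  lower_bounds <- prof$per_read$repeat_count[!prof$per_read$spanning]
  expect_gte(max(lower_bounds), 100)
  # non-spanning counts never define the allele modes
  expect_true(all(prof$allele_summary$repeat_count <=
                    max(c(0, prof$per_read$repeat_count[prof$per_read$spanning]))))
  expect_equal(decide_str(prof, q)$result$status, "confirmed")
})

test_that("mosaic expansions produce a nonzero mosaic range", {
  g <- make_genome(1, 100000, seed = 61,
                   str_loci = data.frame(chrom = "chr1", pos = 50000,
                                         motif = "CTG", ref_count = 21))
  loc <- g$str_loci
  sim <- simulate_alignments(
    build_haplotypes(g, list(var_str("chr1", loc$start, loc$end, "CTG", 21, 340,
                                     hap = 2, mosaic_jitter = 10))),
    sim_config(seed = 62, depth = 16))
  q <- query_str("dmpk", "chr1", loc$start, loc$end, "CTG", 36)
  out <- decide_str(profile_str_locus(sim$alignments, q, g), q)
  expect_equal(out$result$status, "confirmed")
  expect_gt(diff(out$decision$mosaic_range), 0)
})

test_that("the decision threshold boundary is >= by default and configurable", {
  prof <- structure(list(
    locus = gi("chr1", 100, 163), motif = "CAG",
    per_read = data.frame(read_id = c("a", "b"), repeat_count = c(35, 36),
                          spanning = TRUE, n_interruptions = 0L),
    interruptions = cbind(read_id = character(0),
                          lrconfirm:::empty_interruptions()),
    max_observed = 36,
    allele_summary = data.frame(repeat_count = 36, n_reads = 2),
    depth = 14), class = "lrc_repeat_profile")
  q36 <- query_str("x", "chr1", 100, 163, "CAG", 36)
  q37 <- query_str("x", "chr1", 100, 163, "CAG", 37)
  expect_equal(decide_str(prof, q36)$result$status, "confirmed")
  expect_equal(decide_str(prof, q37)$result$status, "not_confirmed")
  expect_equal(decide_str(prof, q36, thresholds(str_count_ge = FALSE))$result$status,
               "not_confirmed")
  # depth floor
  prof$depth <- 11
  expect_equal(decide_str(prof, q36)$result$status, "insufficient_coverage")
  # the bundled locus catalog is well-formed
  cat <- str_catalog()
  expect_true(all(c("gene", "motif", "threshold") %in% names(cat)))
  expect_true(all(cat$threshold > 0))
})
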