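test_that("SSC decision honors the 12x floor and the support rule", {
  ref20 <- strrep("ACGT", 5)
  alt20 <- ref20; substr(alt20, 11, 11) <- "T"
  q <- query_ssc("s", "chr1", 10, "G", "T", mito = FALSE)
  mk <- function(n_alt, n_ref) {
    rows <- c(lapply(seq_len(n_alt), function(i) rec(paste0("a", i), "chr1", 0, "20M", seq = alt20)),
              lapply(seq_len(n_ref), function(i) rec(paste0("r", i), "chr1", 0, "20M", seq = ref20)))
    alignment_frame(do.call(rbind, rows))
  }
  # depth 11: insufficient regardless of support
  r <- confirm_ssc(q, mk(6, 5))
  expect_equal(r$status, "insufficient_coverage")
  expect_equal(r$depth, 11)
  expect_length(r$evidence, 0)
  # depth 30, zero alt reads
  expect_equal(confirm_ssc(q, mk(0, 30))$status, "not_confirmed")
  # support thresholds are AND-ed: 3 reads but < 20% of depth 30
  expect_equal(confirm_ssc(q, mk(3, 27))$status, "not_confirmed")
  expect_equal(confirm_ssc(q, mk(6, 24))$status, "confirmed")
  # boundary: exactly 12x with exactly 3 alt reads at 25%
  expect_equal(confirm_ssc(q, mk(3, 9))$status, "confirmed")
})

test_that("a simulated heterozygous SNV is confirmed at adequate depth", {
  s <- sim_het_snv(sseed = 8, depth = 16)
  r <- confirm_ssc(s$query, s$sim$alignments)
  expect_equal(r$status, "confirmed")
  expect_gt(r$evidence$alt_count / r$evidence$depth, 0.2)
})

test_that("heteroplasmy percent uses half-away-from-zero rounding", {
  # every internally consistent observed-count pair reproduces its percent
  rows <- list(c(20, 1274, 2), c(34, 1280, 3), c(41, 1284, 3),
               c(658, 1699, 39), c(1835, 1905, 96), c(1146, 1193, 96))
  for (r in rows)
    expect_equal(heteroplasmy_estimate(r[1], r[2])$percent_rounded, r[3])
  expect_equal(heteroplasmy_estimate(5, 1000)$percent_rounded, 1)   # 0.5 rounds up
  expect_equal(heteroplasmy_estimate(0, 1200)$fraction, 0)
  e <- heteroplasmy_estimate(658, 1699)
  expect_true(e$fraction >= 0 && e$fraction <= 1)
})

test_that("mitochondrial confirmation requires 1000x and estimates the fraction", {
  gm <- make_genome(1, 6000, seed = 17, chrom_names = "chrM")
  rb <- ref_base(gm, "chrM", 3000); ab <- other_base(rb)
  f <- 658 / 1699
  haps <- build_haplotypes(gm, list(var_snv("chrM", 3000, ab, hap = 2)),
                           copy_depths = list(chrM = c(1 - f, f) * 1400))
  sim <- simulate_alignments(haps, sim_config(seed = 21, read_length_mean = 2000))
  q <- query_ssc("m", "chrM", 3000, rb, ab)
  out <- heteroplasmy(q, sim$alignments)
  expect_equal(out$result$status, "confirmed")
  expect_gt(out$estimate$depth, 1000)
  expect_lt(abs(out$estimate$fraction - f), 0.04)
  # same pileup at sub-1000x: insufficient
  th_hi <- thresholds(min_mito_depth = out$estimate$depth + 1)
  expect_equal(heteroplasmy(q, sim$alignments, th_hi)$result$status,
               "insufficient_coverage")
  # zero alt reads: fraction 0, not confirmed
  ref_reads <- alignment_frame(do.call(rbind, lapply(1:1200, function(i)
    rec(paste0("r", i), "chrM", 0, "41M", seq = strrep("A", 41)))))
  q0 <- query_ssc("m0", "chrM", 20, "A", "G")
  out0 <- heteroplasmy(q0, ref_reads)
  expect_equal(out0$estimate$fraction, 0)
  expect_equal(out0$result$status, "not_confirmed")
})

test_that("low-fraction heteroplasmy is recovered within one percentage point", {
  # the concordance band the assay claims below 30% heteroplasmy, checked
  # where the clinical rows sit (a few percent) at ~1300x
  gm <- make_genome(1, 5000, seed = 19, chrom_names = "chrM")
  rb <- ref_base(gm, "chrM", 2500); ab <- other_base(rb)
  q <- query_ssc("m", "chrM", 2500, rb, ab)
  n_ok <- 0; n_tot <- 0
  for (f in c(0.01, 0.02, 0.03)) {
    haps <- build_haplotypes(gm, list(var_snv("chrM", 2500, ab, hap = 2)),
                             copy_depths = list(chrM = c(1 - f, f) * 1300))
    for (s in 1:2) {
      sim <- simulate_alignments(haps, sim_config(seed = 100 + s, read_length_mean = 2000))
      est <- heteroplasmy(q, sim$alignments)$estimate
      n_tot <- n_tot + 1
      if (abs(est$fraction - f) <= 0.01) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, n_tot - 1)
})

test_that("read-backed phasing separates cis from trans and is symmetric", {
  gp <- make_genome(1, 70000, seed = 23)
  p1 <- 34000; p2 <- 35075    # the pair sits ~1 kb apart, well inside one read
  rb1 <- ref_base(gp, "chr1", p1); rb2 <- ref_base(gp, "chr1", p2)
  a1 <- other_base(rb1); a2 <- other_base(rb2)
  q1 <- query_ssc("v1", "chr1", p1, rb1, a1)
  q2 <- query_ssc("v2", "chr1", p2, rb2, a2)
  sim_tr <- simulate_alignments(
    build_haplotypes(gp, list(var_snv("chr1", p1, a1, hap = 1),
                              var_snv("chr1", p2, a2, hap = 2))),
    sim_config(seed = 31, depth = 20))
  pc <- phase_pair(q1, q2, sim_tr$alignments)
  expect_equal(pc$relationship, "trans")
  # symmetry: swapping the queries swaps the single-variant classes
  pc_swap <- phase_pair(q2, q1, sim_tr$alignments)
  expect_equal(pc_swap$relationship, "trans")
  expect_equal(pc_swap$reads_v1_only, pc$reads_v2_only)
  expect_equal(pc_swap$reads_v2_only, pc$reads_v1_only)
  expect_equal(pc_swap$reads_both, pc$reads_both)

  sim_cis <- simulate_alignments(
    build_haplotypes(gp, list(var_snv("chr1", p1, a1, hap = 1),
                              var_snv("chr1", p2, a2, hap = 1))),
    sim_config(seed = 32, depth = 20))
  expect_equal(phase_pair(q1, q2, sim_cis$alignments)$relationship, "cis")

  # no double-spanning reads -> unphased
  short <- aln_of(rec("x", "chr1", p1 - 50, "100M"),
                  rec("y", "chr1", p2 - 50, "100M"))
  expect_equal(phase_pair(q1, q2, short)$relationship, "unphased")
  expect_error(phase_pair(q1, query_ssc("z", "chr9", 10, "A", "C"), short),
               "same chromosome")
})

test_that("heterozygous SNVs are recovered genome-wide with no false confirmations", {
  # 40 spiked het SNVs and 40 unspiked control loci on one contig; among
  # sufficiently covered loci, nearly all spiked are confirmed and no
  # control is
  g <- make_genome(1, 450000, seed = 41)
  pos <- seq(15000, 405000, by = 10000)
  spike <- pos[seq(1, length(pos), by = 2)]
  ctrl <- pos[seq(2, length(pos), by = 2)]
  vars <- lapply(spike, function(p)
    var_snv("chr1", p, other_base(ref_base(g, "chr1", p)), hap = 1))
  sim <- simulate_alignments(build_haplotypes(g, vars),
                             sim_config(seed = 43, depth = 16))
  res <- function(p) {
    rb <- ref_base(g, "chr1", p)
    confirm_ssc(query_ssc(paste0("q", p), "chr1", p, rb, other_base(rb)),
                sim$alignments)$status
  }
  st_spike <- vapply(spike, res, character(1))
  st_ctrl <- vapply(ctrl, res, character(1))
  eval_spike <- st_spike[st_spike != "insufficient_coverage"]
  expect_gte(length(eval_spike), 15)
  expect_gte(mean(eval_spike == "confirmed"), 0.95)
  expect_true(all(st_ctrl != "confirmed"))
})
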