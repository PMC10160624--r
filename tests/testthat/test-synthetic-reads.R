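test_that("genome construction is reproducible and plants repeat tracts", {
  g1 <- make_genome(2, 20000, seed = 7)
  g2 <- make_genome(2, 20000, seed = 7)
  expect_identical(g1$seq, g2$seq)
  g3 <- make_genome(2, 20000, seed = 8)
  expect_false(identical(g1$seq, g3$seq))
  gs <- make_genome(1, 20000, seed = 7,
                    str_loci = data.frame(chrom = "chr1", pos = 10000,
                                          motif = "CAG", ref_count = 16))
  expect_equal(gs$str_loci$end - gs$str_loci$start, 48)   # 16 x 3 bp
  expect_equal(substr(gs$seq[[1]], 10001, 10048), strrep("CAG", 16))
  expect_error(make_genome(1, 1000), "too small")
})

test_that("identical configurations reproduce byte-identical output", {
  g <- make_genome(1, 50000, seed = 9)
  haps <- build_haplotypes(g, list(var_snv("chr1", 25000, "A", hap = 1)))
  s1 <- simulate_alignments(haps, sim_config(seed = 4))
  s2 <- simulate_alignments(haps, sim_config(seed = 4))
  expect_identical(as.data.frame(s1$alignments), as.data.frame(s2$alignments))
  expect_identical(s1$truth$reads, s2$truth$reads)
  s3 <- simulate_alignments(haps, sim_config(seed = 5))
  expect_false(identical(as.data.frame(s1$alignments), as.data.frame(s3$alignments)))
})

test_that("read counts land near the depth-implied expectation", {
  g <- make_genome(1, 100000, seed = 11)
  sim <- simulate_alignments(build_haplotypes(g), sim_config(seed = 12, depth = 12))
  n <- nrow(sim$truth$reads)
  expected <- 12 * (1e5 + 1e4) / 1e4
  expect_gt(n, expected - 4 * sqrt(expected))
  expect_lt(n, expected + 4 * sqrt(expected))
  # depth recovery: median depth over the interior within binomial bounds
  d <- local_depth(sim$alignments, gi("chr1", 25000, 75000))
  expect_gte(d, 9); expect_lte(d, 15)
})

test_that("error-free reads are exact substrings of their haplotype", {
  g <- make_genome(1, 60000, seed = 13)
  sim <- simulate_alignments(build_haplotypes(g), errorfree_config(14, depth = 8))
  a <- sim$alignments
  for (i in seq_len(nrow(a)))
    expect_identical(a$seq[i], substr(g$seq[[1]], a$start[i] + 1, a$end[i]))
})

test_that("emitted CIGARs are self-consistent under the full error model", {
  g <- make_genome(1, 80000, seed = 15)
  sim <- simulate_alignments(
    build_haplotypes(g, list(var_del("chr1", 40000, 40100, hap = 1),
                             var_ins("chr1", 20000, strrep("ACGT", 80), hap = 2))),
    sim_config(seed = 16, depth = 10))
  a <- sim$alignments
  # alignment_frame() already enforces query-length == sequence-length;
  # additionally the reference span must match the CIGAR
  for (i in seq_len(nrow(a)))
    expect_equal(a$end[i] - a$start[i], lrconfirm:::cigar_ref_len(a$cigar[i]))
  expect_s3_class(a, "lrc_alignments")
})

test_that("realized error rates track the configured rates", {
  g <- make_genome(1, 200000, seed = 17)
  cfg <- sim_config(seed = 18, depth = 8)
  sim <- simulate_alignments(build_haplotypes(g), cfg)
  a <- sim$alignments
  ops <- lapply(a$cigar, lrconfirm:::cigar_ops)
  M <- sum(vapply(ops, function(x) sum(x$len[x$op == "M"]), numeric(1)))
  I <- sum(vapply(ops, function(x) sum(x$len[x$op == "I"]), numeric(1)))
  D <- sum(vapply(ops, function(x) sum(x$len[x$op == "D"]), numeric(1)))
  # homopolymer context multiplies indel rates; with ~25% of positions in
  # homopolymer context and multiplier 2 the effective rate is ~1.25x
  hp_frac <- local({
    s <- strsplit(substr(g$seq[[1]], 1, 50000), "")[[1]]
    mean(s[-1] == s[-length(s)])
  })
  eff <- 1 + (cfg$homopolymer_indel_multiplier - 1) * hp_frac
  expect_lt(abs(I / M - cfg$error_ins * eff) / (cfg$error_ins * eff), 0.15)
  expect_lt(abs(D / M - cfg$error_del * eff) / (cfg$error_del * eff), 0.15)
  # substitutions: compare M-aligned bases to the reference
  sub_mm <- 0; sub_tot <- 0
  for (i in seq_len(min(30, nrow(a)))) {
    co <- ops[[i]]; r <- a$start[i]; q <- 0
    for (k in seq_len(nrow(co))) {
      if (co$op[k] == "M") {
        o <- utf8ToInt(substr(a$seq[i], q + 1, q + co$len[k]))
        e <- utf8ToInt(substr(g$seq[[1]], r + 1, r + co$len[k]))
        sub_mm <- sub_mm + sum(o != e); sub_tot <- sub_tot + co$len[k]
        r <- r + co$len[k]; q <- q + co$len[k]
      } else if (co$op[k] %in% c("I", "S")) q <- q + co$len[k]
      else if (co$op[k] == "D") r <- r + co$len[k]
    }
  }
  expect_lt(abs(sub_mm / sub_tot - cfg$error_sub) / cfg$error_sub, 0.2)
})

test_that("variant spikes change exactly the requested haplotypes", {
  g <- make_genome(1, 50000, seed = 19)
  haps <- build_haplotypes(g, list(var_snv("chr1", 25000, "A", hap = 1)))
  expect_equal(nrow(haps$copies[["chr1.1"]]$snvs), 1)
  expect_equal(nrow(haps$copies[["chr1.2"]]$snvs), 0)
  hom <- build_haplotypes(g, list(var_snv("chr1", 25000, "A", hap = 0)))
  expect_equal(nrow(hom$copies[["chr1.2"]]$snvs), 1)
  # STR expansion to 68 units of a 3 bp motif: 52 extra units = 156 bp inserted
  gs <- make_genome(1, 50000, seed = 20,
                    str_loci = data.frame(chrom = "chr1", pos = 25000,
                                          motif = "CAG", ref_count = 16))
  hs <- build_haplotypes(gs, list(var_str("chr1", 25000, 25048, "CAG", 16, 68, hap = 2)))
  segs <- hs$copies[["chr1.2"]]$segments
  ins <- Filter(function(s) s$type == "ins", segs)
  expect_length(ins, 1)
  expect_equal(nchar(ins[[1]]$seq), (68 - 16) * 3)
  # an inversion produces a reverse-strand segment
  hi <- build_haplotypes(g, list(var_inv("chr1", 10000, 20000, hap = 1)))
  strands <- vapply(Filter(function(s) s$type == "ref", hi$copies[["chr1.1"]]$segments),
                    `[[`, character(1), "strand")
  expect_true("-" %in% strands)
  # overlapping structural specs are rejected with the collision listed
  expect_error(build_haplotypes(g, list(var_del("chr1", 100, 900, hap = 1),
                                        var_inv("chr1", 500, 2000, hap = 1))),
               "overlapping")
})

test_that("reads crossing an inversion junction split into opposite-strand segments", {
  g <- make_genome(1, 200000, seed = 21)
  sim <- simulate_alignments(build_haplotypes(g, list(var_inv("chr1", 60000, 140000, hap = 0))),
                             errorfree_config(22, depth = 10))
  a <- sim$alignments
  split_ids <- names(which(table(a$read_id) > 1))
  expect_gt(length(split_ids), 0)
  near_junction <- vapply(split_ids, function(id) {
    rr <- a[a$read_id == id, ]
    length(unique(rr$strand)) == 2
  }, logical(1))
  expect_true(all(near_junction))
  # exactly one primary record per split read
  for (id in split_ids)
    expect_equal(sum(a$role[a$read_id == id] == "primary"), 1)
})
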