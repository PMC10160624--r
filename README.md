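# lrconfirm

Orthogonal confirmation of genetic variants from low-pass long-read
(nanopore-style) whole-genome alignments.

## What it is for

Clinical genetic testing pipelines discover variants with short-read WGS but
often need an independent technology to confirm them before reporting —
and some variant classes (exact STR expansion lengths, phase of compound
heterozygotes, structural-variant breakpoints) are not fully resolvable by
short reads at all. Low-pass long-read sequencing (~10 kb reads, ~12x
genomic / >1000x mitochondrial depth) can confirm all of these classes at
once: the candidate's coordinates are known, so confirmation is a targeted
inspection of the long-read alignments for the expected signature.

`lrconfirm` implements that inspection as code, for analysts building or
validating such a confirmation workflow. For every queried candidate it
returns one of three verdicts:

* **confirmed** — the expected signature is present with adequate support;
* **not_confirmed** — coverage was adequate (≥12x genomic / ≥1000x
  mitochondrial) but the signature is absent;
* **insufficient_coverage** — local depth is below the floor; the
  operational answer is more sequencing, not a negative call.

Supported classes and their evidence models:

| class | evidence |
|---|---|
| SNV / indel < 50 bp | allele pileup: ≥3 alternate reads and ≥20% alternate fraction |
| mitochondrial SSC | same pileup at ≥1000x; heteroplasmy = alt reads / depth |
| compound het pair | joint classification of double-spanning reads → cis / trans / unphased |
| STR expansion | per-read repeat counting between reference flanks, with interruptions; clipped reads give lower bounds; confirmed when any count ≥ the reportable threshold |
| insertion (incl. mobile elements) | in-read insertion operations within ±30% of expected length; consensus insert emitted for external classification |
| deletion / duplication | in-read CIGAR evidence (≤1 kb) or orientation-consistent split reads at both breakpoints |
| inversion | split reads with opposite-strand segments at the two breakpoints |
| CNV | depth-normalized copy track (1.0 = diploid; het deletion ≈ 0.5) |
| aneuploidy | per-chromosome normalized ploidy (≈ integer copy count) |
| UPD | ≥20 informative parental loci read reference-only, plus a deletion rule-out on the copy track |

The package also ships exact (Clopper–Pearson) binomial validation
statistics — sensitivity, specificity, PPV and accuracy with 95% intervals
from confusion counts, the interval being
`qbeta(α/2, s, n−s+1)` / `qbeta(1−α/2, s+1, n−s)` with the closed boundary
forms `(α/2)^(1/n)` — and a deterministic synthetic long-read simulator
(haplotype spiking, aligner-faithful split reads and soft clips, Q16-like
error model) so the entire decision logic is testable with no external data.

## Worked example

Simulate a small genome carrying a heterozygous SNV and a 16/68 CAG
expansion, then confirm both from the reads alone:

```r
library(lrconfirm)

genome <- make_genome(1, 120000, seed = 205,
                      str_loci = data.frame(chrom = "chr1", pos = 60000,
                                            motif = "CAG", ref_count = 16))
tract <- genome$str_loci
ref_b <- substr(genome$seq[[1]], 30001, 30001)
alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
haps <- build_haplotypes(genome, list(
  var_snv("chr1", 30000, alt_b, hap = 1),
  var_str("chr1", tract$start, tract$end, "CAG", 16, 68, hap = 2)))
sim <- simulate_alignments(haps, sim_config(seed = 42, depth = 16))

confirm_ssc(query_ssc("snv1", "chr1", 30000, ref_b, alt_b), sim$alignments)
#> <result snv1> [SSC] confirmed (depth 16)
#>   depth=16  ref_count=12  alt_count=4  other_count=0

strq <- query_str("str1", "chr1", tract$start, tract$end, "CAG",
                  pathogenic_threshold = 36)
profile_str_locus(sim$alignments, strq, genome)
#> <repeat profile> CAG x chr1:60,001-60,048  depth 14
#>   14 reads counted (13 spanning), max observed 68 units, 141 interruption(s)
#>   alleles:  16 units (10 reads), 68 units (3 reads)
decide_str(profile_str_locus(sim$alignments, strq, genome), strq)$result
#> <result str1> [STR] confirmed (depth 14)
#>   max_observed=68  expanded_reads=4  spanning_reads=13  n_interruption_reads=9
```

The SNV is confirmed with 4 of 16 reads on the alternate allele (a 25%
alternate fraction, above the 3-read / 20% rule); the STR profiles as two
alleles of 16 and 68 units, and 68 ≥ 36 confirms the expansion. The
interruption count is high because read errors inside the repeat tract
shift the counting frame on noisy reads — the total unit count, which the
decision uses, is unaffected (see the methods vignette).

Validation statistics from confusion counts:

```r
metrics(confusion_counts(tp = 164, fp = 0, fn = 1, tn = 168))
#> <validation metrics> TP=164 FP=0 FN=1 TN=168
#>   Sensitivity  0.99394 (95% CI = 0.9667-0.9998)
#>   Specificity  1.00000 (95% CI = 0.9783-1.0000)
#>   PPV          1.00000
#>   Accuracy     0.99700 (95% CI = 0.9834-0.9999)
```

File-based workflows use `read_alignments()` (SAM/BAM), `read_queries()`
(VCF + sidecar TSV for STR/CNV/aneuploidy/UPD rows), `confirm_variants()`
and `write_report()` (TSV/JSON); `inst/cli/confirm.R` wraps them for the
shell. The methods vignette (`vignettes/confirmation-methods.Rmd`) explains
every decision rule, tolerance and simulator assumption.

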