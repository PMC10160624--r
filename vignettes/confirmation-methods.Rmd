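---
title: "Orthogonal variant confirmation from low-pass long reads: models and decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal variant confirmation from low-pass long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrconfirm)
```

## The problem

Short-read whole-genome sequencing detects most clinically reportable
variants, but several classes resist definitive resolution: the exact length
of expanded short tandem repeats (STRs), the phase of candidate compound
heterozygotes, and the breakpoints of many structural variants. Regulatory
practice may additionally require that every reportable variant be confirmed
by an independent ("orthogonal") technology. Low-pass long-read sequencing
(~10 kb nanopore reads at ~12x genomic and >1000x mitochondrial depth) can
serve as that single orthogonal technology: the candidate variant's
coordinates are known, so confirmation reduces to inspecting the long-read
alignments at those coordinates for the expected signature.

`lrconfirm` operationalizes that inspection. Each confirmer takes a typed
query (the candidate variant) and a set of alignments and returns one of
three verdicts:

* `confirmed` — the expected signature is present with adequate support;
* `not_confirmed` — coverage was adequate but the signature is absent
  (in a validation setting, a false negative of the upstream caller, or a
  refuted candidate);
* `insufficient_coverage` — local depth is below the floor (12x genomic,
  1000x mitochondrial by default), so nothing can be concluded. The
  operational response to this verdict is additional sequencing, not a
  negative call.

## Decision rules per variant class

**Small sequence changes (< 50 bp).** Every depth-eligible read spanning the
VCF-style allele window is classified `ref` / `alt` / `other` by comparing
its aligned bases (insertions and deletions included) to the two alleles.
The variant confirms when at least `min_support_reads` (3) alternate reads
are present *and* the alternate fraction reaches `min_support_fraction`
(0.2). These two numbers operationalize what a human reviewer would accept
as "clearly present" in an alignment viewer; they are deliberately exposed
in `thresholds()`. The `other` class absorbs sequencing noise (raw long-read
accuracy is the method's main limitation) and never counts toward
confirmation. Indels of 5 bp and more tolerate a ±1 bp length mismatch,
reflecting homopolymer length noise in nanopore basecalls; set
`indel_len_tol = 0` for strict matching.

**Mitochondrial variants and heteroplasmy.** Identical pileup machinery with
a 1000x floor. The heteroplasmy estimate is the alternate-read fraction;
percentages are rounded half away from zero, which reproduces the package's
bundled clinical concordance rows. One bundled row (82 alt / 1201 reads,
printed as "~6%") is inconsistent with any single rounding rule — 82/1201 =
6.83% — and is documented here rather than special-cased: the package
reports 7% for those counts. No minimum fraction is imposed beyond the
3-read support rule: at 1000x+, heteroplasmies of about 2% are detectable,
and the estimate tracks truth within about one percentage point below 30%
heteroplasmy and about four points above (the band the validation data
support).

**Phasing.** Reads spanning both loci of a candidate compound-heterozygous
pair are jointly classified. A `trans` call requires each single-alternate
class to reach the support minimum while double-alternate reads stay within
a 10% noise allowance; `cis` symmetrically; anything else is `unphased`
(never a phase call on inadequate evidence).

**STR expansions.** Each read overlapping the repeat tract is counted
individually: the two reference flanks are located in the read (edit
distance up to 20% of flank length, accommodating read errors), and the
tract between them is scanned unit by unit. A unit within one mismatch of
the motif counts as a repeat; any other unit is recorded as an interruption
and still counts toward the total tract length — a tract printed as "74 CTG
+3 interrupting" is a 77-unit tract with 3 interruptions. This greedy
unit-by-unit design is transparent and exactly checkable against a regular
expression on error-free reads; under indel errors the total-unit count
remains accurate even when a frame shift misclassifies individual units as
interruptions, which is the property the pathogenic-threshold decision
needs. Reads containing only one flank (expansions longer than the read, or
soft-clipped alignments) contribute lower bounds: they may trigger
confirmation — an expansion beyond the reportable threshold was directly
observed — but never define the reported allele modes. Spanning counts are
clustered into at most two modes by splitting at the largest gap when counts
spread over six or more units; somatic mosaicism shows up as the spread of
expanded-read counts (`mosaic_range`). The threshold comparison is `>=` (a
count equal to the reportable threshold confirms); set
`str_count_ge = FALSE` for strict `>`.

**Structural variants.** Events small enough to sit inside one alignment
(up to `max_inread_sv` = 1 kb) are confirmed from CIGAR evidence: deletion
operations, or insertion operations within ±30% of the expected length (the
tolerance matching the approximate lengths at which such events are
reported). Insertions additionally emit a consensus inserted sequence so the
element family can be classified externally (e.g. BLAST); clip-only evidence
is reported but never suffices alone. Larger events rely on split reads:
segments of one read mapping around both breakpoints within
`breakpoint_window` (±500 bp, the scale of long-read alignment jitter at
kb-resolution breakpoints). Orientation is the discriminating contract —
an inversion requires opposite-strand segment pairs (one breakpoint as
primary, the other as an opposite-orientation supplementary), a deletion
requires same-strand segments that end at the left breakpoint and resume at
the right, a tandem duplication the back-wrapping junction (a segment
ending at the right breakpoint whose partner starts at the left). Three
consistent junction reads confirm; the default is a decision made explicit,
since no numeric rule accompanies visual review. Breakpoint depth is
measured in the flanks pointing away from the event, because the interior
of a real deletion is legitimately depleted.

**Copy number and aneuploidy.** The copy track divides per-window mean depth
(100 kb windows by default) by the median over autosomal windows, putting
the diploid state at 1.0 — a heterozygous deletion at ~0.5, a heterozygous
duplication at ~1.5. The median normalizer makes the track exactly invariant
under global depth rescaling, and no GC correction is applied in this
version. Depth-only evidence is flagged low-confidence for regions under
300 kb (three windows). A CNV confirms when the regional mean is within
±0.2 copies of `expected_copy / 2`; chromosome-level ploidy is per-base
coverage normalized to the autosomal median and scaled to 2, with a ±0.3
tolerance for aneuploidy claims. Both tolerances are package decisions: the
underlying observable is reported only qualitatively (~0.5, ~2x) in the
validation data. Note the normalizer needs genuinely diploid autosomal
material; a query region that spans essentially the whole genome being
normalized cannot be assessed this way.

**Uniparental disomy (UPD).** An informative locus has the non-transmitting
parent homozygous-alternate and the UPD-source parent homozygous-reference:
under biparental inheritance the proband must be heterozygous there, so the
absence of the alternate allele across many loci confirms the UPD,
identically for isodisomy and heterodisomy. Twenty loci are drawn spread
across the region (one per equal-width bin, seeded) — far beyond the
historical minimum of two; under biparental inheritance with per-locus
dropout rate *d*, the probability that all 20 clean loci read
reference-only is bounded by *d*^20, which is the transparency argument
behind the 20-locus standard rather than a formal test. A locus counts as
`alt_seen` only with ≥2 alternate reads at ≥10% of depth, so isolated read
errors cannot overturn a call. Finally the regional normalized copy must be
within ±0.2 of 1.0, ruling out a heterozygous deletion that would mimic
allele absence.

## The synthetic-read generator

Every decision rule above is exercised against simulated data, because the
confirmers' contracts — not an aligner's — are what need testing. The
generator therefore emits alignment records directly from known haplotype
coordinates: haplotypes are segment lists over a reference (with SNV
overlays, insertion segments, reverse-strand segments for inversions,
duplicated or deleted runs, and whole-chromosome copy counts), and each read
is assembled by walking its haplotype interval. Deletions up to 1 kb stay
in-read as D operations and insertions up to 3 kb as I operations; anything
larger splits the read into primary + supplementary segments with soft
clips, reproducing aligner behavior at junctions, including opposite-strand
segments at inversion breakpoints.

Defaults emulate the validated assay: log-normal read lengths with 10 kb
mean (truncated at 500 bp; fragment-shearing protocols yield a long-tailed
distribution whose exact shape is not critical), 12x genomic depth split
across haplotype copies, ≥1000x mitochondrial depth, and per-base error
rates (substitution 1.0%, insertion 0.6%, deletion 0.9%, indels doubled in
homopolymer context) chosen so total error is ~2.5%, i.e. mean read accuracy
around Q16. Error injection is done per record on the CIGAR/sequence pair,
preserving the query-length invariant exactly; simulation is deterministic
per seed.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data — includes basecaller-specific error structure
beyond rate knobs and homopolymer elevation, mappability artifacts
(every simulated read maps uniquely and correctly up to injected errors),
reference bias, chimeric reads, and coverage biases such as GC dependence.
The recovery suite shows the decision logic is correct given
aligner-faithful input; it is not a validation of basecalling or alignment.

## Numerical and operational choices

* Local depth is the *median* per-base count of primary, mapq>0 reads over
  the interval — robust at interval edges; "local observed coverage" has no
  universal formula. Supplementary segments count toward depth only in the
  structural-variant confirmers, where a split read's segments are that
  read's presence at the locus.
* At a nominal 12x, local depth fluctuates essentially as Poisson(12), so
  roughly half of all loci sit below a 12x floor in any single run. The
  clinical procedure answers `insufficient_coverage` with additional
  sequencing; the scenario battery (`scenario_battery()`) mirrors exactly
  that, re-simulating a scenario at higher depth only when the verdict was
  `insufficient_coverage` (never after a refutation).
* Mode clustering for STR alleles splits sorted spanning counts at the
  largest gap only when the spread reaches 6 units; ties in medians round
  half away from zero.
* Degenerate inputs error loudly: empty intervals, non-ACGT alleles,
  breakpoints on different chromosomes for an inversion, a copy track with
  no autosomal coverage, a UPD region with fewer informative candidates
  than requested.

## Problem sizes used in tests

Scenario simulations are scaled to desk size as the package's own study
design: multi-megabase clinical events are represented by a 1.2 Mb
inversion and a 600 kb heterozygous deletion on 2 Mb contigs, karyotype
scenarios by a six-contig toy genome (250 kb contigs), UPD by a 400 kb
chromosome with 120 informative loci, and mitochondrial scenarios by a 6 kb
circular-genome stand-in at ~1100x with ~2 kb reads. The ploidy-recovery
property test uses 1.5 kb reads on a ten-contig toy genome so that
per-chromosome read counts are statistically tight at 12x. Nothing in the
decision logic depends on these sizes; they keep the full suite reproducible
in minutes on one CPU.

## Known limitations

* No GC-bias correction in the copy track (hook: normalize externally and
  feed `alignment_frame()` directly).
* STR counting assumes the motif register starts at the tract boundary;
  frame-shifting indel errors inside a unit are absorbed into the total
  count but misattribute individual units as interruptions, so interruption
  *positions* on noisy reads are approximate (interruption counts on clean
  reads are exact).
* The UPD confirmer requires parental genotypes; it does not discover UPD
  regions, only confirms queried ones.
* Segmentation, mosaic aneuploidy fractions, translocations and de novo SV
  discovery are out of scope: the package confirms queried candidates, it
  does not call variants.
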