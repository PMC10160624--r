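Package: lrconfirm
Title: Orthogonal Variant Confirmation from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Confirms candidate genetic variants against low-pass long-read
    (nanopore-style) whole-genome alignments, as used for orthogonal
    verification in clinical genetic testing. Provides per-variant-type
    evidence extraction and three-way confirm / not-confirm /
    insufficient-coverage decisions for small sequence changes (with
    read-backed phasing and mitochondrial heteroplasmy estimation), short
    tandem repeat expansions (per-read repeat counting with interruption
    detection and clipped-read lower bounds), structural variants (split and
    clipped read evidence, inversion orientation checks), depth-normalized
    copy-number and whole-chromosome ploidy, and uniparental disomy via
    informative parental loci. Includes exact (Clopper-Pearson) binomial
    validation statistics and a deterministic synthetic long-read simulator
    so every confirmer is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
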