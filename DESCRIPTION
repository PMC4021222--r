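Package: panelscan
Title: Candidate-Gene Mining from Nonsynonymous SNPs in Binary-Contrast Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines candidate genes from a resequenced inbred panel split into
    two phenotypic contrast groups (e.g. drought-tolerant versus
    drought-sensitive lines). Implements two complementary locus filters on
    nonsynonymous SNPs: a common-variants (CV) scan for alleles fixed within
    each group but different between groups, and a cluster scan that codes
    loci as a (0,1) non-reference matrix, decomposes it by SVD, applies Ward's
    minimum-variance clustering to the locus-side singular vectors, and selects
    clusters by average variant frequency (AVF) thresholds. Around the two
    scans it provides ANNOVAR-style genomic-region and codon-effect annotation
    from FASTA/GFF3, per-gene nonsynonymous/synonymous substitution profiles,
    singular enrichment analysis of GO terms (Fisher's exact test with
    Bonferroni adjustment), chromosome-bin and QTL integration, expression
    cross-checks, and a fully synthetic panel generator with a planted
    group-differential nsSNP cluster for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
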