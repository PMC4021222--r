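---
title: "Mining candidate genes from nonsynonymous SNPs in a binary-contrast inbred panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining candidate genes from nonsynonymous SNPs in a binary-contrast inbred panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A panel of fully homozygous inbred lines is resequenced against a common
reference assembly and split, by phenotype, into two extreme contrast groups
(here: drought-tolerant vs drought-sensitive maize inbreds) plus a set of
lines with intermediate phenotype. If a trait-relevant allele has been fixed
by selection in one group and absent from the other, the loci carrying it
can be found without any mapping population: they are simply the loci whose
alleles are fixed within each group and differ between the groups. Because
the functional prior is on protein changes, both filters implemented here
operate on nonsynonymous SNPs (nsSNPs).

`panelscan` implements two complementary locus filters plus the machinery
around them:

* **CV (common-variants) scan** — `cv_candidates()` keeps locus $\ell$ iff
  every tolerant line carries one allele $a_T$, every sensitive line carries
  one allele $a_S$, $a_T \neq a_S$, and $\ell$ is nonsynonymous. It is a
  pure set filter: no test statistic, no population-structure correction.
* **Cluster scan** — per chromosome, `build_binary_matrix()` codes the
  nsSNP-by-line matrix $M \in \{0,1\}^{m \times n}$ with
  $M_{\ell j} = 1$ iff line $j$'s allele differs from the reference line's
  allele; rows identical across all lines are removed. `svd_decompose()`
  computes the thin SVD $M = V\,\mathrm{diag}(D)\,G^\top$ ($V$: locus-side
  vectors, $G$: line-side vectors). `ward_cluster()` applies Ward's
  minimum-variance agglomerative clustering to the locus vectors, and
  `select_cluster()` scans $K = k_{\min} \dots k_{\max}$, computing for each
  cluster $c$ and line $j$ the **average variant frequency**
  $\mathrm{AVF}(c, j) = \frac{1}{|c|}\sum_{\ell \in c} M_{\ell j}$,
  and returns the smallest $K$ at which some cluster satisfies
  $\min_{j \in \text{tolerant}} \mathrm{AVF}(c,j) > 0.8$ and
  $\max_{j \in \text{sensitive}} \mathrm{AVF}(c,j) < 0.1$.

The thresholds 0.8 / 0.1 are the selection criterion of the procedure and
are exposed as `tol_min` / `sens_max`. The reference line's column of $M$ is
identically zero by construction, so its AVF is 0 in every cluster — a
useful invariant that the tests assert on every run.

## Clustering the locus-side singular vectors

Two genuinely open choices had to be fixed:

* **Weighting.** The locus-side matrix $V$ has orthonormal columns; feeding
  it to Ward unweighted gives every singular direction equal scale, which
  whitens the decomposition and amplifies the directions that carry the
  least data variation. `select_cluster()` therefore clusters
  $V\,\mathrm{diag}(D)$ by default: since $G$ is orthogonal, Euclidean
  distances between rows of $V\,\mathrm{diag}(D)$ equal distances between
  the raw rows of $M$, so the SVD standardizes the matrix without
  distorting the cluster geometry. On planted synthetic panels the weighted
  form recovers the causal cluster markedly better than the whitened form;
  `svd_weighted = FALSE` restores the literal unweighted variant, and
  `svd_dims` truncates to the leading components.
* **Centering.** The decomposition is applied to the raw (0,1) matrix, not
  a column-centered one (`center = TRUE` exists for conventional biplots).
  Centering subtracts column means and leaves row-difference geometry
  unchanged, so it does not affect the clustering.

Ward linkage is `stats::hclust(method = "ward.D2")` on Euclidean distances
— the Lance–Williams Ward update — and the $K$-partition is obtained by
cutting one agglomerative tree, so the $K$-partition always refines the
$(K{-}1)$-partition and results are deterministic for a given input order
(`hclust` breaks equal merge heights by element order). If several clusters
satisfy the criterion at the selected $K$, all are returned and flagged;
if none satisfies it by `k_max`, a no-selection result (not an error) is
returned.

`biplot_coords()` exports the first two columns of $V$ and $G$ as plotting
coordinates. Coordinates along a numerically zero singular value
($D_k \le 10^{-12} D_1$) are reported as 0, because the corresponding
singular vectors are an arbitrary basis of the null space.

## Variant annotation

`annotate_snps()` assigns every SNP exactly one region label under the
precedence **exonic > splicing > UTR > intronic > promoter > intergenic**,
evaluated across all overlapping transcripts — the categories are mutually
exclusive and sum to the SNP total. Conventions:

* promoter = within `promoter_span` (default 2000 bases) upstream of the
  transcription start, on the transcript's strand;
* splicing = within `splice_window` (default 2) intronic bases of an
  exon/intron boundary;
* `utr5_utr3` labels positions that are 5'-UTR of one transcript and
  3'-UTR of another;
* a position in several transcripts takes the highest-precedence label.

`codon_effect()` rebuilds the reference codon from the spliced CDS in
coding order (reverse-complementing on the minus strand), substitutes the
alternate base and translates with the standard nuclear code, yielding
`synonymous`, `nonsynonymous`, `stop_gain` or `stop_loss`. Reference
alleles are checked against the genome and a mismatch is an error naming
the locus. The test suite verifies the caller against an independent
oracle that translates the entire mutated protein and diffs it against the
reference protein, over a thousand random coding SNPs on both strands, and
checks invariance under reverse-complementing the whole genome.

`summarize_distribution()` tabulates counts, densities (SNPs/kb) and
percentages per region; `gene_ratios()` reports per-gene
nonsynonymous/synonymous counts and their quotient. The reported ratio is
the raw count quotient; genes without synonymous SNPs are flagged
`nonsyn_only` and excluded from the panel mean rather than given an
arbitrary value. No per-site (dN/dS-style) normalization is applied.

Candidate eligibility in both scans is `effect == "nonsynonymous"`:
stop-gain and stop-loss variants are counted as their own categories and
are not folded into the nsSNP set.

## GO enrichment

`sea()` performs singular enrichment analysis: for each term annotated to
at least one study gene, a one-sided Fisher's exact test (hypergeometric
upper tail) of over-representation against the background, then Bonferroni
adjustment over the *tested* terms (the `m` counted is the number of terms
with a study hit, not the whole ontology — exposed via the returned
`p_adjusted = min(1, m p)`). Under-representation is not tested.
`propagate_annotations()` closes gene annotations over `is_a` ancestor
edges first (true-path rule), detects cycles, and is idempotent. The
background defaults to "all genes in the supplied annotation universe";
the study set must be a subset of it.

## Integration reports

* `assign_bins()` places loci into chromosome bins and reports per-bin
  percentages rounded to 2 decimals plus the modal bin.
* `method_overlap()` intersects CV and cluster candidate sets at locus and
  gene level and labels the union `CV` / `cluster` / `both`.
* `qtl_overlap()` joins gene spans (from the GFF3) with QTL intervals;
  both are treated as 1-based inclusive, so touching intervals overlap.
* `expression_crosscheck()` calls a candidate significant when its
  adjusted p is below `alpha` in any tissue and *strong* when additionally
  $|\log_2 FC| \ge 1$ in a significant tissue — "fold change of more than
  two" is interpreted inclusively at the boundary.
* `genotype_concordance()` compares two callsets over loci typed in both;
  loci missing in either are not comparable, and zero comparable loci
  yield an `NA` rate rather than an error.

Missing-call policies: the CV scan is strict by default (a missing call in
any group member excludes the locus; `missing = "tolerate"` requires only
the non-missing members to agree), heterozygous VCF genotypes are read as
missing (inbred-panel assumption), and the binary matrix excludes loci
with any missing call on the chromosome (the count is reported on the
returned object).

## The synthetic panel generator

No real resequencing panel ships with the package; `generate_genome()` /
`generate_panel()` build one from scratch so that every claim the tests
make can be checked against a known truth record.

* The genome is random DNA with non-overlapping protein-coding genes
  (ATG…stop CDS, no internal stops, 1–5 exons, 5'/3' UTRs, both strands)
  spread evenly along each chromosome, and equal-width bins named in the
  maize convention (`"1.07"`).
* Background SNPs are placed uniformly; each locus draws its
  non-reference-allele frequency from `background_alt_freq`
  (default U(0.05, 0.5)) and lines carry the alternate allele
  independently. A background locus that happens to reproduce the exact
  fixed-different pattern between the two contrast groups is re-drawn:
  *neutral* here means "carries no group-differential signal", which is
  what makes the planted causal set the complete truth set and
  precision/recall against it well defined.
* Causal loci are nonsynonymous coding positions inside one designated
  bin (default `"1.07"`); the alternate base is re-sampled until the codon
  effect is nonsynonymous. Every tolerant line carries the alternate
  allele, every sensitive line (including the reference line) the
  reference allele, and each moderate line is an independent
  Bernoulli(`moderate_carrier_prob` = 0.5) carrier.
* Missing calls are injected at `missing_rate` everywhere except
  causal-locus calls of the contrast lines; `noise_rate` flips non-missing
  calls symmetrically. The reference line is exempt from noise because its
  alleles *define* the 0 code (they are the assembly itself); flipping
  them would invert whole rows of the binary matrix rather than perturb
  them.

What the generator deliberately does **not** emulate: linkage
disequilibrium and shared haplotype structure (all loci are independent),
sequencing-read-level error processes, heterozygosity, indels and
structural variants, and realistic gene density. The independence of the
moderate lines matters most: in real panels the moderate lines share
haplotypes, which makes causal rows mutually similar in the moderate
coordinates too; under the Bernoulli stand-in those coordinates are pure
noise, so recovery results on synthetic panels are conservative for the
clustering step. Passing tests demonstrate the correctness of the
machinery and the behavior of the selection criterion under these stated
conditions — not performance on real resequencing data.

## Problem sizes and numerical choices

The validation suite uses planted panels of 50 causal plus 5,000
background SNPs on a 1 Mb chromosome carrying 20 genes, with 3 tolerant,
3 sensitive and 10 moderate lines, over 20 seeds (noise-free and with 5%
genotype noise), plus smaller panels (300 background SNPs on 200 kb) for
unit tests — sizes at which the complete truth record is enumerable and
brute-force oracles (exhaustive CV definition, full-protein translation
diff, hypergeometric tail sums, all-pairs interval joins, exhaustive
2-partitions) run comfortably. Other fixed choices: SVD reconstruction and
orthonormality are asserted at 1e-8; Fisher p-values are checked against
explicit tail sums at 1e-10; bin percentages are rounded to 2 decimals;
equal Ward merge costs follow `hclust`'s deterministic element-order
tie-break; K-scans default to `k_min = 2`, `k_max = min(50, m)`.

## Known limitations

* The CV scan is exact but brittle by design: one genotyping error or
  missing call in a contrast line removes a true locus (strict policy).
* The smallest-satisfying-K rule returns the *first* cluster that meets
  the AVF criterion; under genotype noise this can be a pure subcluster of
  the causal set (high precision, partial recall).
* Only `is_a` ontology edges are propagated; Bonferroni is the only
  multiple-testing adjustment offered, matching the procedure this
  package reproduces.
* Multi-allelic records are split and indels skipped at VCF ingestion;
  effects of indels/CNVs are out of scope.
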