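# panelscan

Candidate-gene mining from nonsynonymous SNPs (nsSNPs) in a resequenced
panel of homozygous inbred lines split into two phenotypic contrast groups
— the setting of drought-tolerance screens in maize, where a handful of
extremely tolerant and extremely sensitive inbreds (plus lines of moderate
phenotype) are resequenced against the B73 reference assembly. The package
is for geneticists who want to run, test or stress such screens end to end,
including on fully synthetic panels with a known planted signal.

Two locus filters are implemented:

* **CV (common-variants) scan** — keep nsSNP locus $\ell$ iff all tolerant
  lines share one allele, all sensitive lines share one allele, and the two
  alleles differ (`cv_candidates()`).
* **Cluster scan** — per chromosome, code nsSNP loci × lines as a (0,1)
  matrix $M$ against the reference line ($M_{\ell j}=1$ iff line $j$
  differs from the reference line), take the thin SVD
  $M = V\,\mathrm{diag}(D)\,G^\top$, cluster the locus-side vectors with
  Ward's minimum-variance linkage, and scan $K$ for the smallest number of
  clusters at which some cluster's **average variant frequency**
  $\mathrm{AVF}(c,j)=\frac{1}{|c|}\sum_{\ell\in c}M_{\ell j}$ exceeds 0.8
  in every tolerant line while staying below 0.1 in every sensitive line
  (`build_binary_matrix()`, `svd_decompose()`, `ward_cluster()`, `avf()`,
  `select_cluster()`, `biplot_coords()`).

Around the filters: ANNOVAR-style region classification (exonic > splicing
> UTR > intronic > promoter > intergenic, 2 kb promoters) with codon-level
effect calls from FASTA + GFF3 (`annotate_snps()`), per-gene Nonsyn/Syn
profiles (`gene_ratios()`), GO singular enrichment analysis with Fisher's
exact test and Bonferroni adjustment (`sea()`), chromosome-bin and QTL
integration (`assign_bins()`, `qtl_overlap()`), expression cross-checks
(`expression_crosscheck()`), genotype concordance
(`genotype_concordance()`), and a synthetic-panel generator with a planted
group-differential nsSNP cluster (`generate_genome()`, `generate_panel()`,
`write_dataset()`). See the vignette in `vignettes/` for the methods.

## Worked example

Generate a 16-line synthetic panel (3 tolerant / 3 sensitive / 10 moderate
lines, 5,000 background SNPs, 50 causal nsSNPs planted in bin 1.07 of a
1 Mb chromosome) and run the whole analysis:

```r
library(panelscan)
cfg <- sim_config(seed = 1, missing_rate = 0)
out <- run_pipeline(cfg)
out$selections[["1"]]
#> cluster_selection: chr 1, K = 2, cluster(s) 2, 56 loci
out$cv
#> candidate_set (CV): 50 loci, 2 genes, 2 transcripts
str(out$summary)
#> List of 14
#>  $ n_loci                     : int 5050
#>  $ n_causal                   : int 50
#>  $ n_nsSNPs                   : int 71
#>  $ cv_loci                    : int 50
#>  $ cv_genes                   : int 2
#>  $ cluster_loci               : int 56
#>  $ cluster_genes              : int 6
#>  $ overlap_loci               : int 50
#>  $ overlap_genes              : int 2
#>  $ union_loci                 : int 56
#>  $ mode_bin                   : chr "1.07"
#>  $ mode_bin_percentage        : num 89.3
#>  ...
```

Reading the output: of 5,050 simulated SNPs, 71 are nonsynonymous; the CV
scan returns exactly the 50 planted causal loci (2 genes), and the K-scan
selects, at K = 2, a 56-locus cluster containing all 50 planted loci plus
6 background nsSNPs whose random carriage pattern resembles the contrast.
All 50 loci found by both methods ("overlap") sit in bin 1.07, the planted
bin, which holds 89.3% of the union candidate set — the bin-density signal
the cluster scan is designed to expose. The same objects give the AVF
table (`out$selections[["1"]]$avf`), biplot coordinates, GO enrichment and
expression cross-check.

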