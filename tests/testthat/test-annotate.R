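test_that("region precedence and promoter window behave as specified", {
  ## gene body [10001, 12000] on +, so the promoter is (8000, 10001)
  seqs <- setNames(paste(rep("ACGT", 5000), collapse = ""), "c1")
  m <- toy_models(chrom = "c1", start = 10001L, end = 12000L, strand = "+")
  snp <- function(pos) data.frame(chrom = "c1", pos = pos,
                                  ref = substr(seqs, pos, pos),
                                  alt = if (substr(seqs, pos, pos) == "A") "C" else "A",
                                  locus_id = paste0("s", pos))
  expect_equal(classify_region(snp(9500L), m)$region, "promoter")
  expect_equal(classify_region(snp(8001L), m)$region, "promoter")
  expect_equal(classify_region(snp(8000L), m)$region, "intergenic")
  expect_equal(classify_region(snp(10001L), m)$region, "exonic")
  expect_equal(classify_region(snp(3000L), m)$region, "intergenic")
  expect_error(classify_region(data.frame(chrom = "cX", pos = 5L, ref = "A",
                                          alt = "G", locus_id = "x"), m),
               "unknown chromosome")
})

test_that("exonic beats splicing across overlapping transcripts; utr5_utr3 needs both sides", {
  ## txA: two exons [11,40] + [61,90], CDS across both; its intron is [41,60]
  ## txB: single-exon CDS gene overlapping txA's intron
  f <- function(tx, gene, s, e) data.frame(tx_id = tx, gene_id = gene,
                                           chrom = "c1", start = s, end = e,
                                           strand = "+", stringsAsFactors = FALSE)
  genes <- rbind(f("x", "gA", 11L, 90L)[-1], f("x", "gB", 35L, 50L)[-1])
  genes$gene_id <- c("gA", "gB")
  m <- gene_models(
    genes = genes,
    transcripts = rbind(f("tA", "gA", 11L, 90L), f("tB", "gB", 35L, 50L)),
    exons = rbind(f("tA", "gA", 11L, 40L), f("tA", "gA", 61L, 90L),
                  f("tB", "gB", 35L, 50L)),
    cds = rbind(f("tA", "gA", 11L, 40L), f("tA", "gA", 61L, 90L),
                f("tB", "gB", 35L, 50L))
  )
  ## position 41: splice site of tA (first 2 intron bases) AND exonic in tB
  s41 <- data.frame(chrom = "c1", pos = 41L, ref = "A", alt = "G", locus_id = "s41")
  r <- classify_region(s41, m)
  expect_equal(r$region, "exonic")
  expect_equal(r$gene_id, "gB")
  ## position 51: inside tA's intron only (tB ends at 50)
  s51 <- data.frame(chrom = "c1", pos = 51L, ref = "A", alt = "G", locus_id = "s51")
  expect_equal(classify_region(s51, m)$region, "intronic")
  ## position 60: splice site of tA (last 2 intron bases), outside tB
  s60 <- data.frame(chrom = "c1", pos = 60L, ref = "A", alt = "G", locus_id = "s60")
  expect_equal(classify_region(s60, m)$region, "splicing")

  ## utr5_utr3: 3'-UTR of a + gene overlapping 5'-UTR of another + gene
  m2 <- gene_models(
    genes = data.frame(gene_id = c("gU", "gV"), chrom = "c1",
                       start = c(11L, 35L), end = c(40L, 70L), strand = "+"),
    transcripts = data.frame(tx_id = c("tU", "tV"), gene_id = c("gU", "gV"),
                             chrom = "c1", start = c(11L, 35L),
                             end = c(40L, 70L), strand = "+"),
    exons = data.frame(tx_id = c("tU", "tV"), chrom = "c1",
                       start = c(11L, 35L), end = c(40L, 70L), strand = "+"),
    cds = data.frame(tx_id = c("tU", "tV"), chrom = "c1",
                     start = c(11L, 45L), end = c(31L, 70L), strand = "+")
  )
  ## 36..40 is 3'-UTR of tU and 5'-UTR of tV
  s38 <- data.frame(chrom = "c1", pos = 38L, ref = "A", alt = "G", locus_id = "s38")
  expect_equal(classify_region(s38, m2)$region, "utr5_utr3")
  ## 41..44 is 5'-UTR of tV only
  s42b <- data.frame(chrom = "c1", pos = 42L, ref = "A", alt = "G", locus_id = "s42b")
  expect_equal(classify_region(s42b, m2)$region, "utr5")
})

test_that("codon effects match hand-derived changes on the plus strand", {
  seqs <- toy_sequences("ATGGCATAA")
  m <- toy_models()
  ## CDS offset 4: GCA -> ACA, Ala -> Thr
  eff <- codon_effect(list(chrom = "t1", pos = 14L, ref = "G", alt = "A"),
                      "gA_T01", m, seqs)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$ref_codon, "GCA"); expect_equal(eff$alt_codon, "ACA")
  expect_equal(eff$ref_aa, "A"); expect_equal(eff$alt_aa, "T")
  expect_equal(eff$aa_pos, 2L)

  ## wobble position: GCT -> GCC stays Ala
  seqs2 <- toy_sequences("ATGGCTTAA")
  eff2 <- codon_effect(list(chrom = "t1", pos = 16L, ref = "T", alt = "C"),
                       "gA_T01", m, seqs2)
  expect_equal(eff2$effect, "synonymous")

  ## TAC -> TAA via third-position C -> A is a stop gain
  seqs3 <- toy_sequences("ATGTACTAA")
  eff3 <- codon_effect(list(chrom = "t1", pos = 16L, ref = "C", alt = "A"),
                       "gA_T01", m, seqs3)
  expect_equal(eff3$effect, "stop_gain")

  ## reference mismatch is a consistency error naming the locus
  expect_error(codon_effect(list(chrom = "t1", pos = 14L, ref = "C", alt = "A",
                                 locus_id = "badref"),
                            "gA_T01", m, seqs),
               "mismatch.*badref")
  ## outside the CDS is a precondition error
  expect_error(codon_effect(list(chrom = "t1", pos = 50L, ref = "A", alt = "G"),
                            "gA_T01", m, seqs),
               "outside the CDS")
})

test_that("minus-strand codon effects are the mirror of plus-strand calls", {
  ## place revcomp("ATGGCATAA") = TTATGCCAT at 11..19 on the minus strand
  seqs <- toy_sequences("TTATGCCAT")
  m <- toy_models(strand = "-")
  ## genomic position 16 is CDS offset 4 (G in coding orientation);
  ## genomic C -> T is coding G -> A, GCA -> ACA
  eff <- codon_effect(list(chrom = "t1", pos = 16L, ref = "C", alt = "T"),
                      "gA_T01", m, seqs)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$ref_codon, "GCA"); expect_equal(eff$alt_codon, "ACA")
})

test_that("codon_effect agrees with full-protein translation diff on random panels", {
  ## property check over synthetic transcripts of both strands
  cfg <- sim_config(chrom_length = 1e5, n_genes_per_chrom = 6L,
                    n_bins_per_chrom = 2L, causal_bin = "1.01",
                    n_background_snps = 10L, n_causal_nssnps = 2L, seed = 31L)
  g <- generate_genome(cfg)
  set.seed(31)
  cds <- g$models$cds
  for (rep in 1:200) {
    i <- sample(nrow(cds), 1L)
    pos <- sample(cds$start[i]:cds$end[i], 1L)
    ref <- substr(g$sequences[[cds$chrom[i]]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    snp <- list(chrom = cds$chrom[i], pos = pos, ref = ref, alt = alt)
    expect_equal(codon_effect(snp, cds$tx_id[i], g$models, g$sequences)$effect,
                 oracle_protein_effect(g$models, g$sequences, cds$tx_id[i], snp),
                 label = sprintf("tx %s pos %d %s>%s", cds$tx_id[i], pos, ref, alt))
  }
})

test_that("effect calls are invariant under genome reverse-complementation", {
  cfg <- sim_config(chrom_length = 5e4, n_genes_per_chrom = 4L,
                    n_bins_per_chrom = 2L, causal_bin = "1.01",
                    n_background_snps = 10L, n_causal_nssnps = 2L, seed = 17L)
  g <- generate_genome(cfg)
  L <- cfg$chrom_length
  ## mirror the genome: revcomp sequence, flip strands and coordinates
  seqs_rc <- setNames(revcomp_str(g$sequences[["1"]]), "1")
  flip_df <- function(d) {
    d2 <- d
    d2$start <- L - d$end + 1L
    d2$end <- L - d$start + 1L
    d2$strand <- ifelse(d$strand == "+", "-", "+")
    d2
  }
  m_rc <- gene_models(flip_df(g$models$genes), flip_df(g$models$transcripts),
                      flip_df(g$models$exons), flip_df(g$models$cds))
  cds <- g$models$cds
  set.seed(99)
  for (rep in 1:50) {
    i <- sample(nrow(cds), 1L)
    pos <- sample(cds$start[i]:cds$end[i], 1L)
    ref <- substr(g$sequences[["1"]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    fwd <- codon_effect(list(chrom = "1", pos = pos, ref = ref, alt = alt),
                        cds$tx_id[i], g$models, g$sequences)
    rc <- codon_effect(list(chrom = "1", pos = L - pos + 1L,
                            ref = chartr("ACGT", "TGCA", ref),
                            alt = chartr("ACGT", "TGCA", alt)),
                       cds$tx_id[i], m_rc, seqs_rc)
    expect_equal(rc$effect, fwd$effect)
    expect_equal(rc$ref_codon, fwd$ref_codon)
    expect_equal(rc$aa_pos, fwd$aa_pos)
  }
})

test_that("region labels partition the SNP set and summaries reconcile", {
  sp <- small_panel(seed = 23L)
  ann <- annotate_snps(sp$panel$genotypes$loci, sp$genome$models,
                       sp$genome$sequences)
  expect_equal(nrow(ann), nrow(sp$panel$genotypes$loci))
  expect_true(all(ann$region %in% c("exonic", "splicing", "utr5", "utr3",
                                    "utr5_utr3", "intronic", "promoter",
                                    "intergenic")))
  expect_true(all((ann$effect != "none") == (ann$region == "exonic")))
  s <- summarize_distribution(ann, c("1" = sp$config$chrom_length))
  tot <- s$per_chrom[s$per_chrom$chrom == "total", ]
  expect_equal(sum(tot[, c("exonic", "splicing", "utr5", "utr3", "utr5_utr3",
                           "intronic", "promoter", "intergenic")]),
               nrow(ann))
  expect_equal(sum(s$percentages), 100, tolerance = 1e-9)
  expect_equal(tot$density_per_kb, nrow(ann) / (sp$config$chrom_length / 1000))
})

test_that("per-gene Nonsyn/Syn profiles follow the counting rules", {
  ann <- data.frame(
    locus_id = sprintf("l%d", 1:10),
    chrom = "1", pos = 1:10, ref = "A", alt = "G",
    region = c(rep("exonic", 9), "intronic"),
    gene_id = c(rep("g1", 6), rep("g2", 3), NA),
    transcript_id = NA,
    effect = c(rep("nonsynonymous", 2), rep("synonymous", 4),
               rep("nonsynonymous", 3), "none"),
    stringsAsFactors = FALSE)
  gr <- gene_ratios(ann)
  p <- gr$profiles
  expect_equal(p$ratio[p$gene_id == "g1"], 0.5)
  expect_true(p$nonsyn_only[p$gene_id == "g2"])
  expect_true(is.na(p$ratio[p$gene_id == "g2"]))
  expect_equal(gr$mean_ratio, 0.5)  # mean over defined ratios only
  ## mean over two defined ratios with one undefined
  ann2 <- ann
  ann2$effect[7] <- "synonymous"  # g2 now 2 nonsyn / 1 syn? -> recompute
  gr2 <- gene_ratios(ann2)
  expect_equal(gr2$mean_ratio, mean(c(0.5, 2)))
})
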