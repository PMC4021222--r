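test_that("generated gene models are well-formed and CDS translate cleanly", {
  cfg <- sim_config(chrom_length = 2e5, n_genes_per_chrom = 5L,
                    n_bins_per_chrom = 4L, causal_bin = "1.02",
                    n_background_snps = 100L, n_causal_nssnps = 5L, seed = 11L)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$models$genes), 5L)
  ## non-overlapping genes
  gn <- g$models$genes[order(g$models$genes$start), ]
  expect_true(all(gn$start[-1] > gn$end[-nrow(gn)]))
  for (tx in g$models$transcripts$tx_id) {
    seg <- g$models$cds[g$models$cds$tx_id == tx, ]
    seg <- seg[order(seg$start), ]
    s <- paste(substring(g$sequences[[seg$chrom[1]]], seg$start, seg$end),
               collapse = "")
    if (seg$strand[1] == "-") s <- revcomp_str(s)
    expect_equal(nchar(s) %% 3L, 0L)
    expect_equal(substr(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- as.character(Biostrings::GENETIC_CODE[codons])
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("bin table partitions each chromosome exactly", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length = 1e6, n_bins_per_chrom = 10L,
                    n_genes_per_chrom = 3L, n_background_snps = 10L,
                    n_causal_nssnps = 2L, seed = 3L)
  g <- generate_genome(cfg)
  for (ch in c("1", "2")) {
    b <- g$bins[g$bins$chrom == ch, ]
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 1L)
    expect_equal(b$end[nrow(b)], 1000000L)
    expect_true(all(b$start[-1] == b$end[-nrow(b)] + 1L))  # contiguous, disjoint
  }
  expect_equal(nrow(g$bins), 20L)
})

test_that("planted contrast holds at every causal locus and missing_rate=0 means no missing", {
  sp <- small_panel(seed = 5L)
  gm <- sp$panel$genotypes
  expect_false(anyNA(gm$calls))
  tol <- sp$groups$tolerant; sen <- sp$groups$sensitive
  for (id in sp$panel$truth$locus_id) {
    expect_true(all(gm$calls[id, tol] == 1L))
    expect_true(all(gm$calls[id, sen] == 0L))
  }
  ## reference line is all-reference by definition (no noise injected)
  expect_true(all(gm$calls[, "B73"] == 0L))
})

test_that("causal loci are nonsynonymous coding SNPs inside the causal bin", {
  sp <- small_panel(seed = 9L)
  ann <- annotate_snps(sp$panel$truth, sp$genome$models, sp$genome$sequences)
  expect_true(all(ann$effect == "nonsynonymous"))
  bin <- sp$genome$bins[sp$genome$bins$bin == sp$config$causal_bin, ]
  expect_true(all(sp$panel$truth$pos >= bin$start & sp$panel$truth$pos <= bin$end))
})

test_that("same seed and config reproduce byte-identical dataset files", {
  cfg <- sim_config(chrom_length = 1e5, n_genes_per_chrom = 4L,
                    n_bins_per_chrom = 4L, causal_bin = "1.02",
                    n_background_snps = 80L, n_causal_nssnps = 5L, seed = 21L)
  run <- function(dir) {
    g <- generate_genome(cfg)
    p <- generate_panel(g, panel_design(), cfg)
    write_dataset(dir, g, p, panel_design())
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- run(d1); p2 <- run(d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[f])), unname(tools::md5sum(p2[f])),
                     label = sprintf("md5 of %s", f))
})

test_that("every emitted format round-trips to the in-memory object", {
  sp <- small_panel(seed = 13L)
  expr <- generate_expression_table(sp$genome$models$genes$gene_id,
                                    sp$panel$truth$gene_id, seed = 13L)
  go <- generate_go_map(sp$genome$models$genes$gene_id,
                        sp$panel$truth$gene_id, seed = 13L)
  d <- withr::local_tempdir()
  paths <- write_dataset(d, sp$genome, sp$panel, sp$design,
                         expression = expr, go = go)

  expect_identical(read_genome_fasta(paths["fasta"]),
                   sp$genome$sequences)

  m2 <- read_gene_models(paths["gff3"])
  norm <- function(d) {
    d <- d[do.call(order, d[intersect(c("chrom", "start", "tx_id"), names(d))]), ]
    rownames(d) <- NULL
    d
  }
  for (part in c("genes", "transcripts", "exons", "cds"))
    expect_equal(norm(m2[[part]]), norm(sp$genome$models[[part]]),
                 label = part)

  gm2 <- read_genotypes(paths["vcf"])
  expect_equal(gm2$loci, sp$panel$genotypes$loci, ignore_attr = TRUE)
  expect_identical(gm2$calls, sp$panel$genotypes$calls)
  expect_identical(gm2$lines, sp$panel$genotypes$lines)

  expect_equal(read_bins(paths["bins"]), sp$genome$bins, ignore_attr = TRUE)
  expect_equal(read_tsv_check(paths["expression"]), expr)
  expect_equal(read_tsv_check(paths["go_map"]), go$gene2term)
  d2 <- read_design(paths["design"])
  expect_identical(d2$lines$line, sp$design$lines$line)
  expect_identical(d2$reference_line, sp$design$reference_line)
})

test_that("heterozygous and missing VCF genotypes are read as missing", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1\t.",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t0"
  ), tmp)
  gm <- read_genotypes(tmp)
  expect_identical(unname(gm$calls["v1", ]), c(NA_integer_, 1L, NA_integer_))
  expect_identical(unname(gm$calls["v2", ]), c(0L, 1L, 0L))
})

test_that("expression generator honours de_fraction boundaries and null model", {
  genes <- sprintf("G%03d", 1:120)
  truth <- genes[1:40]
  sig_genes <- function(tab) {
    hit <- tab$padj < 0.05 & abs(tab$log2fc) >= 1
    unique(tab$gene_id[hit])
  }
  all_de <- generate_expression_table(genes, truth, de_fraction = 1, seed = 2L)
  expect_true(all(truth %in% sig_genes(all_de)))
  none_de <- generate_expression_table(genes, truth, de_fraction = 0, seed = 2L)
  expect_equal(sig_genes(none_de), character(0))  # null padj >= 0.05 throughout
  ## de_fraction = 0.7: binomial count within a 99.99% band around 0.7 * 40
  part <- generate_expression_table(genes, truth, de_fraction = 0.7, seed = 7L)
  n_sig <- sum(truth %in% sig_genes(part))
  expect_gte(n_sig, qbinom(5e-5, 40, 0.7))
  expect_lte(n_sig, qbinom(1 - 5e-5, 40, 0.7))
  ## non-truth genes stay centred on zero
  bg <- part[!part$gene_id %in% truth, ]
  expect_lt(abs(mean(bg$log2fc)), 0.2)
})

test_that("infeasible configurations raise sizing errors", {
  expect_error(sim_config(n_background_snps = 0), "positive count")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  ## genes cannot fit their slot
  cfg <- sim_config(chrom_length = 5000L, n_genes_per_chrom = 10L,
                    n_background_snps = 10L, n_causal_nssnps = 2L,
                    n_bins_per_chrom = 2L, causal_bin = "1.01", seed = 1L)
  expect_error(generate_genome(cfg), "slot")
  ## causal bin without enough coding room
  cfg2 <- sim_config(chrom_length = 2e5, n_genes_per_chrom = 4L,
                     n_bins_per_chrom = 100L, causal_bin = "1.99",
                     n_background_snps = 10L, n_causal_nssnps = 50L, seed = 1L)
  g2 <- generate_genome(cfg2)
  expect_error(generate_panel(g2, panel_design(), cfg2), "coding positions")
})

test_that("multi-allelic records are split and indels skipped at VCF ingestion", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "1\t100\tm1\tA\tG,T\t.\tPASS\t.\tGT\t1\t2",
    "1\t200\tind\tAT\tA\t.\tPASS\t.\tGT\t0\t1",
    "1\t300\tsnp\tC\tT\t.\tPASS\t.\tGT\t0\t1"
  ), tmp)
  expect_message(gm <- read_genotypes(tmp), "skipped 1 indel")
  expect_equal(gm$loci$locus_id, c("m1_alt1", "m1_alt2", "snp"))
  expect_equal(gm$loci$alt[1:2], c("G", "T"))
  ## sample carrying the other alternate allele is missing for this split
  expect_identical(unname(gm$calls["m1_alt1", ]), c(1L, NA_integer_))
  expect_identical(unname(gm$calls["m1_alt2", ]), c(NA_integer_, 1L))
  expect_equal(attr(gm, "n_skipped_indels"), 1L)
})
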