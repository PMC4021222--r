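## Independent oracles and small fixtures shared across the suite.

## --- fixtures -------------------------------------------------------------

## toy chromosome with an embedded sequence at a fixed window
toy_sequences <- function(insert, at = 11L, chrom = "t1", length = 120L,
                          seed = 42L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  substr(s, at, at + nchar(insert) - 1L) <- insert
  setNames(s, chrom)
}

## single-gene single-exon model covering [start, end]
toy_models <- function(chrom = "t1", start = 11L, end = 19L, strand = "+",
                       gene_id = "gA", tx_id = "gA_T01") {
  f <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                  stringsAsFactors = FALSE)
  gene_models(genes = cbind(gene_id = gene_id, f),
              transcripts = cbind(tx_id = tx_id, gene_id = gene_id, f),
              exons = cbind(tx_id = tx_id, f),
              cds = cbind(tx_id = tx_id, f))
}

## random genotype matrix (no annotation semantics)
random_gm <- function(n_loci, n_lines, missing_rate = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  calls <- matrix(sample(c(0L, 1L), n_loci * n_lines, replace = TRUE),
                  nrow = n_loci)
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  loci <- data.frame(chrom = "1", pos = seq_len(n_loci) * 10L,
                     ref = "A", alt = "G",
                     locus_id = sprintf("loc%05d", seq_len(n_loci)),
                     stringsAsFactors = FALSE)
  genotype_matrix(loci, lines, calls)
}

## annotation table declaring every locus a nonsynonymous exonic SNP
all_ns_annotations <- function(gm) {
  data.frame(locus_id = gm$loci$locus_id,
             region = "exonic",
             gene_id = sprintf("gene%03d", (seq_len(nrow(gm$loci)) - 1L) %/% 5L + 1L),
             transcript_id = sprintf("tx%03d", (seq_len(nrow(gm$loci)) - 1L) %/% 5L + 1L),
             effect = "nonsynonymous",
             stringsAsFactors = FALSE)
}

## small planted panel for unit tests (fast); bins of 50 kb, causal bin 1.02
small_panel <- function(seed = 1L, ...) {
  cfg <- sim_config(chrom_length = 2e5, n_genes_per_chrom = 8L,
                    n_bins_per_chrom = 4L, causal_bin = "1.02",
                    n_background_snps = 300L, n_causal_nssnps = 12L,
                    missing_rate = 0, seed = seed, ...)
  genome <- generate_genome(cfg)
  panel <- generate_panel(genome, panel_design(), cfg)
  list(config = cfg, genome = genome, panel = panel,
       design = panel_design(), groups = group_spec(panel_design()))
}

## --- oracles --------------------------------------------------------------

## exhaustive per-locus CV definition
oracle_cv_loci <- function(gm, tolerant, sensitive, ns_ids) {
  out <- character(0)
  for (i in seq_len(nrow(gm$calls))) {
    tc <- gm$calls[i, tolerant]
    sc <- gm$calls[i, sensitive]
    if (any(is.na(tc)) || any(is.na(sc))) next
    if (length(unique(tc)) == 1L && length(unique(sc)) == 1L &&
        tc[1] != sc[1] && gm$loci$locus_id[i] %in% ns_ids)
      out <- c(out, gm$loci$locus_id[i])
  }
  out
}

## full-protein translation diff (independent of codon_effect): mutate the
## genome, splice the CDS by its own path, translate with Biostrings
oracle_protein_effect <- function(models, sequences, tx_id, snp) {
  splice <- function(seqs) {
    seg <- models$cds[models$cds$tx_id == tx_id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    s <- paste(substring(seqs[[seg$chrom[1]]], seg$start, seg$end), collapse = "")
    if (seg$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  mut <- sequences
  chrom_seq <- mut[[snp$chrom]]
  stopifnot(substr(chrom_seq, snp$pos, snp$pos) == snp$ref)
  substr(chrom_seq, snp$pos, snp$pos) <- snp$alt
  mut[[snp$chrom]] <- chrom_seq
  tr <- function(x) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE)), "")[[1]]
  p_ref <- tr(splice(sequences))
  p_alt <- tr(splice(mut))
  d <- which(p_ref != p_alt)
  if (length(d) == 0L) return("synonymous")
  if (p_alt[d[1]] == "*") return("stop_gain")
  if (p_ref[d[1]] == "*") return("stop_loss")
  "nonsynonymous"
}

## hypergeometric upper-tail by explicit summation
oracle_hyper_tail <- function(a, b, n, N) {
  ks <- seq(a, min(b, n))
  sum(choose(b, ks) * choose(N - b, n - ks)) / choose(N, n)
}

## quadratic all-pairs interval join (1-based inclusive)
oracle_interval_join <- function(genes, qtls) {
  hits <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(qtls))) {
    if (genes$chrom[i] == qtls$chrom[j] &&
        genes$start[i] <= qtls$end[j] && qtls$start[j] <= genes$end[i])
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

## exhaustive minimum within-cluster-variance 2-partition of the rows of X
oracle_best_2partition <- function(X) {
  n <- nrow(X)
  wss <- function(M) if (nrow(M) <= 1L) 0 else sum(scale(M, scale = FALSE)^2)
  best <- NULL; best_w <- Inf
  for (m in seq_len(2^(n - 1L) - 1L)) {
    grp <- as.integer(intToBits(m))[seq_len(n)]
    w <- wss(X[grp == 1L, , drop = FALSE]) + wss(X[grp == 0L, , drop = FALSE])
    if (w < best_w) { best_w <- w; best <- grp }
  }
  best
}

## compare two 2-partitions up to label swap
same_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  all(a == b) || all(a == 3L - b)
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

read_tsv_check <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
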