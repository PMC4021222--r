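#' Generate a synthetic genome, gene models and bin table
#'
#' Builds random chromosome sequences carrying non-overlapping protein-coding
#' genes. Every CDS starts with ATG, ends with a stop codon, has length
#' divisible by three and contains no internal stop; genes carry 5'/3' UTRs
#' and a configurable number of exons, on either strand. Each chromosome is
#' partitioned into equal-width bins named `"<chrom>.<nn>"`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_genome`: `sequences` (named character vector
#'   of chromosome sequences), `models` (a [gene_models()]), `bins` (data
#'   frame `bin`, `chrom`, `start`, `end`; 1-based inclusive).
#' @export
#' @examples
#' g <- generate_genome(sim_config(chrom_length = 2e5, n_genes_per_chrom = 4))
#' nrow(g$models$genes)
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chromosomes))
  L <- config$chrom_length
  slot <- L %/% config$n_genes_per_chrom

  seqs <- setNames(character(length(chroms)), chroms)
  genes <- list(); txs <- list(); exons <- list(); cds <- list()
  gi <- 0L
  for (chrom in chroms) {
    chrom_seq <- rand_dna(L)
    for (s in seq_len(config$n_genes_per_chrom)) {
      gi <- gi + 1L
      g <- build_gene_structure(config)
      if (g$length + 2L > slot)
        stopf(paste0("generate_genome: gene of %d bp cannot fit the %d bp ",
                     "slot implied by chrom_length/n_genes_per_chrom"),
              g$length, slot)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") g <- flip_gene_structure(g)
      offset <- (s - 1L) * slot + sample.int(slot - g$length - 1L, 1L)
      substr(chrom_seq, offset + 1L, offset + g$length) <- g$seq
      gene_id <- sprintf("GENE%04d", gi)
      tx_id <- sprintf("%s_T01", gene_id)
      genes[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                start = offset + 1L, end = offset + g$length,
                                strand = strand, stringsAsFactors = FALSE)
      txs[[gi]] <- data.frame(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                              start = offset + 1L, end = offset + g$length,
                              strand = strand, stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(tx_id = tx_id, chrom = chrom,
                                start = g$exons$start + offset,
                                end = g$exons$end + offset,
                                strand = strand, stringsAsFactors = FALSE)
      cds[[gi]] <- data.frame(tx_id = tx_id, chrom = chrom,
                              start = g$cds$start + offset,
                              end = g$cds$end + offset,
                              strand = strand, stringsAsFactors = FALSE)
    }
    seqs[chrom] <- chrom_seq
  }
  models <- gene_models(do.call(rbind, genes), do.call(rbind, txs),
                        do.call(rbind, exons), do.call(rbind, cds))
  bins <- make_bin_table(chroms, L, config$n_bins_per_chrom)
  structure(list(sequences = seqs, models = models, bins = bins),
            class = "sim_genome")
}

## one gene laid out on the + strand in gene-local coordinates (1..length)
build_gene_structure <- function(config) {
  n_aa <- sample(50:150, 1L)
  cds_seq <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_aa, replace = TRUE), collapse = ""),
                    sample(STOP_CODONS, 1L))
  utr5 <- rand_dna(sample(30:100, 1L))
  utr3 <- rand_dna(sample(30:150, 1L))
  mrna <- paste0(utr5, cds_seq, utr3)
  mlen <- nchar(mrna)
  n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
  n_ex <- min(n_ex, mlen)
  cuts <- if (n_ex > 1L) sort(sample(seq_len(mlen - 1L), n_ex - 1L)) else integer(0)
  exon_lens <- diff(c(0L, cuts, mlen))
  intron_lens <- if (n_ex > 1L) sample(60:200, n_ex - 1L, replace = TRUE) else integer(0)

  pieces <- character(0)
  exon_start <- integer(n_ex); exon_end <- integer(n_ex)
  pos <- 0L; mpos <- 0L
  mrna_to_local <- integer(mlen)  # mRNA coordinate -> gene-local genomic coordinate
  for (i in seq_len(n_ex)) {
    exon_start[i] <- pos + 1L
    exon_end[i] <- pos + exon_lens[i]
    pieces <- c(pieces, substr(mrna, mpos + 1L, mpos + exon_lens[i]))
    mrna_to_local[(mpos + 1L):(mpos + exon_lens[i])] <- (pos + 1L):(pos + exon_lens[i])
    pos <- pos + exon_lens[i]; mpos <- mpos + exon_lens[i]
    if (i < n_ex) {
      pieces <- c(pieces, rand_dna(intron_lens[i]))
      pos <- pos + intron_lens[i]
    }
  }
  gseq <- paste(pieces, collapse = "")
  cds_m <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds_seq))
  ## CDS segments = exon pieces intersected with the CDS span of the mRNA
  exon_m_start <- cumsum(c(1L, exon_lens[-n_ex] + 0L))
  exon_m_start <- c(1L, cumsum(exon_lens)[-n_ex] + 1L)
  exon_m_end <- cumsum(exon_lens)
  seg <- list()
  for (i in seq_len(n_ex)) {
    s <- max(exon_m_start[i], cds_m[1]); e <- min(exon_m_end[i], cds_m[2])
    if (s <= e)
      seg[[length(seg) + 1L]] <- c(mrna_to_local[s], mrna_to_local[e])
  }
  seg <- do.call(rbind, seg)
  list(seq = gseq, length = nchar(gseq),
       exons = data.frame(start = exon_start, end = exon_end),
       cds = data.frame(start = seg[, 1], end = seg[, 2]))
}

## mirror a +-strand local structure onto the - strand
flip_gene_structure <- function(g) {
  L <- g$length
  flip <- function(d) {
    out <- data.frame(start = L - d$end + 1L, end = L - d$start + 1L)
    out[order(out$start), , drop = FALSE]
  }
  list(seq = revcomp(g$seq), length = L,
       exons = flip(g$exons), cds = flip(g$cds))
}

make_bin_table <- function(chroms, chrom_length, n_bins) {
  w <- ceiling(chrom_length / n_bins)
  do.call(rbind, lapply(chroms, function(chrom) {
    start <- seq(1L, chrom_length, by = w)
    end <- pmin(start + w - 1L, chrom_length)
    data.frame(bin = sprintf("%s.%02d", chrom, seq_along(start)),
               chrom = chrom, start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }))
}
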