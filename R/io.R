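## Dataset writers and readers. Writers emit plain-text standard formats
## (GFF3/VCF 1-based, BED 0-based half-open); readers go through
## Biostrings / rtracklayer / vcfR and reconstruct the in-memory objects.

write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_dataset
#' @param path File path to read.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

write_gff3 <- function(models, path) {
  utrs <- derive_utrs(models)
  lines <- c("##gff-version 3")
  g <- models$genes
  for (i in order(g$chrom, g$start)) {
    gid <- g$gene_id[i]
    lines <- c(lines, sprintf("%s\tpanelscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid))
    txs <- models$transcripts[models$transcripts$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tid <- txs$tx_id[j]
      lines <- c(lines,
                 sprintf("%s\tpanelscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         txs$chrom[j], txs$start[j], txs$end[j], txs$strand[j],
                         tid, gid))
      ex <- models$exons[models$exons$tx_id == tid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 0L)
        lines <- c(lines,
                   sprintf("%s\tpanelscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           ex$chrom, ex$start, ex$end, ex$strand, tid))
      seg <- cds_in_coding_order(models, tid)
      ph <- cds_phases(seg)
      lines <- c(lines,
                 sprintf("%s\tpanelscan\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                         seg$chrom, seg$start, seg$end, seg$strand, ph, tid))
      for (side in c("utr5", "utr3")) {
        u <- utrs[[side]]
        u <- u[u$tx_id == tid, , drop = FALSE]
        type <- if (side == "utr5") "five_prime_UTR" else "three_prime_UTR"
        if (nrow(u) > 0L)
          lines <- c(lines,
                     sprintf("%s\tpanelscan\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                             u$chrom, type, u$start, u$end, u$strand, tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  first_parent <- function(p) vapply(p, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
  genes <- d[d$type == "gene", , drop = FALSE]
  txs <- d[d$type == "mRNA", , drop = FALSE]
  exons <- d[d$type == "exon", , drop = FALSE]
  cds <- d[d$type == "CDS", , drop = FALSE]
  gene_models(
    genes = data.frame(gene_id = genes$ID, chrom = genes$seqnames,
                       start = genes$start, end = genes$end,
                       strand = genes$strand, stringsAsFactors = FALSE),
    transcripts = data.frame(tx_id = txs$ID,
                             gene_id = first_parent(txs$Parent),
                             chrom = txs$seqnames, start = txs$start,
                             end = txs$end, strand = txs$strand,
                             stringsAsFactors = FALSE),
    exons = data.frame(tx_id = first_parent(exons$Parent),
                       chrom = exons$seqnames, start = exons$start,
                       end = exons$end, strand = exons$strand,
                       stringsAsFactors = FALSE),
    cds = data.frame(tx_id = first_parent(cds$Parent),
                     chrom = cds$seqnames, start = cds$start, end = cds$end,
                     strand = cds$strand, stringsAsFactors = FALSE)
  )
}

write_vcf <- function(gm, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=panelscan")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$lines), collapse = "\t"))
  gt <- gm$calls
  gtc <- matrix(".", nrow = nrow(gt), ncol = ncol(gt))
  gtc[!is.na(gt) & gt == 0L] <- "0"
  gtc[!is.na(gt) & gt == 1L] <- "1"
  body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$locus_id, gm$loci$ref,
                gm$loci$alt, ".", "PASS", ".", "GT",
                apply(gtc, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(fix$ID, colnames(v@gt)[-1]))
  code <- function(x, k) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0", "0/0", "0|0")] <- 0L
    kk <- as.character(k)
    out[x %in% c(kk, paste0(kk, "/", kk), paste0(kk, "|", kk))] <- 1L
    out  # heterozygous and anything else stays missing (inbred panel policy)
  }
  ## fast path: already biallelic SNPs throughout
  if (all(nchar(fix$REF) == 1L) && all(nchar(fix$ALT) == 1L)) {
    calls <- apply(gt, 2L, code, k = 1L)
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt),
                                             dimnames = dimnames(gt))
    loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT, locus_id = fix$ID,
                       stringsAsFactors = FALSE)
    gm <- genotype_matrix(loci, colnames(gt), calls)
    attr(gm, "n_skipped_indels") <- 0L
    return(gm)
  }
  rows <- list(); loci <- list()
  n_indel <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    for (k in seq_along(alts)) {
      if (nchar(fix$REF[i]) != 1L || nchar(alts[k]) != 1L) {
        n_indel <- n_indel + 1L
        next
      }
      id <- fix$ID[i]
      if (is.na(id) || id == ".") id <- sprintf("%s_%s", fix$CHROM[i], fix$POS[i])
      if (multi) id <- sprintf("%s_alt%d", id, k)
      loci[[length(loci) + 1L]] <-
        data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                   ref = fix$REF[i], alt = alts[k], locus_id = id,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- code(gt[i, ], k)
    }
  }
  if (length(loci) == 0L)
    stopf("read_genotypes: no biallelic SNP records in '%s'", path)
  if (n_indel > 0L)
    message(sprintf("read_genotypes: skipped %d indel allele(s)", n_indel))
  gm <- genotype_matrix(do.call(rbind, loci), colnames(gt), do.call(rbind, rows))
  attr(gm, "n_skipped_indels") <- n_indel
  gm
}

write_bed_bins <- function(bins, path) {
  writeLines(paste(bins$chrom, bins$start - 1L, bins$end, bins$bin, sep = "\t"),
             path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_bins <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(bin = gr$name, chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname write_dataset
#' @export
read_qtl <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(trait = gr$name, chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             pve = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
             stringsAsFactors = FALSE)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a complete synthetic dataset to standard-format files
#'
#' Emits the reference FASTA, gene-model GFF3 (1-based), panel VCF v4.2
#' (GT-only, one haploid sample column per inbred line), bin BED (0-based
#' half-open), panel-design TSV, truth TSV and, when given, expression and
#' GO-map TSVs. `read_*` counterparts reproduce the in-memory objects.
#'
#' @param outdir Output directory (created if missing).
#' @param genome A [generate_genome()] result.
#' @param panel A [generate_panel()] result.
#' @param design A [panel_design()].
#' @param expression Optional expression table
#'   ([generate_expression_table()]).
#' @param go Optional GO map ([generate_go_map()]).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(outdir, genome, panel, design,
                          expression = NULL, go = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(fasta = p("reference.fa"), gff3 = p("genes.gff3"),
             vcf = p("panel.vcf"), bins = p("bins.bed"),
             design = p("design.tsv"), truth = p("truth.tsv"))
  write_fasta(genome$sequences, paths["fasta"])
  write_gff3(genome$models, paths["gff3"])
  write_vcf(panel$genotypes, paths["vcf"],
            contig_lengths = vapply(genome$sequences, nchar, integer(1)))
  write_bed_bins(genome$bins, paths["bins"])
  dsn <- design$lines
  dsn$is_reference <- dsn$line == design$reference_line
  write_tsv(dsn, paths["design"])
  write_tsv(panel$truth, paths["truth"])
  if (!is.null(expression)) {
    paths["expression"] <- p("expression.tsv")
    write_tsv(expression, paths["expression"])
  }
  if (!is.null(go)) {
    paths["go_map"] <- p("go_map.tsv")
    paths["go_parents"] <- p("go_parents.tsv")
    write_tsv(go$gene2term, paths["go_map"])
    write_tsv(go$parents, paths["go_parents"])
  }
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  panel_design(lines = d[c("line", "class")],
               reference_line = d$line[as.logical(d$is_reference)][1])
}
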