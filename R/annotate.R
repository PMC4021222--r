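## Variant-effect annotation: ANNOVAR-style region taxonomy with a fixed
## precedence, plus codon-level effect calls from spliced CDS.

REGION_LEVELS <- c("exonic", "splicing", "utr5", "utr3", "utr5_utr3",
                   "intronic", "promoter", "intergenic")
EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stop_gain", "stop_loss", "none")

snp_frame <- function(snps) {
  stopifnot(is.data.frame(snps),
            all(c("chrom", "pos", "ref", "alt") %in% names(snps)))
  if (!"locus_id" %in% names(snps))
    snps$locus_id <- sprintf("%s_%d", snps$chrom, snps$pos)
  bad <- snps$ref == snps$alt |
    !(snps$ref %in% DNA_BASES) | !(snps$alt %in% DNA_BASES)
  if (any(bad))
    stopf("invalid SNP record(s): %s",
          paste(utils::head(snps$locus_id[bad], 3), collapse = ", "))
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps
}

#' Classify SNPs into genomic-region categories
#'
#' Assigns exactly one region label per SNP under the precedence
#' exonic > splicing > UTR > intronic > promoter > intergenic, evaluated over
#' all overlapping transcripts. A position that is 5'-UTR of one transcript
#' and 3'-UTR of another is labelled `utr5_utr3`. `exonic` means overlapping
#' a CDS segment; promoter means within `promoter_span` bases upstream of a
#' transcription start on the transcript's strand; splicing means within
#' `splice_window` intronic bases of an exon/intron boundary.
#'
#' @param snps Data frame with `chrom`, `pos` (1-based), `ref`, `alt` and
#'   optionally `locus_id`.
#' @param models A [gene_models()] object.
#' @param promoter_span Promoter width upstream of the transcription start
#'   (default 2000 bases).
#' @param splice_window Intronic bases flanking each exon boundary that count
#'   as splice sites (default 2).
#' @return Data frame: `locus_id`, `region`, `gene_id`, `transcript_id`.
#' @export
classify_region <- function(snps, models, promoter_span = 2000L,
                            splice_window = 2L) {
  snps <- snp_frame(snps)
  known <- unique(c(models$genes$chrom, models$transcripts$chrom))
  unknown <- setdiff(unique(snps$chrom), known)
  ## SNPs on chromosomes without any gene model are legal (intergenic) only
  ## if the chromosome itself is known to the caller; with models as the only
  ## geography we treat model-less chromosomes as unknown.
  if (length(unknown) > 0L)
    stopf("classify_region: unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))

  n <- nrow(snps)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  tx2gene <- setNames(models$transcripts$gene_id, models$transcripts$tx_id)

  as_gr <- function(d) {
    if (nrow(d) == 0L)
      return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
    S4Vectors::mcols(gr)$tx_id <- d$tx_id
    gr
  }
  first_hit <- function(gr) {
    if (length(gr) == 0L) return(rep(NA_integer_, n))
    h <- GenomicRanges::findOverlaps(snp_gr, gr, select = "first")
    h
  }

  introns <- derive_introns(models)
  utrs <- derive_utrs(models)
  w <- as.integer(splice_window)
  splice <- if (nrow(introns) > 0L && w > 0L) {
    left <- transform(introns, end = pmin(end, start + w - 1L))
    right <- transform(introns, start = pmax(start, end - w + 1L))
    rbind(left, right)
  } else introns[0, , drop = FALSE]
  prom <- derive_promoters(models, promoter_span)
  prom_gr <- if (nrow(prom) > 0L) {
    gr <- GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(prom$start, prom$end))
    S4Vectors::mcols(gr)$tx_id <- prom$tx_id
    gr
  } else GenomicRanges::GRanges()

  hits <- list(
    exonic = first_hit(as_gr(models$cds)),
    splicing = first_hit(as_gr(splice)),
    utr5 = first_hit(as_gr(utrs$utr5)),
    utr3 = first_hit(as_gr(utrs$utr3)),
    intronic = first_hit(as_gr(introns)),
    promoter = if (length(prom_gr)) GenomicRanges::findOverlaps(snp_gr, prom_gr, select = "first") else rep(NA_integer_, n)
  )
  tx_of <- list(
    exonic = models$cds$tx_id, splicing = splice$tx_id,
    utr5 = utrs$utr5$tx_id, utr3 = utrs$utr3$tx_id,
    intronic = introns$tx_id, promoter = prom$tx_id
  )

  region <- rep("intergenic", n)
  tx <- rep(NA_character_, n)
  ## assign lowest precedence first, override with higher
  for (lab in c("promoter", "intronic", "utr3", "utr5", "splicing", "exonic")) {
    idx <- !is.na(hits[[lab]])
    region[idx] <- lab
    tx[idx] <- tx_of[[lab]][hits[[lab]][idx]]
  }
  both_utr <- !is.na(hits$utr5) & !is.na(hits$utr3) & region %in% c("utr5", "utr3")
  region[both_utr] <- "utr5_utr3"

  data.frame(locus_id = snps$locus_id,
             region = region,
             gene_id = ifelse(is.na(tx), NA_character_, unname(tx2gene[tx])),
             transcript_id = tx,
             stringsAsFactors = FALSE)
}

## spliced CDS of a transcript in coding orientation, with its genomic-order
## segment table (already in coding order)
spliced_cds <- function(models, sequences, tx_id) {
  seg <- cds_in_coding_order(models, tx_id)
  strand <- seg$strand[1]
  parts <- vapply(seq_len(nrow(seg)), function(j) {
    s <- substr(sequences[[seg$chrom[j]]], seg$start[j], seg$end[j])
    if (strand == "-") revcomp(s) else s
  }, character(1))
  list(seq = paste(parts, collapse = ""), seg = seg, strand = strand)
}

codon_effect_at <- function(sp, pos, ref, alt, locus_id) {
  seg <- sp$seg; strand <- sp$strand
  lens <- seg$end - seg$start + 1L
  i <- which(pos >= seg$start & pos <= seg$end)
  if (length(i) == 0L)
    stopf("codon_effect: position %d is outside the CDS of %s", pos, seg$tx_id[1])
  i <- i[1]
  before <- if (i > 1L) sum(lens[seq_len(i - 1L)]) else 0L
  off <- if (strand == "-") before + (seg$end[i] - pos + 1L)
         else before + (pos - seg$start[i] + 1L)
  ref_c <- if (strand == "-") comp_base(ref) else ref
  alt_c <- if (strand == "-") comp_base(alt) else alt
  if (substr(sp$seq, off, off) != ref_c)
    stopf("reference allele mismatch at locus %s: VCF says %s, genome has %s",
          locus_id, ref, if (strand == "-") comp_base(substr(sp$seq, off, off)) else substr(sp$seq, off, off))
  ci <- (off - 1L) %/% 3L
  wi <- (off - 1L) %% 3L
  ref_codon <- substr(sp$seq, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, wi + 1L, wi + 1L) <- alt_c
  ref_aa <- unname(CODON_TABLE[ref_codon])
  alt_aa <- unname(CODON_TABLE[alt_codon])
  effect <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "stop_gain"
            else if (ref_aa == "*") "stop_loss"
            else "nonsynonymous"
  list(effect = effect, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, aa_pos = ci + 1L)
}

#' Codon-level effect of a coding SNP
#'
#' Builds the reference codon from the transcript's spliced CDS in coding
#' order (reverse-complemented on the minus strand), substitutes the
#' alternate base and translates with the standard nuclear code.
#'
#' @param snp One-row data frame (or list) with `chrom`, `pos`, `ref`, `alt`
#'   and optionally `locus_id`.
#' @param tx_id Transcript whose CDS contains the SNP.
#' @param models A [gene_models()].
#' @param sequences Named character vector of chromosome sequences.
#' @return List: `effect` (`synonymous`, `nonsynonymous`, `stop_gain`,
#'   `stop_loss`), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `aa_pos`.
#' @export
codon_effect <- function(snp, tx_id, models, sequences) {
  snp <- as.list(snp)
  sp <- spliced_cds(models, sequences, tx_id)
  codon_effect_at(sp, as.integer(snp$pos), snp$ref, snp$alt,
                  snp$locus_id %||% sprintf("%s_%d", snp$chrom, snp$pos))
}

#' Annotate a SNP table with regions and codon effects
#'
#' Region classification for every SNP (see [classify_region()]) plus codon
#' effects for exonic SNPs via [codon_effect()]. Reference alleles are
#' checked against the genome; a mismatch raises an error naming the locus.
#'
#' @inheritParams classify_region
#' @param sequences Named character vector of chromosome sequences.
#' @return Data frame with one row per SNP: `locus_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `region`, `gene_id`, `transcript_id`, `effect`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `aa_pos`. `effect` is
#'   `"none"` for non-exonic SNPs.
#' @export
annotate_snps <- function(snps, models, sequences, promoter_span = 2000L,
                          splice_window = 2L) {
  snps <- snp_frame(snps)
  ## genome consistency check for every SNP
  for (chrom in unique(snps$chrom)) {
    idx <- snps$chrom == chrom
    if (!chrom %in% names(sequences))
      stopf("annotate_snps: no sequence for chromosome '%s'", chrom)
    gbase <- substring(sequences[[chrom]], snps$pos[idx], snps$pos[idx])
    bad <- gbase != snps$ref[idx]
    if (any(bad))
      stopf("reference allele mismatch at locus %s: VCF says %s, genome has %s",
            snps$locus_id[idx][bad][1], snps$ref[idx][bad][1], gbase[bad][1])
  }
  reg <- classify_region(snps, models, promoter_span, splice_window)
  out <- cbind(snps[c("locus_id", "chrom", "pos", "ref", "alt")],
               reg[c("region", "gene_id", "transcript_id")])
  out$effect <- "none"
  out$ref_codon <- NA_character_; out$alt_codon <- NA_character_
  out$ref_aa <- NA_character_; out$alt_aa <- NA_character_
  out$aa_pos <- NA_integer_
  ex <- which(out$region == "exonic")
  if (length(ex) > 0L) {
    for (tx in unique(out$transcript_id[ex])) {
      sp <- spliced_cds(models, sequences, tx)
      for (i in ex[out$transcript_id[ex] == tx]) {
        eff <- codon_effect_at(sp, out$pos[i], out$ref[i], out$alt[i],
                               out$locus_id[i])
        out$effect[i] <- eff$effect
        out$ref_codon[i] <- eff$ref_codon; out$alt_codon[i] <- eff$alt_codon
        out$ref_aa[i] <- eff$ref_aa; out$alt_aa[i] <- eff$alt_aa
        out$aa_pos[i] <- eff$aa_pos
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize SNP distribution over genomic regions
#'
#' Per-chromosome and total counts by region category (with the exonic
#' effect breakdown), SNP density per kb and global percentages.
#'
#' @param ann Annotated SNP table from [annotate_snps()].
#' @param chrom_lengths Named vector of chromosome lengths in bases.
#' @return List: `per_chrom` (data frame, one row per chromosome plus a
#'   `total` row), `percentages` (named vector over region categories,
#'   summing to 100 up to rounding), `exonic_nonsyn_syn_ratio` (raw count
#'   quotient; `NA` when no synonymous SNPs).
#' @export
summarize_distribution <- function(ann, chrom_lengths) {
  stopifnot(all(ann$chrom %in% names(chrom_lengths)))
  chroms <- names(chrom_lengths)
  count_cat <- function(idx) {
    reg <- factor(ann$region[idx], levels = REGION_LEVELS)
    eff <- factor(ann$effect[idx], levels = EFFECT_LEVELS)
    c(total = sum(idx), table(reg),
      nonsyn = sum(eff == "nonsynonymous"), syn = sum(eff == "synonymous"),
      stop_gain = sum(eff == "stop_gain"), stop_loss = sum(eff == "stop_loss"))
  }
  rows <- lapply(chroms, function(ch) count_cat(ann$chrom == ch))
  per_chrom <- as.data.frame(do.call(rbind, rows))
  per_chrom <- cbind(chrom = chroms, per_chrom,
                     density_per_kb = per_chrom$total / (unname(chrom_lengths[chroms]) / 1000))
  total_row <- count_cat(rep(TRUE, nrow(ann)))
  total <- cbind(chrom = "total", as.data.frame(as.list(total_row)),
                 density_per_kb = nrow(ann) / (sum(chrom_lengths) / 1000))
  names(total) <- names(per_chrom)
  per_chrom <- rbind(per_chrom, total)
  rownames(per_chrom) <- NULL
  counts <- total_row[REGION_LEVELS]
  pct <- 100 * counts / max(1L, nrow(ann))
  n_syn <- total_row[["syn"]]
  list(per_chrom = per_chrom,
       percentages = setNames(as.numeric(pct), REGION_LEVELS),
       exonic_nonsyn_syn_ratio = if (n_syn > 0) total_row[["nonsyn"]] / n_syn else NA_real_)
}

#' Per-gene nonsynonymous/synonymous substitution profiles
#'
#' Counts nonsynonymous and synonymous exonic SNPs per gene and their ratio.
#' Genes without synonymous SNPs are flagged `nonsyn_only` and excluded from
#' the panel mean.
#'
#' @param ann Annotated SNP table from [annotate_snps()].
#' @return List: `profiles` (data frame `gene_id`, `n_nonsyn`, `n_syn`,
#'   `ratio`, `nonsyn_only`) and `mean_ratio` (mean over genes with defined
#'   ratio; `NA` when none).
#' @export
gene_ratios <- function(ann) {
  ex <- ann[ann$region == "exonic" &
              ann$effect %in% c("nonsynonymous", "synonymous"), , drop = FALSE]
  if (nrow(ex) == 0L)
    return(list(profiles = data.frame(gene_id = character(),
                                      n_nonsyn = integer(), n_syn = integer(),
                                      ratio = numeric(), nonsyn_only = logical()),
                mean_ratio = NA_real_))
  genes <- sort(unique(ex$gene_id))
  n_ns <- vapply(genes, function(g)
    sum(ex$gene_id == g & ex$effect == "nonsynonymous"), integer(1))
  n_s <- vapply(genes, function(g)
    sum(ex$gene_id == g & ex$effect == "synonymous"), integer(1))
  ratio <- ifelse(n_s > 0L, n_ns / n_s, NA_real_)
  profiles <- data.frame(gene_id = genes, n_nonsyn = unname(n_ns),
                         n_syn = unname(n_s), ratio = unname(ratio),
                         nonsyn_only = unname(n_s == 0L),
                         stringsAsFactors = FALSE)
  rownames(profiles) <- NULL
  list(profiles = profiles,
       mean_ratio = if (any(!is.na(ratio))) mean(ratio, na.rm = TRUE) else NA_real_)
}
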