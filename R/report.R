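## Candidate-set integration: bin density, method overlap, QTL overlap,
## expression cross-check and genotype concordance.

#' Assign loci to chromosome bins and report per-bin percentages
#'
#' @param loci Data frame with `locus_id`, `chrom`, `pos`.
#' @param bins Bin table (`bin`, `chrom`, `start`, `end`, 1-based inclusive).
#' @return List: `per_locus` (data frame `locus_id`, `bin`), `per_bin`
#'   (`bin`, `count`, `percentage` rounded to 2 decimals, over occupied
#'   bins), `mode_bin` (the bin holding the most loci).
#' @export
assign_bins <- function(loci, bins) {
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(loci)),
            all(c("bin", "chrom", "start", "end") %in% names(bins)))
  bin_of <- rep(NA_character_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    idx <- which(loci$chrom == ch)
    for (i in idx) {
      hit <- which(b$start <= loci$pos[i] & b$end >= loci$pos[i])
      if (length(hit) > 0L) bin_of[i] <- b$bin[hit[1]]
    }
  }
  if (anyNA(bin_of))
    stopf("assign_bins: %d locus/loci outside all bins (first: %s)",
          sum(is.na(bin_of)), loci$locus_id[which(is.na(bin_of))[1]])
  counts <- table(bin_of)
  per_bin <- data.frame(bin = names(counts), count = as.integer(counts),
                        percentage = round(100 * as.integer(counts) / nrow(loci), 2),
                        stringsAsFactors = FALSE)
  per_bin <- per_bin[order(-per_bin$count, per_bin$bin), , drop = FALSE]
  rownames(per_bin) <- NULL
  list(per_locus = data.frame(locus_id = loci$locus_id, bin = bin_of,
                              stringsAsFactors = FALSE),
       per_bin = per_bin,
       mode_bin = per_bin$bin[1])
}

#' Overlap between CV and cluster candidate sets
#'
#' @param cv,cluster `candidate_set` objects ([cv_candidates()],
#'   [cluster_candidates()]).
#' @return List: `loci` and `genes`, each with `both`, `cv_only`,
#'   `cluster_only` id vectors and `counts`; plus `labels`, a data frame
#'   labelling every union member `CV`, `cluster` or `both`.
#' @export
method_overlap <- function(cv, cluster) {
  stopifnot(inherits(cv, "candidate_set"), inherits(cluster, "candidate_set"))
  part <- function(a, b) {
    list(both = sort(intersect(a, b)),
         cv_only = sort(setdiff(a, b)),
         cluster_only = sort(setdiff(b, a)),
         counts = c(cv = length(a), cluster = length(b),
                    both = length(intersect(a, b)),
                    union = length(union(a, b))))
  }
  loci <- part(cv$loci$locus_id, cluster$loci$locus_id)
  genes <- part(cv$genes, cluster$genes)
  union_loci <- union(cv$loci$locus_id, cluster$loci$locus_id)
  labels <- data.frame(
    locus_id = union_loci,
    method = ifelse(union_loci %in% loci$both, "both",
                    ifelse(union_loci %in% cv$loci$locus_id, "CV", "cluster")),
    stringsAsFactors = FALSE)
  list(loci = loci, genes = genes, labels = labels)
}

#' Genes overlapping QTL intervals
#'
#' Interval-intersection join between gene spans and QTL intervals
#' (1-based inclusive on both sides; touching intervals overlap).
#'
#' @param genes Data frame: `gene_id`, `chrom`, `start`, `end`.
#' @param qtls Data frame: `trait`, `chrom`, `start`, `end`, optional `pve`.
#' @return Data frame, one row per overlapping (gene, QTL) pair.
#' @export
qtl_overlap <- function(genes, qtls) {
  for (d in list(genes, qtls))
    if (any(d$start > d$end)) stopf("qtl_overlap: malformed interval (start > end)")
  g_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  q_gr <- GenomicRanges::GRanges(qtls$chrom, IRanges::IRanges(qtls$start, qtls$end))
  h <- GenomicRanges::findOverlaps(g_gr, q_gr)
  out <- data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(h)],
                    trait = qtls$trait[S4Vectors::subjectHits(h)],
                    qtl_chrom = qtls$chrom[S4Vectors::subjectHits(h)],
                    qtl_start = qtls$start[S4Vectors::subjectHits(h)],
                    qtl_end = qtls$end[S4Vectors::subjectHits(h)],
                    stringsAsFactors = FALSE)
  if ("pve" %in% names(qtls)) out$pve <- qtls$pve[S4Vectors::subjectHits(h)]
  rownames(out) <- NULL
  out
}

#' Cross-check candidate genes against an expression result table
#'
#' A covered gene is `significant` when its adjusted p is below `alpha` in
#' any tissue, and `strong` when additionally |log2FC| is at least
#' `lfc_threshold` in a significant tissue (the inclusive boundary means a
#' fold change of exactly 2 counts as strong at the default threshold).
#'
#' @param candidate_genes Character vector of gene ids.
#' @param expression Data frame: `gene_id`, `tissue`, `log2fc`, `padj`.
#' @param alpha Significance level (default 0.05).
#' @param lfc_threshold |log2FC| cut for a strong change (default 1,
#'   i.e. two-fold).
#' @return List: `per_gene` (data frame `gene_id`, `covered`, `significant`,
#'   `strong`), `summary` (`n_candidates`, `n_covered`, `n_significant`,
#'   `n_strong`, `frac_significant`, `frac_strong`, computed over covered
#'   genes), `per_tissue` (`tissue`, `up`, `down` counts among significant
#'   records of covered candidates).
#' @export
expression_crosscheck <- function(candidate_genes, expression, alpha = 0.05,
                                  lfc_threshold = 1) {
  stopifnot(all(c("gene_id", "tissue", "log2fc", "padj") %in% names(expression)))
  genes <- unique(candidate_genes)
  ex <- expression[expression$gene_id %in% genes, , drop = FALSE]
  sig_rec <- ex$padj < alpha
  per_gene <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  per_gene$covered <- genes %in% ex$gene_id
  per_gene$significant <- vapply(genes, function(g)
    any(sig_rec[ex$gene_id == g]), logical(1))
  per_gene$strong <- vapply(genes, function(g)
    any(sig_rec[ex$gene_id == g] &
          abs(ex$log2fc[ex$gene_id == g]) >= lfc_threshold), logical(1))
  n_cov <- sum(per_gene$covered)
  sig_ex <- ex[sig_rec, , drop = FALSE]
  tissues <- sort(unique(expression$tissue))
  per_tissue <- data.frame(
    tissue = tissues,
    up = vapply(tissues, function(t) sum(sig_ex$tissue == t & sig_ex$log2fc > 0), integer(1)),
    down = vapply(tissues, function(t) sum(sig_ex$tissue == t & sig_ex$log2fc < 0), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_tissue) <- NULL
  list(per_gene = per_gene,
       summary = list(n_candidates = length(genes), n_covered = n_cov,
                      n_significant = sum(per_gene$significant),
                      n_strong = sum(per_gene$strong),
                      frac_significant = if (n_cov > 0) sum(per_gene$significant) / n_cov else NA_real_,
                      frac_strong = if (n_cov > 0) sum(per_gene$strong) / n_cov else NA_real_),
       per_tissue = per_tissue)
}

#' Genotype concordance between two callsets
#'
#' Concordance rate over loci typed (non-missing) in both callsets; loci
#' missing in either set are not comparable.
#'
#' @param a,b [genotype_matrix()] objects sharing locus ids and line names.
#' @return List: `rate` (`NA` with a warning-free undefined signal when no
#'   locus is comparable), `n_comparable`, `n_match`, `discordant`
#'   (data frame `locus_id`, `line`).
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  shared_loci <- intersect(a$loci$locus_id, b$loci$locus_id)
  shared_lines <- intersect(a$lines, b$lines)
  if (length(shared_loci) == 0L || length(shared_lines) == 0L)
    return(list(rate = NA_real_, n_comparable = 0L, n_match = 0L,
                discordant = data.frame(locus_id = character(), line = character())))
  ca <- a$calls[shared_loci, shared_lines, drop = FALSE]
  cb <- b$calls[shared_loci, shared_lines, drop = FALSE]
  comparable <- !is.na(ca) & !is.na(cb)
  n_comp <- sum(comparable)
  if (n_comp == 0L)
    return(list(rate = NA_real_, n_comparable = 0L, n_match = 0L,
                discordant = data.frame(locus_id = character(), line = character())))
  match_m <- comparable & ca == cb
  disc <- which(comparable & ca != cb, arr.ind = TRUE)
  list(rate = sum(match_m) / n_comp,
       n_comparable = n_comp,
       n_match = sum(match_m),
       discordant = data.frame(locus_id = shared_loci[disc[, 1]],
                               line = shared_lines[disc[, 2]],
                               stringsAsFactors = FALSE))
}
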