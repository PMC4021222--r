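## Common-variants (CV) scan: loci fixed within each contrast group but
## different between groups, restricted to nonsynonymous SNPs.

#' Loci at which a group of lines shares one allele
#'
#' Under the default `"strict"` missing policy a locus qualifies only when
#' every group member has the same non-missing call; under `"tolerate"`,
#' loci with some missing calls qualify if all non-missing members agree
#' (at least one call must be non-missing).
#'
#' @param gm A [genotype_matrix()].
#' @param group Character vector of line names.
#' @param missing `"strict"` (default) or `"tolerate"`.
#' @return Data frame: `locus_id`, `shared` (0 = reference allele,
#'   1 = alternate).
#' @export
common_within_group <- function(gm, group, missing = c("strict", "tolerate")) {
  missing <- match.arg(missing)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(group) == 0L) stopf("common_within_group: group must be non-empty")
  unknown <- setdiff(group, gm$lines)
  if (length(unknown) > 0L)
    stopf("common_within_group: unknown line(s): %s", paste(unknown, collapse = ", "))
  sub <- gm$calls[, group, drop = FALSE]
  n_na <- rowSums(is.na(sub))
  mx <- suppressWarnings(apply(sub, 1L, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
  agree <- n_na < ncol(sub) & mx == mn
  ok <- if (missing == "strict") agree & n_na == 0L else agree
  data.frame(locus_id = gm$loci$locus_id[ok],
             shared = as.integer(mx[ok]),
             stringsAsFactors = FALSE)
}

#' Common-variants candidate nsSNPs and genes
#'
#' Selects nonsynonymous loci whose allele is fixed within the tolerant
#' group, fixed within the sensitive group, and different between the two
#' groups, then maps them to their owning genes and transcripts.
#'
#' @param gm A [genotype_matrix()].
#' @param groups A [group_spec()].
#' @param annotations Annotated SNP table from [annotate_snps()]; must cover
#'   all loci of `gm`.
#' @param missing Missing-call policy, see [common_within_group()].
#' @return Object of class `candidate_set`: `loci` (data frame `locus_id`,
#'   `gene_id`, `transcript_id`, `tolerant_allele`, `sensitive_allele`),
#'   `genes`, `transcripts`, `method = "CV"`.
#' @export
cv_candidates <- function(gm, groups, annotations,
                          missing = c("strict", "tolerate")) {
  missing <- match.arg(missing)
  stopifnot(inherits(gm, "genotype_matrix"), inherits(groups, "group_spec"))
  if (!all(gm$loci$locus_id %in% annotations$locus_id))
    stopf("cv_candidates: annotations must cover every locus")
  tol <- common_within_group(gm, groups$tolerant, missing)
  sen <- common_within_group(gm, groups$sensitive, missing)
  m <- merge(tol, sen, by = "locus_id", suffixes = c("_tol", "_sen"))
  m <- m[m$shared_tol != m$shared_sen, , drop = FALSE]
  ann <- annotations[match(m$locus_id, annotations$locus_id), , drop = FALSE]
  keep <- ann$effect == "nonsynonymous"
  m <- m[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]
  loci <- data.frame(locus_id = m$locus_id,
                     gene_id = ann$gene_id,
                     transcript_id = ann$transcript_id,
                     tolerant_allele = m$shared_tol,
                     sensitive_allele = m$shared_sen,
                     stringsAsFactors = FALSE)
  loci <- loci[order(match(loci$locus_id, gm$loci$locus_id)), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci,
                 genes = sort(unique(loci$gene_id)),
                 transcripts = sort(unique(loci$transcript_id)),
                 method = "CV"),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set (%s): %d loci, %d genes, %d transcripts\n",
              x$method, nrow(x$loci), length(x$genes), length(x$transcripts)))
  invisible(x)
}
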