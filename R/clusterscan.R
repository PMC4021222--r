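## Cluster scan: (0,1) non-reference coding of nsSNP loci, SVD, Ward's
## minimum-variance clustering of the locus-side singular vectors, and
## average-variant-frequency (AVF) threshold selection with a K-scan.

#' Build the (0,1) binary variant matrix for one chromosome
#'
#' Restricts to nonsynonymous loci of `chromosome`, codes each call 0 when
#' the allele equals the reference line's allele at that locus and 1
#' otherwise, drops loci with any missing call (counted), and removes rows
#' whose entries are identical across all lines (variants common to all
#' tested materials carry no contrast).
#'
#' @param gm A [genotype_matrix()].
#' @param annotations Annotated SNP table from [annotate_snps()].
#' @param reference_line Line whose alleles define the 0 code.
#' @param chromosome Chromosome to scan.
#' @return Object of class `binary_variant_matrix`: `B` (integer matrix
#'   loci x lines), `loci` (data frame), `lines`, `reference_line`,
#'   `chromosome`, `n_dropped_missing`, `n_dropped_common`. When no locus
#'   qualifies, `B` has zero rows (an empty-matrix signal, not an error).
#' @export
build_binary_matrix <- function(gm, annotations, reference_line, chromosome) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!reference_line %in% gm$lines)
    stopf("build_binary_matrix: reference line '%s' is not in the panel",
          reference_line)
  ann <- annotations[match(gm$loci$locus_id, annotations$locus_id), , drop = FALSE]
  sel <- gm$loci$chrom == chromosome & !is.na(ann$effect) &
    ann$effect == "nonsynonymous"
  calls <- gm$calls[sel, , drop = FALSE]
  loci <- gm$loci[sel, , drop = FALSE]
  complete <- rowSums(is.na(calls)) == 0L
  n_missing <- sum(!complete)
  calls <- calls[complete, , drop = FALSE]
  loci <- loci[complete, , drop = FALSE]
  B <- (calls != calls[, reference_line]) + 0L
  varying <- apply(B, 1L, function(r) length(unique(r)) > 1L)
  n_common <- sum(!varying)
  B <- B[varying, , drop = FALSE]
  loci <- loci[varying, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(B = B, loci = loci, lines = gm$lines,
                 reference_line = reference_line, chromosome = chromosome,
                 n_dropped_missing = n_missing, n_dropped_common = n_common),
            class = "binary_variant_matrix")
}

#' @export
print.binary_variant_matrix <- function(x, ...) {
  cat(sprintf(paste0("binary_variant_matrix: chr %s, %d loci x %d lines ",
                     "(dropped: %d missing, %d common)\n"),
              x$chromosome, nrow(x$B), length(x$lines),
              x$n_dropped_missing, x$n_dropped_common))
  invisible(x)
}

#' Thin singular value decomposition of the binary variant matrix
#'
#' @param x A `binary_variant_matrix` or a plain numeric matrix
#'   (loci as rows).
#' @param center Center columns before decomposing (off by default; the
#'   procedure operates on the raw (0,1) matrix, a `center = TRUE` variant
#'   exists for conventional biplots).
#' @return Object of class `svd_result`: `V` (loci x r locus-side vectors),
#'   `D` (r singular values, descending), `G` (lines x r line-side vectors),
#'   plus `loci` and `lines` labels when available.
#' @export
svd_decompose <- function(x, center = FALSE) {
  M <- if (inherits(x, "binary_variant_matrix")) x$B else as.matrix(x)
  if (nrow(M) == 0L) stopf("svd_decompose: empty matrix")
  if (center) M <- scale(M, center = TRUE, scale = FALSE)
  s <- svd(M)
  structure(list(V = s$u, D = s$d, G = s$v,
                 loci = if (inherits(x, "binary_variant_matrix")) x$loci$locus_id else rownames(M),
                 lines = if (inherits(x, "binary_variant_matrix")) x$lines else colnames(M)),
            class = "svd_result")
}

ward_tree <- function(V) {
  hclust(dist(V), method = "ward.D2")
}

#' Ward's minimum-variance clustering of locus vectors
#'
#' Agglomerative clustering under the Ward criterion (Lance-Williams update
#' on Euclidean distances) of the rows of `V`, cut at `K` clusters.
#'
#' @param V Numeric matrix, one row per locus (typically `svd_result$V`).
#' @param K Number of clusters, `1 <= K <= nrow(V)`.
#' @return Integer vector of cluster ids (1..K), one per row of `V`.
#' @export
ward_cluster <- function(V, K) {
  V <- as.matrix(V)
  if (K < 1L || K > nrow(V))
    stopf("ward_cluster: K must lie in [1, %d]", nrow(V))
  if (nrow(V) == 1L) return(1L)
  cutree(ward_tree(V), k = K)
}

#' Average variant frequency per cluster and line
#'
#' @param bvm A [build_binary_matrix()] result.
#' @param assignments Integer cluster id per locus (row of `bvm$B`).
#' @return Numeric matrix clusters x lines; entry (c, l) is the mean of the
#'   0/1 codes of line l over the loci of cluster c. The reference line's
#'   column is identically 0.
#' @export
avf <- function(bvm, assignments) {
  stopifnot(inherits(bvm, "binary_variant_matrix"),
            length(assignments) == nrow(bvm$B))
  sums <- rowsum(bvm$B, group = assignments)
  sizes <- as.vector(table(assignments)[rownames(sums)])
  out <- sums / sizes
  rownames(out) <- rownames(sums)
  out
}

#' K-scan cluster selection by AVF thresholds
#'
#' Scans K from `k_min` to `k_max`; at each K, clusters the locus-side
#' singular vectors with [ward_cluster()] and tests every cluster against
#' the selection criterion: minimum AVF over the tolerant lines above
#' `tol_min` and maximum AVF over the sensitive lines below `sens_max`.
#' Returns the smallest K with at least one satisfying cluster. If several
#' clusters satisfy the criterion at that K, all are reported and flagged.
#'
#' @param bvm A [build_binary_matrix()] result.
#' @param groups A [group_spec()].
#' @param tol_min Lower AVF bound for tolerant lines (default 0.8).
#' @param sens_max Upper AVF bound for sensitive lines (default 0.1).
#' @param k_min,k_max K-scan range (defaults 2 and `min(50, n loci)`).
#' @param svd_weighted Weight the columns of V by the singular values before
#'   clustering (default TRUE). With weighting, Euclidean distances between
#'   locus vectors equal the distances between the raw (0,1) rows, so the
#'   decomposition standardizes without distorting the cluster geometry;
#'   `FALSE` clusters the orthonormal V columns directly.
#' @param svd_dims Number of leading columns of V to cluster on
#'   (default: all).
#' @param center Passed to [svd_decompose()].
#' @return Object of class `cluster_selection`: `found`, `K`, `assignments`
#'   (named by locus id), `selected` (satisfying cluster id(s)),
#'   `multiple` flag, `avf` (AVF table at the selected K), `loci` (locus
#'   ids of the selected cluster(s)), `thresholds`, `chromosome`, `svd`.
#'   When no K satisfies the criterion, `found = FALSE` and `K = NA`.
#' @export
select_cluster <- function(bvm, groups, tol_min = 0.8, sens_max = 0.1,
                           k_min = 2L, k_max = NULL, svd_weighted = TRUE,
                           svd_dims = NULL, center = FALSE) {
  stopifnot(inherits(bvm, "binary_variant_matrix"),
            inherits(groups, "group_spec"))
  if (tol_min < 0 || tol_min > 1 || sens_max < 0 || sens_max > 1)
    stopf("select_cluster: thresholds must lie in [0, 1]")
  n <- nrow(bvm$B)
  if (is.null(k_max)) k_max <- min(50L, n)
  if (k_max < k_min) stopf("select_cluster: k_max < k_min")
  unknown <- setdiff(c(groups$tolerant, groups$sensitive), bvm$lines)
  if (length(unknown) > 0L)
    stopf("select_cluster: unknown line(s): %s", paste(unknown, collapse = ", "))
  empty <- structure(list(found = FALSE, K = NA_integer_,
                          assignments = integer(0), selected = integer(0),
                          multiple = FALSE, avf = NULL, loci = character(0),
                          thresholds = c(tol_min = tol_min, sens_max = sens_max),
                          chromosome = bvm$chromosome, svd = NULL),
                     class = "cluster_selection")
  if (n == 0L) return(empty)
  sv <- svd_decompose(bvm, center = center)
  V <- sv$V
  if (svd_weighted) V <- sweep(V, 2L, sv$D, `*`)
  if (!is.null(svd_dims)) V <- V[, seq_len(min(svd_dims, ncol(V))), drop = FALSE]
  tree <- if (n > 1L) ward_tree(V) else NULL
  for (K in seq(min(k_min, n), min(k_max, n))) {
    asg <- if (n == 1L) 1L else cutree(tree, k = K)
    tab <- avf(bvm, asg)
    tol_min_avf <- apply(tab[, groups$tolerant, drop = FALSE], 1L, min)
    sens_max_avf <- apply(tab[, groups$sensitive, drop = FALSE], 1L, max)
    hit <- which(tol_min_avf > tol_min & sens_max_avf < sens_max)
    if (length(hit) > 0L) {
      ids <- as.integer(rownames(tab)[hit])
      names(asg) <- bvm$loci$locus_id
      return(structure(list(found = TRUE, K = K, assignments = asg,
                            selected = ids, multiple = length(ids) > 1L,
                            avf = tab,
                            loci = bvm$loci$locus_id[asg %in% ids],
                            thresholds = c(tol_min = tol_min, sens_max = sens_max),
                            chromosome = bvm$chromosome, svd = sv),
                       class = "cluster_selection"))
    }
  }
  empty
}

#' @export
print.cluster_selection <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("cluster_selection: chr %s, no cluster satisfied the AVF criterion\n",
                x$chromosome))
  } else {
    cat(sprintf("cluster_selection: chr %s, K = %d, cluster(s) %s, %d loci%s\n",
                x$chromosome, x$K, paste(x$selected, collapse = ","),
                length(x$loci), if (x$multiple) " [multiple clusters]" else ""))
  }
  invisible(x)
}

#' Candidate set from a cluster selection
#'
#' Maps the loci of the selected cluster(s) to genes/transcripts via the
#' annotation table, mirroring the CV candidate structure so the two methods
#' can be intersected.
#'
#' @param selection A [select_cluster()] result with `found = TRUE`.
#' @param annotations Annotated SNP table from [annotate_snps()].
#' @return A `candidate_set` with `method = "cluster"`.
#' @export
cluster_candidates <- function(selection, annotations) {
  stopifnot(inherits(selection, "cluster_selection"))
  if (!selection$found)
    return(structure(list(loci = data.frame(locus_id = character(),
                                            gene_id = character(),
                                            transcript_id = character(),
                                            stringsAsFactors = FALSE),
                          genes = character(0), transcripts = character(0),
                          method = "cluster"),
                     class = "candidate_set"))
  ann <- annotations[match(selection$loci, annotations$locus_id), , drop = FALSE]
  loci <- data.frame(locus_id = selection$loci, gene_id = ann$gene_id,
                     transcript_id = ann$transcript_id, stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  structure(list(loci = loci, genes = sort(unique(loci$gene_id)),
                 transcripts = sort(unique(loci$transcript_id)),
                 method = "cluster"),
            class = "candidate_set")
}

#' Biplot coordinates from the SVD
#'
#' First two locus-side and line-side singular vectors, exported as
#' coordinate tables (no rendering).
#'
#' @param sv An [svd_decompose()] result with rank >= 2.
#' @return List of data frames `loci` (`locus_id`, `x`, `y`) and `lines`
#'   (`line`, `x`, `y`).
#' @export
biplot_coords <- function(sv) {
  stopifnot(inherits(sv, "svd_result"))
  if (length(sv$D) < 2L)
    stopf("biplot_coords: need at least two singular vectors, have %d",
          length(sv$D))
  ## a (numerically) zero singular value spans no data variation; its
  ## singular vectors are an arbitrary null-space basis, so those
  ## coordinates are reported as 0
  keep <- sv$D > 1e-12 * max(sv$D[1], .Machine$double.eps)
  vx <- if (keep[1]) sv$V[, 1] else 0; vy <- if (keep[2]) sv$V[, 2] else 0
  gx <- if (keep[1]) sv$G[, 1] else 0; gy <- if (keep[2]) sv$G[, 2] else 0
  list(loci = data.frame(locus_id = sv$loci %||% seq_len(nrow(sv$V)),
                         x = vx, y = vy,
                         stringsAsFactors = FALSE),
       lines = data.frame(line = sv$lines %||% seq_len(nrow(sv$G)),
                          x = gx, y = gy,
                          stringsAsFactors = FALSE))
}
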