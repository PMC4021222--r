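#' Run the full candidate-gene mining pipeline on a synthetic panel
#'
#' Generates a synthetic genome + panel, annotates every SNP, runs the CV
#' scan and the per-chromosome cluster scan, intersects the two candidate
#' sets, assigns candidate loci to bins, tests GO enrichment of the
#' candidate genes and cross-checks expression — the whole analysis from a
#' single configuration.
#'
#' @param config A [sim_config()].
#' @param design A [panel_design()].
#' @param tol_min,sens_max,k_min,k_max Cluster-selection parameters, see
#'   [select_cluster()].
#' @param de_fraction Share of truth genes made differentially expressed in
#'   the synthetic expression table.
#' @param outdir Optional directory: when given, the dataset files and a
#'   JSON summary of all counts are written there.
#' @return List with every stage's result (`genome`, `panel`,
#'   `annotations`, `cv`, `selections`, `cluster`, `overlap`, `bins`,
#'   `enrichment`, `expression`, `summary`).
#' @export
run_pipeline <- function(config = sim_config(), design = panel_design(),
                         tol_min = 0.8, sens_max = 0.1, k_min = 2L,
                         k_max = NULL, de_fraction = 0.7, outdir = NULL) {
  genome <- generate_genome(config)
  panel <- generate_panel(genome, design, config)
  ann <- annotate_snps(panel$genotypes$loci, genome$models, genome$sequences)
  groups <- group_spec(design)

  cv <- cv_candidates(panel$genotypes, groups, ann)

  selections <- list()
  cl_loci <- character(0)
  for (ch in names(genome$sequences)) {
    bvm <- build_binary_matrix(panel$genotypes, ann, design$reference_line, ch)
    sel <- select_cluster(bvm, groups, tol_min = tol_min, sens_max = sens_max,
                          k_min = k_min, k_max = k_max)
    selections[[ch]] <- sel
    if (sel$found) cl_loci <- c(cl_loci, sel$loci)
  }
  cl <- structure(list(loci = data.frame(
    locus_id = cl_loci,
    gene_id = ann$gene_id[match(cl_loci, ann$locus_id)],
    transcript_id = ann$transcript_id[match(cl_loci, ann$locus_id)],
    stringsAsFactors = FALSE),
    genes = sort(unique(ann$gene_id[match(cl_loci, ann$locus_id)])),
    transcripts = sort(unique(ann$transcript_id[match(cl_loci, ann$locus_id)])),
    method = "cluster"), class = "candidate_set")

  ov <- method_overlap(cv, cl)
  cand_loci <- ov$labels$locus_id
  bin_assign <- if (length(cand_loci) > 0L)
    assign_bins(panel$genotypes$loci[match(cand_loci, panel$genotypes$loci$locus_id),
                                     c("locus_id", "chrom", "pos")],
                genome$bins)
  else NULL

  all_genes <- genome$models$genes$gene_id
  cand_genes <- union(cv$genes, cl$genes)
  go <- generate_go_map(all_genes, panel$truth$gene_id, seed = config$seed + 2L)
  enr <- if (length(cand_genes) > 0L) sea(cand_genes, all_genes, go) else NULL
  expr_tab <- generate_expression_table(all_genes, panel$truth$gene_id,
                                        de_fraction = de_fraction,
                                        seed = config$seed + 3L)
  expr <- if (length(cand_genes) > 0L)
    expression_crosscheck(cand_genes, expr_tab) else NULL

  summary <- list(
    n_loci = nrow(panel$genotypes$loci),
    n_causal = nrow(panel$truth),
    n_nsSNPs = sum(ann$effect == "nonsynonymous"),
    cv_loci = nrow(cv$loci), cv_genes = length(cv$genes),
    cluster_loci = nrow(cl$loci), cluster_genes = length(cl$genes),
    overlap_loci = unname(ov$loci$counts["both"]),
    overlap_genes = unname(ov$genes$counts["both"]),
    union_loci = unname(ov$loci$counts["union"]),
    mode_bin = if (!is.null(bin_assign)) bin_assign$mode_bin else NA_character_,
    mode_bin_percentage = if (!is.null(bin_assign)) bin_assign$per_bin$percentage[1] else NA_real_,
    n_enriched_terms = if (!is.null(enr)) sum(enr$significant) else 0L,
    frac_expression_significant = if (!is.null(expr)) expr$summary$frac_significant else NA_real_
  )

  if (!is.null(outdir)) {
    write_dataset(outdir, genome, panel, design, expression = expr_tab, go = go)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(genome = genome, panel = panel, annotations = ann, cv = cv,
       selections = selections, cluster = cl, overlap = ov,
       bins = bin_assign, enrichment = enr, expression = expr,
       expression_table = expr_tab, summary = summary)
}
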