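#' Genotype matrix for a homozygous inbred panel
#'
#' Inbred lines are fully homozygous, so each call is a single allele:
#' 0 = reference allele, 1 = alternate allele, `NA` = missing.
#'
#' @param loci Data frame: `chrom`, `pos`, `ref`, `alt`, `locus_id`.
#' @param lines Character vector of line names (column order).
#' @param calls Integer matrix loci x lines with values 0/1/`NA`; row names
#'   are locus ids, column names line names.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, lines, calls) {
  loci <- snp_frame(loci)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(loci) || ncol(calls) != length(lines))
    stopf("genotype_matrix: calls must be %d loci x %d lines",
          nrow(loci), length(lines))
  if (anyDuplicated(loci$locus_id))
    stopf("genotype_matrix: duplicated locus ids")
  if (any(!is.na(calls) & !(calls %in% c(0L, 1L))))
    stopf("genotype_matrix: calls must be 0, 1 or NA")
  rownames(calls) <- loci$locus_id
  colnames(calls) <- lines
  structure(list(loci = loci, lines = as.character(lines), calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d lines (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

## TRUE for loci where all tolerant lines share one non-missing call, all
## sensitive lines share one, and the two differ — the planted contrast
is_group_differential <- function(calls, tolerant, sensitive) {
  tl <- calls[, tolerant, drop = FALSE]
  sn <- calls[, sensitive, drop = FALSE]
  t_ok <- rowSums(is.na(tl)) == 0L & apply(tl, 1L, function(r) length(unique(r)) == 1L)
  s_ok <- rowSums(is.na(sn)) == 0L & apply(sn, 1L, function(r) length(unique(r)) == 1L)
  t_ok & s_ok & tl[, 1L] != sn[, 1L]
}

#' Generate the panel genotypes with a planted group-differential signal
#'
#' Places `n_background_snps` neutral SNPs uniformly over the genome, each
#' with a locus-specific alternate-allele frequency drawn from
#' `background_alt_freq`, and `n_causal_nssnps` causal nonsynonymous coding
#' SNPs inside `causal_bin` at which every tolerant line carries the same
#' non-reference allele, every sensitive line (including the reference line)
#' carries the reference allele, and each moderate line carries the
#' non-reference allele independently with `moderate_carrier_prob`.
#' Background loci are re-drawn if they happen to reproduce the exact
#' fixed-different contrast between the two groups, so the planted causal
#' set is, by construction, the complete truth set of group-differential
#' loci. Missing calls are injected at `missing_rate` everywhere except
#' causal-locus calls of tolerant/sensitive lines; genotype noise flips
#' non-missing calls at `noise_rate`.
#'
#' @param genome A [generate_genome()] result.
#' @param design A [panel_design()].
#' @param config The same [sim_config()] used for the genome.
#' @return List: `genotypes` (a [genotype_matrix()]) and `truth` (data frame
#'   of causal loci: `locus_id`, `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `transcript_id`).
#' @export
generate_panel <- function(genome, design, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(design, "panel_design"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lines <- design$lines$line
  n_lines <- length(lines)
  ref_line <- design$reference_line
  tolerant <- lines[design$lines$class == "tolerant"]
  sensitive <- lines[design$lines$class == "sensitive"]
  moderate <- lines[design$lines$class == "moderate"]

  bin <- genome$bins[genome$bins$bin == config$causal_bin, , drop = FALSE]
  if (nrow(bin) != 1L)
    stopf("generate_panel: causal_bin '%s' not found in the bin table",
          config$causal_bin)

  ## candidate coding positions inside the causal bin
  cds <- genome$models$cds
  cds <- cds[cds$chrom == bin$chrom & cds$end >= bin$start & cds$start <= bin$end, ,
             drop = FALSE]
  coding_pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq(max(cds$start[i], bin$start), min(cds$end[i], bin$end))))
  coding_pos <- unique(coding_pos)
  if (length(coding_pos) < 3L * config$n_causal_nssnps)
    stopf("generate_panel: causal bin '%s' holds only %d coding positions; %d causal nsSNPs need more room",
          config$causal_bin, length(coding_pos), config$n_causal_nssnps)
  tx_of_pos <- function(pos) {
    hit <- which(cds$start <= pos & cds$end >= pos)[1]
    cds$tx_id[hit]
  }
  tx2gene <- setNames(genome$models$transcripts$gene_id,
                      genome$models$transcripts$tx_id)

  ## causal loci: re-sample alternate base (and position if needed) until
  ## the codon effect is nonsynonymous
  pool <- sample(coding_pos)
  causal <- list(); pi <- 0L
  sp_cache <- list()
  while (length(causal) < config$n_causal_nssnps) {
    pi <- pi + 1L
    if (pi > length(pool))
      stopf("generate_panel: exhausted coding positions in bin '%s' before placing %d nonsynonymous loci",
            config$causal_bin, config$n_causal_nssnps)
    pos <- pool[pi]
    tx <- tx_of_pos(pos)
    if (is.null(sp_cache[[tx]]))
      sp_cache[[tx]] <- spliced_cds(genome$models, genome$sequences, tx)
    ref <- substring(genome$sequences[[as.character(bin$chrom)]], pos, pos)
    found <- NULL
    for (alt in sample(setdiff(DNA_BASES, ref))) {
      eff <- codon_effect_at(sp_cache[[tx]], pos, ref, alt, sprintf("causal_%d", pos))
      if (eff$effect == "nonsynonymous") { found <- alt; break }
    }
    if (is.null(found)) next
    causal[[length(causal) + 1L]] <-
      data.frame(chrom = as.character(bin$chrom), pos = pos, ref = ref,
                 alt = found, tx_id = tx, stringsAsFactors = FALSE)
  }
  causal <- do.call(rbind, causal)

  ## background loci: uniform over the genome, distinct from causal positions
  chroms <- names(genome$sequences)
  L <- config$chrom_length
  n_bg <- config$n_background_snps
  taken <- paste(causal$chrom, causal$pos)
  bg_chrom <- character(0); bg_pos <- integer(0)
  while (length(bg_pos) < n_bg) {
    need <- n_bg - length(bg_pos)
    ch <- sample(chroms, need, replace = TRUE)
    po <- sample.int(L, need, replace = TRUE)
    key <- paste(ch, po)
    keep <- !(key %in% taken) & !duplicated(key)
    bg_chrom <- c(bg_chrom, ch[keep]); bg_pos <- c(bg_pos, po[keep])
    taken <- c(taken, key[keep])
  }
  bg_ref <- vapply(seq_len(n_bg), function(i)
    substring(genome$sequences[[bg_chrom[i]]], bg_pos[i], bg_pos[i]), character(1))
  bg_alt <- vapply(bg_ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1),
                   USE.NAMES = FALSE)

  ## background carriers: frequency-drawn, never group-differential-fixed
  p <- runif(n_bg, config$background_alt_freq[1], config$background_alt_freq[2])
  draw_calls <- function(idx) {
    m <- matrix(rbinom(length(idx) * n_lines, 1L, rep(p[idx], n_lines)),
                nrow = length(idx), ncol = n_lines)
    colnames(m) <- lines
    m[, ref_line] <- 0L
    m
  }
  bg_calls <- draw_calls(seq_len(n_bg))
  repeat {
    bad <- which(is_group_differential(bg_calls, tolerant, sensitive))
    if (length(bad) == 0L) break
    bg_calls[bad, ] <- draw_calls(bad)
  }

  ## causal carriers: planted contrast
  n_ca <- nrow(causal)
  ca_calls <- matrix(0L, nrow = n_ca, ncol = n_lines, dimnames = list(NULL, lines))
  ca_calls[, tolerant] <- 1L
  if (length(moderate) > 0L)
    ca_calls[, moderate] <- matrix(
      rbinom(n_ca * length(moderate), 1L, config$moderate_carrier_prob),
      nrow = n_ca)

  loci <- rbind(
    data.frame(chrom = bg_chrom, pos = bg_pos, ref = bg_ref, alt = bg_alt,
               causal = FALSE, stringsAsFactors = FALSE),
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt, causal = TRUE, stringsAsFactors = FALSE))
  calls <- rbind(bg_calls, ca_calls)
  ord <- order(match(loci$chrom, chroms), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  loci$locus_id <- sprintf("snp_%s_%d", loci$chrom, loci$pos)

  ## genotype noise, then missingness (causal x tolerant/sensitive protected)
  if (config$noise_rate > 0) {
    flip <- matrix(runif(length(calls)) < config$noise_rate, nrow = nrow(calls))
    ## the reference line's alleles are the assembly itself and define the
    ## 0 code; genotype error does not apply to them
    flip[, lines == ref_line] <- FALSE
    calls[flip] <- 1L - calls[flip]
  }
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < config$missing_rate, nrow = nrow(calls))
    protected <- matrix(FALSE, nrow = nrow(calls), ncol = n_lines,
                        dimnames = list(NULL, lines))
    protected[loci$causal, c(tolerant, sensitive)] <- TRUE
    mask[protected] <- FALSE
    calls[mask] <- NA_integer_
  }

  truth_idx <- which(loci$causal)
  truth <- loci[truth_idx, c("locus_id", "chrom", "pos", "ref", "alt")]
  tx_map <- setNames(causal$tx_id, paste(causal$chrom, causal$pos))
  truth$transcript_id <- unname(tx_map[paste(truth$chrom, truth$pos)])
  truth$gene_id <- unname(tx2gene[truth$transcript_id])
  rownames(truth) <- NULL

  gm <- genotype_matrix(loci[c("chrom", "pos", "ref", "alt", "locus_id")],
                        lines, calls)
  list(genotypes = gm, truth = truth)
}

#' Generate a synthetic differential-expression result table
#'
#' One row per gene and tissue (ovary, leaf, root) with a log2 fold change
#' (stressed vs watered) and an adjusted p value. A `de_fraction` share of
#' the truth genes is made significant (adjusted p < 0.05 and |log2FC| >= 1)
#' in at least one tissue; all other gene/tissue pairs draw log2FC from a
#' null normal with mean 0 and adjusted p uniform on [0.05, 1].
#'
#' @param genes Character vector of all gene ids to cover.
#' @param truth_genes Genes carrying the planted signal.
#' @param de_fraction Share of truth genes made differentially expressed.
#' @param seed Integer seed.
#' @return Data frame: `gene_id`, `tissue`, `log2fc`, `padj`.
#' @export
generate_expression_table <- function(genes, truth_genes, de_fraction = 0.7,
                                      seed = 1L) {
  stopifnot(de_fraction >= 0, de_fraction <= 1)
  set.seed(seed)
  tissues <- c("ovary", "leaf", "root")
  tab <- expand.grid(gene_id = genes, tissue = tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$log2fc <- rnorm(nrow(tab), 0, 0.5)
  tab$padj <- runif(nrow(tab), 0.05, 1)
  truth_genes <- intersect(truth_genes, genes)
  de <- truth_genes[runif(length(truth_genes)) < de_fraction]
  for (g in de) {
    in_tissue <- sample(tissues, sample(1:3, 1L))
    idx <- which(tab$gene_id == g & tab$tissue %in% in_tissue)
    tab$log2fc[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      (1 + abs(rnorm(length(idx), 0, 1.5)))
    tab$padj[idx] <- runif(length(idx), 0, 0.049)
  }
  tab[order(tab$gene_id, tab$tissue), , drop = FALSE] -> tab
  rownames(tab) <- NULL
  tab
}

#' Generate a small GO annotation map with a planted enriched term
#'
#' Builds a toy acyclic ontology (three namespaces, two levels below each
#' root) and assigns 1-4 leaf terms to every gene at random. Truth genes are
#' additionally annotated to one designated stress-response term with high
#' probability, so enrichment analysis has a recoverable signal.
#'
#' @param genes All gene ids (the background).
#' @param truth_genes Genes carrying the planted signal.
#' @param seed Integer seed.
#' @param enriched_term Term id that the truth genes share.
#' @param carrier_prob Probability a truth gene carries `enriched_term`.
#' @return List: `gene2term` (data frame `gene_id`, `term`), `parents`
#'   (data frame `term`, `parent`), `namespace` (data frame `term`,
#'   `namespace`).
#' @export
generate_go_map <- function(genes, truth_genes, seed = 1L,
                            enriched_term = "GO:1000105", carrier_prob = 0.9) {
  set.seed(seed)
  namespaces <- c("biological_process", "cellular_component", "molecular_function")
  parents <- list(); ns <- list(); leaves <- character(0)
  tid <- function(i, j, k) sprintf("GO:%d000%d%02d", i, j, k)
  for (i in seq_along(namespaces)) {
    root <- tid(i, 0, 0)
    ns[[root]] <- namespaces[i]
    for (j in 1:2) {
      mid <- tid(i, 0, j)
      parents[[mid]] <- root; ns[[mid]] <- namespaces[i]
      for (k in 1:4) {
        leaf <- tid(i, 1, (j - 1) * 4 + k)
        parents[[leaf]] <- mid; ns[[leaf]] <- namespaces[i]
        leaves <- c(leaves, leaf)
      }
    }
  }
  g2t <- lapply(genes, function(g)
    data.frame(gene_id = g,
               term = sample(leaves, sample(1:4, 1L)),
               stringsAsFactors = FALSE))
  g2t <- do.call(rbind, g2t)
  truth_genes <- intersect(truth_genes, genes)
  hit <- truth_genes[runif(length(truth_genes)) < carrier_prob]
  if (length(hit) > 0L)
    g2t <- rbind(g2t, data.frame(gene_id = hit, term = enriched_term,
                                 stringsAsFactors = FALSE))
  g2t <- unique(g2t)
  g2t <- g2t[order(g2t$gene_id, g2t$term), , drop = FALSE]
  rownames(g2t) <- NULL
  list(gene2term = g2t,
       parents = data.frame(term = names(parents),
                            parent = unlist(parents, use.names = FALSE),
                            stringsAsFactors = FALSE),
       namespace = data.frame(term = names(ns),
                              namespace = unlist(ns, use.names = FALSE),
                              stringsAsFactors = FALSE))
}
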