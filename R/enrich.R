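## Singular enrichment analysis (SEA): one-sided Fisher's exact test of
## GO-term over-representation with Bonferroni adjustment.

#' True-path closure of a gene-to-term annotation map
#'
#' Extends each gene's term set with all ancestors along the `is_a` parent
#' edges, so a parent term counts every annotation of its descendants.
#' Idempotent; errors on a cyclic parent graph, listing the cycle.
#'
#' @param map List with `gene2term` (data frame `gene_id`, `term`) and
#'   optionally `parents` (data frame `term`, `parent`).
#' @return The map with `gene2term` closed under ancestors.
#' @export
propagate_annotations <- function(map) {
  stopifnot(is.list(map), is.data.frame(map$gene2term))
  parents <- map$parents
  if (is.null(parents) || nrow(parents) == 0L) return(map)
  padj <- split(parents$parent, parents$term)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, path = character(0)) {
    if (term %in% path)
      stopf("propagate_annotations: cycle in ontology: %s",
            paste(c(path[which(path == term):length(path)], term), collapse = " -> "))
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    ps <- padj[[term]]
    out <- if (is.null(ps)) character(0)
           else unique(c(ps, unlist(lapply(ps, ancestors, path = c(path, term)))))
    anc_cache[[term]] <- out
    out
  }
  g2t <- map$gene2term
  closed <- lapply(seq_len(nrow(g2t)), function(i) {
    terms <- c(g2t$term[i], ancestors(g2t$term[i]))
    data.frame(gene_id = g2t$gene_id[i], term = terms, stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, closed))
  out <- out[order(out$gene_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  map$gene2term <- out
  map
}

#' Singular enrichment analysis of a study gene list
#'
#' For every term annotated to at least one study gene, tests
#' over-representation of the term in the study set against the background
#' with a one-sided Fisher's exact test (hypergeometric upper tail), then
#' applies Bonferroni correction over the tested terms.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param map Annotation map (see [propagate_annotations()]).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param propagate Close the map under ancestors first (default TRUE).
#' @return Data frame sorted by p: `term`, `namespace` (when available),
#'   `study_hits`, `study_size`, `background_hits`, `background_size`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
sea <- function(study, background, map, alpha = 0.05, propagate = TRUE) {
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (!all(study %in% background))
    stopf("sea: study genes must be a subset of the background (%d are not)",
          sum(!study %in% background))
  if (propagate) map <- propagate_annotations(map)
  g2t <- map$gene2term
  g2t <- g2t[g2t$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(study)
  bg_hits <- table(unique(g2t)[["term"]])
  st <- g2t[g2t$gene_id %in% study, , drop = FALSE]
  st_hits <- table(unique(st)[["term"]])
  terms <- names(st_hits)  # only terms with >= 1 study hit are tested
  a <- as.integer(st_hits[terms])
  b <- as.integer(bg_hits[terms])
  p <- phyper(a - 1L, b, N - b, n, lower.tail = FALSE)
  m <- length(terms)
  padj <- pmin(1, p * m)
  out <- data.frame(term = terms, study_hits = a, study_size = n,
                    background_hits = b, background_size = N,
                    p_value = p, p_adjusted = padj,
                    significant = padj <= alpha,
                    stringsAsFactors = FALSE)
  if (!is.null(map$namespace))
    out$namespace <- map$namespace$namespace[match(out$term, map$namespace$term)]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
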