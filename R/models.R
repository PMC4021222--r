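#' Gene model container
#'
#' A light container for protein-coding gene models: genes, one or more
#' mRNAs per gene, exons and CDS segments. Coordinates are 1-based inclusive
#' throughout (GFF3 convention); UTRs and introns are derived, not stored.
#'
#' @param genes Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param transcripts Data frame: `tx_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param exons Data frame: `tx_id`, `chrom`, `start`, `end`, `strand`.
#' @param cds Data frame: `tx_id`, `chrom`, `start`, `end`, `strand`.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons, cds) {
  for (d in list(genes, transcripts, exons, cds)) {
    stopifnot(is.data.frame(d), all(c("chrom", "start", "end") %in% names(d)))
    if (any(d$start > d$end)) stopf("gene_models: start > end in a feature")
  }
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stopf("gene_models: transcript with unknown gene_id")
  if (!all(exons$tx_id %in% transcripts$tx_id) ||
      !all(cds$tx_id %in% transcripts$tx_id))
    stopf("gene_models: exon/CDS with unknown tx_id")
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exons, %d CDS segments\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

## CDS segments of one transcript in coding (5'->3') order
cds_in_coding_order <- function(models, tx_id) {
  seg <- models$cds[models$cds$tx_id == tx_id, , drop = FALSE]
  if (nrow(seg) == 0L) stopf("transcript '%s' has no CDS", tx_id)
  strand <- seg$strand[1]
  seg <- seg[order(seg$start, decreasing = (strand == "-")), , drop = FALSE]
  seg
}

## GFF3 phase per CDS segment, in the order of `seg` (coding order)
cds_phases <- function(seg) {
  lens <- seg$end - seg$start + 1L
  before <- c(0L, cumsum(lens)[-length(lens)])
  (3L - (before %% 3L)) %% 3L
}

## derive intron spans per transcript: gaps between sorted exons
derive_introns <- function(models) {
  out <- lapply(unique(models$exons$tx_id), function(tx) {
    ex <- models$exons[models$exons$tx_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(tx_id = tx, chrom = ex$chrom[1],
               start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1] - 1L,
               strand = ex$strand[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tx_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  res[res$start <= res$end, , drop = FALSE]
}

## derive 5'/3' UTR spans per transcript: exon parts outside the CDS span,
## sided by strand
derive_utrs <- function(models) {
  u5 <- list(); u3 <- list()
  for (tx in unique(models$cds$tx_id)) {
    ex <- models$exons[models$exons$tx_id == tx, , drop = FALSE]
    cd <- models$cds[models$cds$tx_id == tx, , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cd) == 0L) next
    strand <- ex$strand[1]
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    left <- ex[ex$start < cds_lo, , drop = FALSE]
    left$end <- pmin(left$end, cds_lo - 1L)
    right <- ex[ex$end > cds_hi, , drop = FALSE]
    right$start <- pmax(right$start, cds_hi + 1L)
    if (strand == "+") {
      u5[[tx]] <- left; u3[[tx]] <- right
    } else {
      u5[[tx]] <- right; u3[[tx]] <- left
    }
  }
  empty <- data.frame(tx_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  list(utr5 = if (length(u5)) do.call(rbind, c(u5, list(make.row.names = FALSE))) else empty,
       utr3 = if (length(u3)) do.call(rbind, c(u3, list(make.row.names = FALSE))) else empty)
}

## promoter spans: promoter_span bases upstream of the transcription start,
## on the transcript's strand, clipped at 1
derive_promoters <- function(models, promoter_span) {
  tx <- models$transcripts
  plus <- tx$strand != "-"
  start <- ifelse(plus, pmax(1L, tx$start - as.integer(promoter_span)), tx$end + 1L)
  end <- ifelse(plus, tx$start - 1L, tx$end + as.integer(promoter_span))
  keep <- start <= end
  data.frame(tx_id = tx$tx_id[keep], gene_id = tx$gene_id[keep],
             chrom = tx$chrom[keep], start = start[keep], end = end[keep],
             strand = tx$strand[keep], stringsAsFactors = FALSE)
}
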