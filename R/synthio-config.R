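#' Simulation configuration for the synthetic panel generator
#'
#' Collects the sizing and noise parameters of the synthetic study: a small
#' genome with protein-coding gene models, a chromosome-bin table, a
#' background of frequency-drawn neutral SNPs and a planted cluster of
#' group-differential nonsynonymous SNPs confined to one bin.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of every chromosome, in bases.
#' @param n_genes_per_chrom Protein-coding genes placed per chromosome
#'   (non-overlapping, spread across the whole chromosome).
#' @param exons_per_gene Integer range `c(min, max)` for the number of exons
#'   per gene.
#' @param n_bins_per_chrom Number of equal-width chromosome bins per
#'   chromosome; bin ids follow the maize convention `"<chrom>.<nn>"`.
#' @param n_background_snps Neutral background SNPs placed uniformly over the
#'   genome.
#' @param n_causal_nssnps Planted causal nonsynonymous SNPs, all inside
#'   `causal_bin`.
#' @param causal_bin Bin id (e.g. `"1.07"`) that receives the causal cluster.
#' @param background_alt_freq Range `c(lo, hi)`; each background locus draws
#'   its non-reference allele frequency uniformly from this range.
#' @param missing_rate Per-call missing probability. Causal-locus calls of
#'   tolerant and sensitive lines are never masked, so the planted contrast
#'   stays observable.
#' @param moderate_carrier_prob Probability that a moderate line carries the
#'   non-reference allele at a causal locus (independent Bernoulli per line
#'   and locus).
#' @param noise_rate Per-call genotype error probability: with this
#'   probability a non-missing call is flipped to the other allele. 0 gives a
#'   noise-free panel.
#' @param seed Integer seed; identical seed + config reproduce the dataset
#'   byte for byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_background_snps = 500, n_causal_nssnps = 10)
#' cfg$causal_bin
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 1e6L,
                       n_genes_per_chrom = 20L,
                       exons_per_gene = c(1L, 5L),
                       n_bins_per_chrom = 10L,
                       n_background_snps = 5000L,
                       n_causal_nssnps = 50L,
                       causal_bin = "1.07",
                       background_alt_freq = c(0.05, 0.5),
                       missing_rate = 0.02,
                       moderate_carrier_prob = 0.5,
                       noise_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    exons_per_gene = as.integer(exons_per_gene),
    n_bins_per_chrom = as.integer(n_bins_per_chrom),
    n_background_snps = as.integer(n_background_snps),
    n_causal_nssnps = as.integer(n_causal_nssnps),
    causal_bin = as.character(causal_bin),
    background_alt_freq = as.numeric(background_alt_freq),
    missing_rate = as.numeric(missing_rate),
    moderate_carrier_prob = as.numeric(moderate_carrier_prob),
    noise_rate = as.numeric(noise_rate),
    seed = as.integer(seed)
  )
  counts <- c("n_chromosomes", "chrom_length", "n_genes_per_chrom",
              "n_bins_per_chrom", "n_background_snps", "n_causal_nssnps")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stopf("sim_config: '%s' must be a single positive count", f)
  }
  if (length(cfg$exons_per_gene) != 2L || any(cfg$exons_per_gene < 1L) ||
      cfg$exons_per_gene[1] > cfg$exons_per_gene[2])
    stopf("sim_config: 'exons_per_gene' must be an increasing range of counts >= 1")
  probs <- c("missing_rate", "moderate_carrier_prob", "noise_rate")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("sim_config: '%s' must lie in [0, 1]", f)
  }
  if (length(cfg$background_alt_freq) != 2L ||
      any(cfg$background_alt_freq < 0) || any(cfg$background_alt_freq > 1) ||
      cfg$background_alt_freq[1] > cfg$background_alt_freq[2])
    stopf("sim_config: 'background_alt_freq' must be a probability range")
  structure(cfg, class = "sim_config")
}

#' Panel design: line names, tolerance classes and the reference line
#'
#' The default design mirrors a 16-line maize panel: three extremely
#' drought-tolerant lines (LX9801, Qi319, Tie7922), three extremely
#' drought-sensitive lines (B73, Ye478, Ji853, with B73 the reference
#' assembly line) and ten lines of moderate tolerance.
#'
#' @param lines Data frame with columns `line` and `class`
#'   (`"tolerant"`, `"sensitive"` or `"moderate"`).
#' @param reference_line Name of the line whose alleles define the reference;
#'   must be a member of `lines` with class `"sensitive"`.
#'
#' @return An object of class `panel_design`.
#' @export
#' @examples
#' d <- panel_design()
#' table(d$lines$class)
panel_design <- function(lines = NULL, reference_line = "B73") {
  if (is.null(lines)) {
    lines <- data.frame(
      line = c("LX9801", "Qi319", "Tie7922",
               "B73", "Ye478", "Ji853",
               "AC7643", "CML206", "Dan598", "Si287", "Han21",
               "Zheng22", "Ji419", "ES40", "X81565", "X178"),
      class = c(rep("tolerant", 3), rep("sensitive", 3), rep("moderate", 10)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(lines), all(c("line", "class") %in% names(lines)))
  if (anyDuplicated(lines$line))
    stopf("panel_design: line names must be unique")
  if (!all(lines$class %in% c("tolerant", "sensitive", "moderate")))
    stopf("panel_design: classes must be tolerant/sensitive/moderate")
  if (sum(lines$class == "tolerant") < 2L || sum(lines$class == "sensitive") < 2L)
    stopf("panel_design: need >= 2 tolerant and >= 2 sensitive lines")
  if (!reference_line %in% lines$line)
    stopf("panel_design: reference line '%s' is not a panel member", reference_line)
  if (lines$class[lines$line == reference_line] != "sensitive")
    stopf("panel_design: reference line must belong to the sensitive class")
  structure(list(lines = lines, reference_line = reference_line),
            class = "panel_design")
}

#' Group specification for the two contrast groups
#'
#' @param design A [panel_design()]; tolerant and sensitive members are taken
#'   from it when `tolerant`/`sensitive` are not given.
#' @param tolerant,sensitive Character vectors of line names.
#' @return Object of class `group_spec` with elements `tolerant`, `sensitive`.
#' @export
group_spec <- function(design = NULL, tolerant = NULL, sensitive = NULL) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "panel_design"))
    tolerant <- tolerant %||% design$lines$line[design$lines$class == "tolerant"]
    sensitive <- sensitive %||% design$lines$line[design$lines$class == "sensitive"]
  }
  if (length(tolerant) == 0L || length(sensitive) == 0L)
    stopf("group_spec: both groups must be non-empty")
  if (length(intersect(tolerant, sensitive)) > 0L)
    stopf("group_spec: groups must be disjoint")
  structure(list(tolerant = as.character(tolerant),
                 sensitive = as.character(sensitive)),
            class = "group_spec")
}
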