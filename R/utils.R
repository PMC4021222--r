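## Small sequence helpers shared by the generator and the annotator.

DNA_BASES <- c("A", "C", "G", "T")

## codon -> amino acid, "*" = stop (standard nuclear code)
CODON_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(CODON_TABLE) <- names(Biostrings::GENETIC_CODE)
SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]
STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## complement of a vector of single bases
comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codons <- function(codons) {
  aa <- CODON_TABLE[codons]
  unname(aa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
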