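# Sequence-level helpers: reverse complement, translation, CDS extraction.
# Standard genetic code only (no selenocysteine / alternative codes).

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' Standard-code translation stopping at the first stop codon.  A trailing
#' incomplete codon is ignored.
#'
#' @param cds Nucleotide string.
#' @return List with `protein` (amino-acid string, no stop symbol) and
#'   `premature_stop` (`TRUE` when a stop codon occurs before the final
#'   complete codon).
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (!length(codons)) return(list(protein = "", premature_stop = FALSE))
  aa <- unname(.codon_table()[codons])
  aa[is.na(aa)] <- "X"   # ambiguous nucleotides
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    first <- stop_at[1L]
    list(protein = paste(aa[seq_len(first - 1L)], collapse = ""),
         premature_stop = first < length(codons))
  } else {
    list(protein = paste(aa, collapse = ""), premature_stop = FALSE)
  }
}

#' Extract CDS and protein for a gene
#'
#' Concatenates exon sequences in transcription order (minus-strand exons are
#' reverse-complemented) and translates with the standard code, stopping at
#' the first stop codon.
#'
#' @param gene A [gene_record()].
#' @param bundle The [genome_bundle()] the gene's coordinates resolve against.
#' @return List with `cds`, `protein`, and `premature_stop`.
#' @export
extract_cds_and_protein <- function(gene, bundle) {
  seq <- bundle$sequences[[gene$locus$chrom]]
  if (is.null(seq)) stop("chromosome ", gene$locus$chrom, " not in bundle")
  chrlen <- nchar(seq)
  parts <- vapply(gene$exons, function(e) {
    if (e$end > chrlen)
      stop("exon of ", gene$gene_id, " extends beyond end of ", e$chrom)
    s <- substr(seq, e$start + 1L, e$end)   # 0-based half-open -> substr
    if (gene$locus$strand == "-") revcomp(s) else s
  }, character(1))
  cds <- paste(parts, collapse = "")
  tr <- translate_cds(cds)
  list(cds = cds, protein = tr$protein, premature_stop = tr$premature_stop)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All 61 sense codons.
sense_codons <- function() {
  tab <- .codon_table()
  names(tab)[tab != "*"]
}
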