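# The packaged gene-inventory fixture: the tubulin catalogue of the
# Camelina sativa DH55 reference genome (NCBI assembly GCA_000633955.1),
# used for desk-scale inventory checks without any download.

#' Read a gene inventory table
#'
#' @param path TSV with columns `name`, `ncbi_gene_id`, `gene_length_bp`,
#'   `exons`, `peptide_length_aa`, `isotype`, `class`, `chromosome`,
#'   `subgenome`, `status`, `family`.  Defaults to the packaged
#'   *C. sativa* tubulin inventory.
#' @return Data frame.
#' @export
read_gene_inventory <- function(path = system.file("extdata",
                                                   "camelina_tubulin_inventory.tsv",
                                                   package = "hexatub")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Per-family gene counts from an inventory
#'
#' @param inv Data frame from [read_gene_inventory()].
#' @return Named integer vector of gene counts per family (functional genes
#'   and pseudogenes included).
#' @export
inventory_counts <- function(inv = read_gene_inventory()) {
  tab <- table(inv$family)
  stats::setNames(as.integer(tab), names(tab))
}
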