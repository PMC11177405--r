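#' Genomic interval
#'
#' Coordinates are 0-based, half-open (`start` inclusive, `end` exclusive),
#' the internal convention throughout the package.  On-disk GFF3 uses 1-based
#' inclusive coordinates; conversion happens only at the I/O boundary.
#'
#' @param chrom Chromosome (or scaffold) identifier.
#' @param start,end Integer base coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Gene record
#'
#' A single gene model: locus, exons (CDS-bearing, transcription order),
#' family/isotype labels and cached coding/protein sequences.  Exons are
#' stored in transcription order: increasing coordinates on the plus strand,
#' decreasing on the minus strand.
#'
#' @param gene_id Stable identifier.
#' @param locus A [genomic_interval()] spanning the gene.
#' @param exons List of [genomic_interval()] in transcription order.
#' @param name Family-style display name (e.g. `"TUA2-A"`), optional.
#' @param family One of `"TUA"`, `"TUB"`, `"TUG"`, `"other"`.
#' @param isotype,cls Optional isotype / class labels.
#' @param subgenome One of `"G1"`, `"G2"`, `"G3"`, `"unplaced"`.
#' @param status `"functional"` or `"pseudogene"`.
#' @param cds,protein Optional cached sequences.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, locus, exons, name = NA_character_,
                        family = "other", isotype = NA_character_,
                        cls = NA_character_, subgenome = "unplaced",
                        status = "functional", cds = NA_character_,
                        protein = NA_character_) {
  stopifnot(inherits(locus, "genomic_interval"), length(exons) >= 1)
  exons <- lapply(exons, function(e) {
    if (!inherits(e, "genomic_interval")) stop("exons must be genomic_interval objects")
    e
  })
  # transcription order: ascending starts on +, descending on -
  starts <- vapply(exons, `[[`, integer(1), "start")
  ends   <- vapply(exons, `[[`, integer(1), "end")
  ord <- if (locus$strand == "+") order(starts) else order(starts, decreasing = TRUE)
  if (!identical(ord, seq_along(exons)))
    stop("exons of ", gene_id, " are not in transcription order")
  # pairwise non-overlap
  g <- order(starts)
  if (length(exons) > 1 && any(starts[g][-1] < ends[g][-length(g)]))
    stop("exons of ", gene_id, " overlap")
  if (any(starts < locus$start) || any(ends > locus$end))
    stop("exon outside gene span for ", gene_id)
  structure(list(gene_id = as.character(gene_id), name = name, family = family,
                 isotype = isotype, cls = cls, subgenome = subgenome,
                 locus = locus, exons = exons, status = status,
                 cds = cds, protein = protein),
            class = "gene_record")
}

gene_length <- function(gene) interval_width(gene$locus)

# 5'-end genomic coordinate of a gene (start on +, end on -); the convention
# used for placing genes on block maps.
gene_five_prime <- function(gene) {
  if (gene$locus$strand == "+") gene$locus$start else gene$locus$end - 1L
}

#' Genome bundle
#'
#' The universe every analysis stage reads: chromosome sequences, gene
#' models, and a chromosome-to-subgenome map.
#'
#' @param sequences Named character vector, chromosome id -> nucleotide string.
#' @param genes Named list of [gene_record()] objects (names = gene ids).
#' @param subgenome_map Named character vector, chromosome id -> `"G1"`,
#'   `"G2"` or `"G3"`.  Chromosomes absent from the map are treated as
#'   unplaced scaffolds.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(sequences, genes, subgenome_map = character()) {
  if (is.null(names(sequences))) stop("sequences must be named by chromosome")
  if (length(genes)) {
    if (is.null(names(genes)))
      names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
    bad <- vapply(genes, function(g) !g$locus$chrom %in% names(sequences), logical(1))
    if (any(bad))
      stop("gene(s) on unknown chromosome: ",
           paste(names(genes)[bad], collapse = ", "))
  }
  structure(list(sequences = sequences, genes = genes,
                 subgenome_map = subgenome_map),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("genome_bundle: %d chromosome(s), %d gene(s), %d mapped to subgenomes\n",
              length(x$sequences), length(x$genes), length(x$subgenome_map)))
  invisible(x)
}

#' Summarize a bundle's genes as a data frame
#'
#' @param bundle A [genome_bundle()].
#' @return A data frame with one row per gene (id, name, family, isotype,
#'   class, subgenome, chrom, start, end, strand, n_exons, status).
#' @export
genes_df <- function(bundle) {
  g <- bundle$genes
  if (!length(g)) return(data.frame(gene_id = character()))
  data.frame(
    gene_id = vapply(g, `[[`, character(1), "gene_id"),
    name = vapply(g, `[[`, character(1), "name"),
    family = vapply(g, `[[`, character(1), "family"),
    isotype = vapply(g, `[[`, character(1), "isotype"),
    cls = vapply(g, `[[`, character(1), "cls"),
    subgenome = vapply(g, function(x) subgenome_of(x, NULL), character(1)),
    chrom = vapply(g, function(x) x$locus$chrom, character(1)),
    start = vapply(g, function(x) x$locus$start, integer(1)),
    end = vapply(g, function(x) x$locus$end, integer(1)),
    strand = vapply(g, function(x) x$locus$strand, character(1)),
    n_exons = vapply(g, function(x) length(x$exons), integer(1)),
    status = vapply(g, `[[`, character(1), "status"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Subgenome of a gene: explicit label unless a bundle map overrides it.
subgenome_of <- function(gene, bundle = NULL) {
  if (!is.null(bundle) && gene$locus$chrom %in% names(bundle$subgenome_map))
    return(unname(bundle$subgenome_map[[gene$locus$chrom]]))
  gene$subgenome
}
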