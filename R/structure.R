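# Exon-intron structure derivation, family structure conformity and
# pseudogene diagnosis.

#' Derive the exon-intron structure of a gene
#'
#' Intron i is the genomic gap between exon i and exon i + 1 in
#' transcription order.
#'
#' @param gene A [gene_record()].
#' @return List with `exon_lengths`, `intron_lengths` and `exon_count`;
#'   `sum(exon_lengths) + sum(intron_lengths)` equals the locus span when the
#'   exons tile the locus.
#' @export
derive_structure <- function(gene) {
  ex <- gene$exons
  if (!length(ex)) stop("gene ", gene$gene_id, " has no exons")
  exon_lengths <- vapply(ex, interval_width, integer(1))
  intron_lengths <- integer(0)
  if (length(ex) > 1) {
    starts <- vapply(ex, `[[`, integer(1), "start")
    ends <- vapply(ex, `[[`, integer(1), "end")
    g <- order(starts)  # genomic order regardless of strand
    if (any(starts[g][-1] < ends[g][-length(g)]))
      stop("overlapping exons in ", gene$gene_id)
    gaps <- starts[g][-1] - ends[g][-length(g)]
    # report introns in transcription order
    intron_lengths <- if (gene$locus$strand == "+") gaps else rev(gaps)
  }
  list(exon_lengths = exon_lengths, intron_lengths = intron_lengths,
       exon_count = length(exon_lengths))
}

#' Check family-typical exon counts
#'
#' Conserved families show class-specific exon counts (here: TUA class I
#' genes have 4 exons, class II 5 exons, TUB genes 3, TUG genes 10).  Every
#' gene is checked against the expectation for its family (and, for TUA,
#' class); deviations are listed as exceptions.
#'
#' @param genes List of [gene_record()]s carrying `family` (and for TUA,
#'   `cls`) labels.
#' @param expectations Named integer vector keyed by `"TUA-I"`, `"TUA-II"`,
#'   `"TUB"`, `"TUG"`.
#' @return Data frame with `gene_id`, `key`, `expected`, `observed`, `pass`;
#'   genes with no family label are skipped with a warning.
#' @export
validate_family_structure <- function(genes,
                                      expectations = c("TUA-I" = 4L, "TUA-II" = 5L,
                                                       TUB = 3L, TUG = 10L)) {
  rows <- list()
  skipped <- character()
  for (g in genes) {
    fam <- g$family
    if (is.na(fam) || fam == "other") { skipped <- c(skipped, g$gene_id); next }
    key <- if (fam == "TUA") paste0("TUA-", g$cls) else fam
    if (!key %in% names(expectations)) { skipped <- c(skipped, g$gene_id); next }
    obs <- length(g$exons)
    exp <- unname(expectations[[key]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, key = key, expected = exp, observed = obs,
      pass = obs == exp, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped gene(s) without usable family label: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) return(data.frame(gene_id = character(), key = character(),
                                       expected = integer(), observed = integer(),
                                       pass = logical()))
  do.call(rbind, rows)
}

#' Diagnose a candidate pseudogene
#'
#' A gene is called a pseudogene when any of three rules fires: a premature
#' stop codon, a frameshift (CDS length not a multiple of 3), or a translated
#' product shorter than `min_len_frac` of the functional reference protein.
#'
#' @param gene A [gene_record()] with `cds` populated (see
#'   [extract_cds_and_protein()]).
#' @param reference_protein Amino-acid string of the functional isotype
#'   representative.
#' @param min_len_frac Minimum tolerated product length as a fraction of the
#'   reference (default 0.6: a 183/450 fragment fails, a 444/450 protein
#'   passes).
#' @return List with `status` (`"functional"` / `"pseudogene"`) and
#'   `reasons` (character vector of triggered rules).
#' @export
diagnose_pseudogene <- function(gene, reference_protein, min_len_frac = 0.6) {
  cds <- gene$cds
  if (is.na(cds) || !nzchar(cds)) stop("empty cds for ", gene$gene_id)
  tr <- translate_cds(cds)
  reasons <- character()
  if (tr$premature_stop) reasons <- c(reasons, "premature_stop")
  if (nchar(cds) %% 3L != 0L) reasons <- c(reasons, "frameshift")
  if (nchar(tr$protein) < min_len_frac * nchar(reference_protein))
    reasons <- c(reasons, "short_product")
  list(status = if (length(reasons)) "pseudogene" else "functional",
       reasons = reasons)
}
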