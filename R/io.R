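# Genome bundle I/O.  On disk: multi-record FASTA (60-column wrap), GFF3
# (gene/mRNA/exon/CDS, 1-based inclusive), subgenome map as 2-column TSV.
# In memory everything is 0-based half-open.

#' Read a genome bundle from FASTA + GFF3 + subgenome table
#'
#' Gene models are built from `gene`/`mRNA`/`CDS` features: the exon model is
#' CDS-bearing (UTRs ignored), so `CDS` features define the exons of each
#' gene.  Only the first mRNA of a gene is used (alternative transcripts are
#' out of scope).
#'
#' @param fasta_path Multi-record FASTA of chromosome sequences.
#' @param gff3_path GFF3 with `gene`, `mRNA` and `CDS` features.
#' @param subgenome_table Path to a two-column TSV (`chrom`, `subgenome`),
#'   or a named character vector, or `NULL` for no map.
#' @return A [genome_bundle()].
#' @export
read_genome_bundle <- function(fasta_path, gff3_path, subgenome_table = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sequences <- stats::setNames(as.character(seqs),
                               sub("\\s.*$", "", names(seqs)))

  gff <- read_gff3(gff3_path)
  unknown <- setdiff(unique(gff$seqid), names(sequences))
  if (length(unknown))
    stop("GFF3 feature(s) reference unknown chromosome(s): ",
         paste(unknown, collapse = ", "))

  sub_map <- character()
  if (!is.null(subgenome_table)) {
    if (is.character(subgenome_table) && is.null(names(subgenome_table)) &&
        length(subgenome_table) == 1L) {
      tab <- utils::read.delim(subgenome_table, header = FALSE,
                               col.names = c("chrom", "subgenome"),
                               stringsAsFactors = FALSE, comment.char = "#")
      sub_map <- stats::setNames(tab$subgenome, tab$chrom)
    } else sub_map <- subgenome_table
  }

  genes_rows <- gff[gff$type == "gene", , drop = FALSE]
  mrna_rows  <- gff[gff$type == "mRNA", , drop = FALSE]
  cds_rows   <- gff[gff$type %in% c("CDS", "exon"), , drop = FALSE]
  # CDS preferred; fall back to exon features for annotations without CDS
  if (any(cds_rows$type == "CDS")) cds_rows <- cds_rows[cds_rows$type == "CDS", ]

  mrna_parent <- stats::setNames(mrna_rows$parent, mrna_rows$id)
  genes <- list()
  for (i in seq_len(nrow(genes_rows))) {
    row <- genes_rows[i, ]
    gid <- row$id
    locus <- genomic_interval(row$seqid, row$start - 1L, row$end, row$strand)
    # exons: CDS children of this gene's mRNAs (or of the gene directly)
    mids <- names(mrna_parent)[mrna_parent == gid]
    keep <- cds_rows$parent %in% c(gid, if (length(mids)) mids[1L])
    ex <- cds_rows[keep, , drop = FALSE]
    if (!nrow(ex)) next
    bad_chrom <- ex$seqid != row$seqid
    if (any(bad_chrom))
      stop("exon feature(s) of ", gid, " on wrong chromosome: ",
           paste(unique(ex$seqid[bad_chrom]), collapse = ", "))
    if (any(ex$start - 1L < locus$start) || any(ex$end > locus$end))
      stop("exon outside gene span for feature ", gid)
    ord <- order(ex$start, decreasing = (row$strand == "-"))
    ex <- ex[ord, , drop = FALSE]
    exons <- lapply(seq_len(nrow(ex)), function(j)
      genomic_interval(ex$seqid[j], ex$start[j] - 1L, ex$end[j], row$strand))
    attrs <- parse_gff_attrs(row$attributes)
    genes[[gid]] <- gene_record(
      gene_id = gid, locus = locus, exons = exons,
      name = attrs[["Name"]] %||% NA_character_,
      family = attrs[["family"]] %||% "other",
      isotype = attrs[["isotype"]] %||% NA_character_,
      cls = attrs[["class"]] %||% NA_character_,
      subgenome = unname(sub_map[row$seqid]) %||% "unplaced",
      status = attrs[["status"]] %||% "functional")
  }
  bundle <- genome_bundle(sequences, genes, sub_map)
  for (gid in names(bundle$genes)) {
    cp <- extract_cds_and_protein(bundle$genes[[gid]], bundle)
    bundle$genes[[gid]]$cds <- cp$cds
    bundle$genes[[gid]]$protein <- cp$protein
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(), strand = character(),
                      attributes = character(), id = character(),
                      parent = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stop("malformed GFF3 line(s): ", which(bad)[1])
  m <- do.call(rbind, f)
  df <- data.frame(seqid = m[, 1], type = m[, 3],
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7], attributes = m[, 9],
                   stringsAsFactors = FALSE)
  df$id <- vapply(df$attributes, function(a)
    parse_gff_attrs(a)[["ID"]] %||% NA_character_, character(1), USE.NAMES = FALSE)
  df$parent <- vapply(df$attributes, function(a)
    parse_gff_attrs(a)[["Parent"]] %||% NA_character_, character(1), USE.NAMES = FALSE)
  df
}

parse_gff_attrs <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else NA_character_)
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Write a genome bundle to FASTA + GFF3 + subgenome TSV
#'
#' Inverse of [read_genome_bundle()]; coordinates are converted to the
#' 1-based inclusive GFF3 dialect so that a read/write cycle round-trips
#' coordinates exactly.
#'
#' @param bundle A [genome_bundle()].
#' @param fasta_path,gff3_path,subgenome_path Output paths (`subgenome_path`
#'   may be `NULL` to skip the map).
#' @return Invisibly, the bundle.
#' @export
write_genome_bundle <- function(bundle, fasta_path, gff3_path,
                                subgenome_path = NULL) {
  seqs <- Biostrings::DNAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)

  lines <- "##gff-version 3"
  for (g in bundle$genes) {
    loc <- g$locus
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$name)) attrs <- paste0(attrs, ";Name=", g$name)
    if (g$family != "other") attrs <- paste0(attrs, ";family=", g$family)
    if (!is.na(g$isotype)) attrs <- paste0(attrs, ";isotype=", g$isotype)
    if (!is.na(g$cls)) attrs <- paste0(attrs, ";class=", g$cls)
    if (g$status != "functional") attrs <- paste0(attrs, ";status=", g$status)
    lines <- c(lines, sprintf("%s\thexatub\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              loc$chrom, loc$start + 1L, loc$end, loc$strand, attrs))
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines, sprintf("%s\thexatub\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              loc$chrom, loc$start + 1L, loc$end, loc$strand,
                              mid, g$gene_id))
    for (k in seq_along(g$exons)) {
      e <- g$exons[[k]]
      lines <- c(lines,
                 sprintf("%s\thexatub\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                         e$chrom, e$start + 1L, e$end, loc$strand, mid, k, mid))
    }
  }
  writeLines(lines, gff3_path)

  if (!is.null(subgenome_path) && length(bundle$subgenome_map)) {
    utils::write.table(
      data.frame(chrom = names(bundle$subgenome_map),
                 subgenome = unname(bundle$subgenome_map)),
      subgenome_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(bundle)
}
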