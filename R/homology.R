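# Cross-referenced homology: genomic-context similarity, relation
# classification (homeolog / tandem / transposed / homeoparalog / ortholog),
# isotype resolution and standardized gene naming.

#' Orthogroups by single-linkage over reciprocal best hits
#'
#' A deliberate simplification of full orthology inference, sufficient for
#' flanking-context comparison: connected components of the RBH graph.
#'
#' @param anchor_tables List of anchor data frames (from [find_anchors()]).
#' @return Named character vector gene_id -> orthogroup id.
#' @export
build_orthogroups <- function(anchor_tables) {
  edges <- do.call(rbind, lapply(anchor_tables, function(a)
    a[, c("gene_a", "gene_b"), drop = FALSE]))
  if (is.null(edges) || !nrow(edges)) return(character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  stats::setNames(paste0("OG", comp), names(comp))
}

#' Genomic-context similarity of two genes
#'
#' Compares the ordered orthogroup profiles of the `window` genes flanking
#' each gene (the focal gene excluded).  `jaccard` is shared / union over
#' orthogroup sets; `order_agreement` is the fraction of shared orthogroups
#' appearing in the same relative order (longest common subsequence of the
#' two ordered shared lists).  At chromosome ends the window shrinks.
#'
#' @param gene_a,gene_b Gene ids.
#' @param ranks A [gene_rank_table()] covering both genes (may span two
#'   bundles, e.g. query genome plus reference genome).
#' @param orthogroups Named vector gene_id -> orthogroup (see
#'   [build_orthogroups()]).
#' @param window Flanking genes on each side (default 10).
#' @return List with `jaccard` and `order_agreement`.
#' @export
context_similarity <- function(gene_a, gene_b, ranks, orthogroups,
                               window = 10L) {
  stopifnot(window > 0)
  fl_a <- flank_profile(gene_a, ranks, orthogroups, window)
  fl_b <- flank_profile(gene_b, ranks, orthogroups, window)
  shared <- intersect(fl_a, fl_b)
  uni <- union(fl_a, fl_b)
  if (!length(uni)) return(list(jaccard = 0, order_agreement = 0))
  j <- length(shared) / length(uni)
  if (!length(shared)) return(list(jaccard = 0, order_agreement = 0))
  sa <- fl_a[fl_a %in% shared]; sb <- fl_b[fl_b %in% shared]
  list(jaccard = j, order_agreement = lcs_length(sa, sb) / length(shared))
}

# Ordered orthogroup ids of the +/- window flanking genes.
flank_profile <- function(gene, ranks, orthogroups, window) {
  if (!gene %in% rownames(ranks)) stop("gene ", gene, " not in rank table")
  chrom <- ranks[gene, "chrom"]; r <- ranks[gene, "rank"]
  here <- ranks[ranks$chrom == chrom, , drop = FALSE]
  fl <- here[here$rank >= r - window & here$rank <= r + window &
             here$gene_id != gene, , drop = FALSE]
  fl <- fl[order(fl$rank), , drop = FALSE]
  og <- orthogroups[fl$gene_id]
  unname(og[!is.na(og)])
}

lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  dp <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    dp[i + 1, j + 1] <- if (a[i] == b[j]) dp[i, j] + 1L
                        else max(dp[i, j + 1], dp[i + 1, j])
  dp[n + 1, m + 1]
}

#' Classify the relation of a gene pair
#'
#' Decision rules applied in order: (1) different subgenomes with chain
#' support and matching block -> homeolog (`disrupted_homeolog` when one
#' member is a pseudogene); (2) same subgenome, same block, within
#' `tandem_max_bp` -> tandem paralog; (3) same subgenome, different block ->
#' transposed paralog; (4) different subgenomes, different isotype lineages
#' -> homeoparalog; (5) cross-species with chain support and block match ->
#' ortholog.  Unresolved pairs fall back to the best context similarity with
#' a low-confidence flag.  Chain support without clade agreement is flagged
#' as a conflict but still classified.
#'
#' @param genes Character vector of 2 gene ids (pair).
#' @param evidence List: `subgenome_a`, `subgenome_b`, `block_a`, `block_b`,
#'   `chain_support`, `clade_agreement`, `context_jaccard`, `distance_bp`
#'   (same-chromosome cases), `status_a`, `status_b`, `isotype_a`,
#'   `isotype_b`, `cross_species` (logical).
#' @param tandem_max_bp Tandem distance cap (default 1e6, enclosing the
#'   sub-megabase tandem cases with margin).
#' @param context_min Minimum context similarity for a low-confidence call.
#' @return List of class `homology_call`: `genes`, `relation`, `evidence`,
#'   `flags`.
#' @export
classify_relation <- function(genes, evidence, tandem_max_bp = 1e6,
                              context_min = 0.3) {
  ev <- evidence
  flags <- character()
  if (isTRUE(ev$chain_support) && identical(ev$clade_agreement, FALSE))
    flags <- c(flags, "conflict")
  same_sg <- !is.null(ev$subgenome_a) && !is.null(ev$subgenome_b) &&
    ev$subgenome_a == ev$subgenome_b
  block_match <- !is.null(ev$block_a) && !is.null(ev$block_b) &&
    !is.na(ev$block_a) && !is.na(ev$block_b) && ev$block_a == ev$block_b
  pseudo <- identical(ev$status_a, "pseudogene") ||
    identical(ev$status_b, "pseudogene")
  iso_differ <- !is.null(ev$isotype_a) && !is.null(ev$isotype_b) &&
    !is.na(ev$isotype_a) && !is.na(ev$isotype_b) && ev$isotype_a != ev$isotype_b
  cross <- isTRUE(ev$cross_species)

  relation <- NULL
  if (!cross && !same_sg && isTRUE(ev$chain_support) && block_match) {
    relation <- if (pseudo) "disrupted_homeolog" else "homeolog"
  } else if (same_sg && block_match && !is.null(ev$distance_bp) &&
             !is.na(ev$distance_bp) && ev$distance_bp <= tandem_max_bp) {
    relation <- "tandem_paralog"
  } else if (same_sg && !block_match) {
    relation <- "transposed_paralog"
  } else if (!cross && !same_sg && iso_differ) {
    relation <- "homeoparalog"
  } else if (cross && isTRUE(ev$chain_support) && block_match) {
    relation <- "ortholog"
  }
  if (is.null(relation)) {
    cj <- ev$context_jaccard %||% 0
    relation <- if (!same_sg || cross) {
      if (cj >= context_min) (if (cross) "ortholog" else "homeolog")
      else "homeoparalog"
    } else "tandem_paralog"
    flags <- c(flags, "low_confidence")
  }
  structure(list(genes = genes, relation = relation, evidence = ev,
                 flags = flags),
            class = "homology_call")
}

#' Resolve the isotype of a gene
#'
#' If the phylogenetic clade uniquely names an isotype, that isotype wins
#' (evidence `"clade"`).  Otherwise the reference isotype whose locus
#' context best matches the gene decides, requiring a block match when block
#' labels are available (evidence `"context"`).  Ties or similarities below
#' `context_min` stay unresolved.
#'
#' @param gene Gene id.
#' @param clade_label Result of [assign_class_by_clade()] against reference
#'   isotype proteins (an isotype name or `"ambiguous"`).
#' @param candidates Character vector of candidate reference isotype names
#'   considered when the clade is ambiguous.
#' @param ref_genes Named vector isotype -> reference gene id.
#' @param ranks,orthogroups Combined rank table and orthogroups spanning
#'   query and reference genomes (see [context_similarity()]).
#' @param gene_block Optional block label of `gene`.
#' @param ref_blocks Optional named vector isotype -> block label.
#' @param context_min Minimum context similarity (default 0.3).
#' @param window Context window (default 10).
#' @return List: `isotype` (or `NA`), `evidence`, `scores`.
#' @export
resolve_isotype <- function(gene, clade_label, candidates, ref_genes,
                            ranks, orthogroups, gene_block = NA,
                            ref_blocks = NULL, context_min = 0.3,
                            window = 10L) {
  if (!is.null(clade_label) && !clade_label %in% c("ambiguous", NA) &&
      clade_label %in% names(ref_genes))
    return(list(isotype = clade_label, evidence = "clade", scores = NULL))
  cand <- sort(intersect(candidates, names(ref_genes)))
  scores <- vapply(cand, function(iso) {
    if (!is.null(ref_blocks) && !is.na(gene_block) &&
        !is.na(ref_blocks[[iso]]) && ref_blocks[[iso]] != gene_block)
      return(-1)
    context_similarity(gene, ref_genes[[iso]], ranks, orthogroups,
                       window)$jaccard
  }, numeric(1))
  if (!length(scores) || max(scores) < context_min)
    return(list(isotype = NA_character_, evidence = "unresolved",
                scores = scores))
  top <- which(scores == max(scores))
  if (length(top) > 1)
    return(list(isotype = NA_character_, evidence = "tie", scores = scores))
  list(isotype = cand[top], evidence = "context", scores = scores)
}

#' Cross-species isotype presence/absence report
#'
#' @param isotype_tables Named list (one per species) of data frames with
#'   columns `isotype` and `status` (`functional`/`pseudogene`).
#' @return List with `matrix` (isotype x species: `present`, `pseudogene`,
#'   `absent`) and `flags` (isotypes absent in exactly one species).
#' @export
detect_missing_orthologs <- function(isotype_tables) {
  stopifnot(length(isotype_tables) >= 2)
  isotypes <- sort(unique(unlist(lapply(isotype_tables, `[[`, "isotype"))))
  m <- matrix("absent", length(isotypes), length(isotype_tables),
              dimnames = list(isotypes, names(isotype_tables)))
  for (sp in names(isotype_tables)) {
    t <- isotype_tables[[sp]]
    for (i in seq_len(nrow(t))) {
      cur <- m[t$isotype[i], sp]
      st <- if (t$status[i] == "functional") "present" else "pseudogene"
      if (cur == "absent" || st == "present") m[t$isotype[i], sp] <- st
    }
  }
  n_absent <- rowSums(m == "absent")
  flags <- data.frame(
    isotype = isotypes[n_absent == 1],
    species = vapply(which(n_absent == 1), function(i)
      colnames(m)[m[i, ] == "absent"], character(1)),
    stringsAsFactors = FALSE)
  list(matrix = m, flags = flags)
}

#' Standardized family gene names
#'
#' Names follow `<prefix><isotype>[p]-<A|B|C|Un>`: a `p` marks pseudogenes,
#' subgenomes G1/G2/G3 map to A/B/C, unplaced genes get `Un`.  Collisions
#' get a numeric suffix with a warning.
#'
#' @param df Data frame with columns `gene_id`, `isotype`, `subgenome`,
#'   `status`.
#' @param prefix Species prefix (default `""`).
#' @return The data frame with a `name` column added.
#' @export
name_genes <- function(df, prefix = "") {
  suffix <- c(G1 = "A", G2 = "B", G3 = "C", unplaced = "Un")
  nm <- sprintf("%s%s%s-%s", prefix, df$isotype,
                ifelse(df$status == "pseudogene", "p", ""),
                suffix[df$subgenome])
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  if (any(dup)) {
    warning("name collision(s): ", paste(unique(nm[dup]), collapse = ", "))
    idx <- stats::ave(seq_along(nm), nm, FUN = seq_along)
    nm[dup] <- paste0(nm[dup], ".", idx[dup])
  }
  df$name <- nm
  df
}
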