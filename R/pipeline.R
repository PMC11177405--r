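# End-to-end orchestration: mine -> anchors/chains -> blocks -> Ka/Ks ->
# relations/naming -> expression, with TSV/JSON artifacts between stages and
# a machine-readable run report.

#' Pipeline configuration
#'
#' @param genome,gff,subgenomes,queries Input paths (FASTA, GFF3, TSV,
#'   reference isotype protein FASTA).
#' @param labeled_anchors Optional TSV of block-labelled syntelog pairs
#'   (`gene_a`, `gene_b`, `block`), the input to block reconstruction.
#' @param expression Optional expression TSV.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the report (stages are deterministic).
#' @param params List of stage parameter overrides (`scan`, `chain`,
#'   `blocks`, `salt`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff, subgenomes, queries,
                            labeled_anchors = NULL, expression = NULL,
                            out_dir = "hexatub_out", seed = 1L,
                            params = list()) {
  structure(list(genome = genome, gff = gff, subgenomes = subgenomes,
                 queries = queries, labeled_anchors = labeled_anchors,
                 expression = expression, out_dir = out_dir,
                 seed = as.integer(seed), params = params),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order: family mining, anchor/chain detection per subgenome pair,
#' block reconstruction (when labelled anchors are supplied), homeolog
#' grouping, Ka/Ks over homeolog groups, relation classification of
#' same-subgenome duplicates, standardized naming, and expression analyses
#' (when a matrix is supplied).  Artifacts are TSV/JSON under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, params = config$params, stages = list())
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    report$stages[[name]] <<- list(...)
  }

  bundle <- read_genome_bundle(config$genome, config$gff, config$subgenomes)
  log_stage("load", n_chroms = length(bundle$sequences),
            n_genes = length(bundle$genes))

  queries <- load_protein_fasta(config$queries)
  mined <- mine_family(bundle, queries)
  utils::write.table(mined, file.path(config$out_dir, "family_members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("mine", n_queries = length(queries), n_members = nrow(mined))
  fam_ids <- mined$target_id

  sgs <- sort(unique(bundle$subgenome_map))
  sub_bundles <- lapply(stats::setNames(sgs, sgs),
                        function(s) subset_bundle(bundle, s))
  pair_results <- list(); anchors_all <- list()
  if (length(sgs) >= 2) {
    prs <- utils::combn(sgs, 2, simplify = FALSE)
    for (pr in prs) {
      key <- paste(pr, collapse = "-")
      a <- find_anchors(sub_bundles[[pr[1]]], sub_bundles[[pr[2]]])
      ch <- chain_collinear(a)
      pair_results[[key]] <- list(anchors = a, chains = ch)
      anchors_all[[key]] <- a
      utils::write.table(a, file.path(config$out_dir,
                                      paste0("anchors_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  log_stage("synteny", n_pairs = length(pair_results),
            n_anchors = sum(vapply(anchors_all, nrow, integer(1))),
            n_chains = sum(vapply(pair_results, function(x)
              length(x$chains), integer(1))))

  block_map <- NULL
  if (!is.null(config$labeled_anchors)) {
    lab <- utils::read.delim(config$labeled_anchors, stringsAsFactors = FALSE)
    block_map <- reconstruct_block_map(bundle, anchors_all, lab,
                                       config$params$blocks %||% list())
    utils::write.table(block_map, file.path(config$out_dir, "block_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("blocks", n_blocks = nrow(block_map))
  }

  ranks <- gene_rank_table(bundle)
  subg <- vapply(bundle$genes, function(g) subgenome_of(g, bundle), character(1))
  # family label of a mined gene = family of its best reference query
  fams <- stats::setNames(substr(mined$query_id, 1, 3), mined$target_id)
  groups <- detect_homeolog_groups(pair_results, fam_ids, ranks, subg, fams)
  log_stage("homeology", triplets = groups$triplets, pairs = groups$pairs,
            singletons = groups$singletons)

  kaks <- list()
  for (grp in groups$groups) {
    if (length(grp) < 2) next
    cmb <- utils::combn(grp, 2)
    for (k in seq_len(ncol(cmb))) {
      res <- kaks_pair(bundle$genes[[cmb[1, k]]]$cds,
                       bundle$genes[[cmb[2, k]]]$cds)
      kaks[[paste(cmb[, k], collapse = "|")]] <- res
    }
  }
  kk_df <- data.frame(pair = names(kaks),
                      ka = vapply(kaks, `[[`, numeric(1), "Ka"),
                      ks = vapply(kaks, `[[`, numeric(1), "Ks"),
                      ratio = vapply(kaks, `[[`, numeric(1), "ratio"),
                      row.names = NULL)
  utils::write.table(kk_df, file.path(config$out_dir, "kaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("kaks", n_pairs = nrow(kk_df),
            max_ka = if (nrow(kk_df)) max(kk_df$ka, na.rm = TRUE) else NA)

  expr_summary <- NULL
  if (!is.null(config$expression)) {
    m <- read_expression(config$expression)
    fam_in <- intersect(fam_ids, rownames(m))
    contrib <- subgenome_contribution(m, subg[fam_in])
    salt <- salt_regulation_calls(m[fam_in, , drop = FALSE],
                                  pairs = attr(m, "salt_pairs"))
    corr <- homeolog_expression_correlation(groups$groups, m)
    utils::write.table(as.data.frame(contrib),
                       file.path(config$out_dir, "contributions.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(salt$calls, file.path(config$out_dir, "salt_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expr_summary <- list(
      mean_contribution = rowMeans(contrib, na.rm = TRUE),
      any_upregulated = salt$summary$any_upregulated,
      shared_pattern_frac = mean(corr$shared_pattern, na.rm = TRUE))
    log_stage("expression", any_upregulated = salt$summary$any_upregulated)
  }

  report$counts <- list(genes = length(bundle$genes),
                        family_members = length(fam_ids),
                        triplets = groups$triplets, pairs = groups$pairs)
  report$expression <- expr_summary
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       na = "null")
  invisible(report)
}

load_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Reconstruct the block map from labelled syntelog pairs
#'
#' Transfers block labels from a labelled pair table onto computed anchors
#' and segments every chromosome with [infer_block_borders()].
#'
#' @param bundle The genome bundle.
#' @param anchors_all List of anchor data frames.
#' @param labeled Data frame `gene_a`, `gene_b`, `block`.
#' @param params Overrides for [infer_block_borders()].
#' @return Combined block annotation data frame.
#' @export
reconstruct_block_map <- function(bundle, anchors_all, labeled,
                                  params = list()) {
  lab_of <- c(stats::setNames(labeled$block, labeled$gene_a),
              stats::setNames(labeled$block, labeled$gene_b))
  rows <- list()
  for (a in anchors_all) {
    if (!nrow(a)) next
    for (side in c("a", "b")) {
      g <- a[[paste0("gene_", side)]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = a[[paste0("chrom_", side)]],
        pos = a[[paste0("pos_", side)]],
        block = unname(lab_of[g]), stringsAsFactors = FALSE)
    }
  }
  pts <- unique(do.call(rbind, rows))
  out <- list()
  for (chrom in sort(unique(pts$chrom))) {
    sub <- pts[pts$chrom == chrom & !is.na(pts$block), , drop = FALSE]
    if (!nrow(sub)) next
    res <- do.call(infer_block_borders,
                   c(list(anchors = sub, chrom = chrom,
                          chrom_len = nchar(bundle$sequences[[chrom]])),
                     params))
    out[[chrom]] <- res$blocks
  }
  do.call(rbind, out)
}
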