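# Expression: TSV ingestion, average-linkage heatmap ordering, subgenome
# contribution percentages, homeolog pattern correlation and salt-stress
# regulation calls.

#' Read an expression matrix
#'
#' First column gene ids, header row of condition labels.  Salt columns are
#' detected from the `<Organ>_ctrl` / `<Organ>_salt` dialect; the remaining
#' columns are developmental tissues.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x conditions) with attributes `tissues`
#'   and `salt_pairs`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene id: ",
                                   df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m))) stop("duplicate condition label")
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value at gene ", rownames(m)[bad[1]], ", condition ",
         colnames(m)[bad[2]])
  }
  if (any(m < 0)) stop("negative expression value")
  ctrl <- grep("_ctrl$", colnames(m), value = TRUE)
  organs <- sub("_ctrl$", "", ctrl)
  stressed <- paste0(organs, "_salt")
  have <- stressed %in% colnames(m)
  attr(m, "tissues") <- setdiff(colnames(m), c(ctrl, stressed[have]))
  attr(m, "salt_pairs") <- data.frame(organ = organs[have],
                                      control = ctrl[have],
                                      stress = stressed[have],
                                      stringsAsFactors = FALSE)
  m
}

#' Write an expression matrix
#' @param m Matrix as returned by [read_expression()].
#' @param path Output TSV.
#' @export
write_expression <- function(m, path) {
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Heatmap row/column order by average-linkage clustering
#'
#' Rows are z-scored (display convention) before Euclidean distances;
#' constant rows z-score to all-zeros (noted).  Leaf order is deterministic:
#' at every merge the smaller cluster comes first (ties by smallest member
#' index).
#'
#' @param m Expression matrix.
#' @param cluster_columns Also order columns (on the z-scored matrix).
#' @return List with `row_order`, `col_order`, `row_merge` (hclust merge
#'   matrix), `col_merge`, `constant_rows`.
#' @export
cluster_heatmap_order <- function(m, cluster_columns = TRUE) {
  if (nrow(m) < 2) stop("need >= 2 rows")
  z <- zscore_rows(m)
  hr <- stats::hclust(stats::dist(z$z, method = "euclidean"),
                      method = "average")
  row_order <- smaller_first_order(hr)
  col_order <- seq_len(ncol(m)); hc <- NULL
  if (cluster_columns && ncol(m) >= 2) {
    hc <- stats::hclust(stats::dist(t(z$z), method = "euclidean"),
                        method = "average")
    col_order <- smaller_first_order(hc)
  }
  list(row_order = rownames(m)[row_order],
       col_order = colnames(m)[col_order],
       row_merge = hr, col_merge = hc, constant_rows = z$constant)
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0
  sd[constant] <- 1
  list(z = (m - mu) / sd, constant = rownames(m)[constant])
}

# Deterministic leaf order: recursive, smaller cluster first; ties broken
# by the lexicographically smallest leaf label so the order is invariant to
# input row permutation.
smaller_first_order <- function(hc) {
  labs <- hc$labels %||% as.character(seq_along(hc$order))
  n_leaves <- function(k) if (k < 0) 1L else counts[k]
  counts <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge)))
    counts[i] <- n_leaves(hc$merge[i, 1]) + n_leaves(hc$merge[i, 2])
  min_leaf <- function(k) if (k < 0) labs[-k] else mins[k]
  mins <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge)))
    mins[i] <- min(min_leaf(hc$merge[i, 1]), min_leaf(hc$merge[i, 2]))
  leaves <- function(k) {
    if (k < 0) return(-k)
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    na <- n_leaves(a); nb <- n_leaves(b)
    first <- if (na < nb || (na == nb && min_leaf(a) <= min_leaf(b))) a else b
    second <- if (identical(first, a)) b else a
    c(leaves(first), leaves(second))
  }
  leaves(nrow(hc$merge))
}

#' Per-subgenome contribution to total expression
#'
#' For each condition, each subgenome's percentage of the summed expression
#' of the included genes.  Default inclusion is functional genes only;
#' specific genes (e.g. members of unclarified origin) can be excluded.
#'
#' @param m Expression matrix.
#' @param subgenomes Named vector gene_id -> `G1`/`G2`/`G3`.
#' @param exclusions Gene ids left out of the analysis.
#' @param conditions Condition subset (default: the matrix's tissue
#'   columns, or all columns).
#' @return Matrix 3 x conditions of percentages (columns sum to 100);
#'   all-zero conditions give `NA` with attribute `flagged`.
#' @export
subgenome_contribution <- function(m, subgenomes, exclusions = character(),
                                   conditions = NULL) {
  if (is.null(conditions))
    conditions <- attr(m, "tissues") %||% colnames(m)
  genes <- setdiff(intersect(rownames(m), names(subgenomes)), exclusions)
  if (!length(genes)) stop("no genes to include")
  sg <- subgenomes[genes]
  if (any(!sg %in% c("G1", "G2", "G3")))
    stop("unmapped subgenome for: ",
         paste(genes[!sg %in% c("G1", "G2", "G3")], collapse = ", "))
  sub <- m[genes, conditions, drop = FALSE]
  out <- matrix(NA_real_, 3, length(conditions),
                dimnames = list(c("G1", "G2", "G3"), conditions))
  flagged <- character()
  for (cond in conditions) {
    tot <- sum(sub[, cond])
    if (tot == 0) { flagged <- c(flagged, cond); next }
    for (s in c("G1", "G2", "G3"))
      out[s, cond] <- 100 * sum(sub[sg == s, cond]) / tot
  }
  attr(out, "flagged") <- flagged
  out
}

#' Salt-stress regulation calls
#'
#' Fold change per organ uses a pseudocount:
#' `FC = (control + pc) / (stress + pc)`; `down` when `FC >= fc_threshold`,
#' `up` when `1/FC >= fc_threshold`, else `unchanged`.
#'
#' @param m Expression matrix with a `salt_pairs` attribute (or supply
#'   `pairs`).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param pseudocount Added to both sides (default 1).
#' @param pairs Optional data frame `organ`, `control`, `stress`.
#' @return List with `calls` (gene, organ, log2fc, label) and `summary`
#'   (per-organ down lists, `any_upregulated`).
#' @export
salt_regulation_calls <- function(m, fc_threshold = 1.5, pseudocount = 1,
                                  pairs = NULL) {
  if (is.null(pairs)) pairs <- attr(m, "salt_pairs")
  if (is.null(pairs) || !nrow(pairs)) stop("no paired control/stress columns")
  missing <- setdiff(c(pairs$control, pairs$stress), colnames(m))
  if (length(missing)) stop("unpaired organ column(s): ",
                            paste(missing, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    fc <- (m[, pairs$control[i]] + pseudocount) /
          (m[, pairs$stress[i]] + pseudocount)
    label <- ifelse(fc >= fc_threshold, "down",
                    ifelse(1 / fc >= fc_threshold, "up", "unchanged"))
    rows[[i]] <- data.frame(gene = rownames(m), organ = pairs$organ[i],
                            log2fc = -log2(fc), label = label,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  calls <- do.call(rbind, rows)
  down <- split(calls$gene[calls$label == "down"],
                calls$organ[calls$label == "down"])
  list(calls = calls,
       summary = list(down_by_organ = down,
                      any_upregulated = any(calls$label == "up")))
}

#' Pairwise expression correlation within homeolog groups
#'
#' Pearson correlation over developmental conditions; a group shares a
#' pattern when its minimum pairwise r reaches `r_min`.
#'
#' @param groups List of gene-id vectors.
#' @param m Expression matrix.
#' @param r_min Shared-pattern threshold (default 0.8).
#' @param conditions Condition subset (default tissue columns).
#' @return Data frame per group: `group`, `n`, `min_r`, `shared_pattern`;
#'   zero-variance members give `NA` r and a flag.
#' @export
homeolog_expression_correlation <- function(groups, m, r_min = 0.8,
                                            conditions = NULL) {
  if (is.null(conditions))
    conditions <- attr(m, "tissues") %||% colnames(m)
  rows <- lapply(seq_along(groups), function(gi) {
    genes <- intersect(groups[[gi]], rownames(m))
    if (length(genes) < 2)
      return(data.frame(group = gi, n = length(genes), min_r = NA_real_,
                        shared_pattern = NA, zero_variance = FALSE))
    sub <- m[genes, conditions, drop = FALSE]
    zv <- apply(sub, 1, stats::sd) == 0
    if (any(zv))
      return(data.frame(group = gi, n = length(genes), min_r = NA_real_,
                        shared_pattern = NA, zero_variance = TRUE))
    cc <- stats::cor(t(sub), method = "pearson")
    min_r <- min(cc[upper.tri(cc)])
    data.frame(group = gi, n = length(genes), min_r = min_r,
               shared_pattern = min_r >= r_min, zero_variance = FALSE)
  })
  do.call(rbind, rows)
}
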