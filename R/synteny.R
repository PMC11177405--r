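# Synteny: reciprocal-best-hit anchors, MCScanX-style collinear chaining,
# homeolog group detection across subgenomes, ancestral-block border
# inference and gene-to-block allocation.

#' Per-chromosome gene order table
#'
#' @param bundle A [genome_bundle()].
#' @return Data frame `gene_id`, `chrom`, `rank` (1-based order of gene
#'   start on its chromosome), `pos` (5'-end coordinate).
#' @export
gene_rank_table <- function(bundle) {
  df <- genes_df(bundle)
  if (!nrow(df)) return(cbind(df, rank = integer(), pos = integer()))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$rank <- stats::ave(df$start, df$chrom, FUN = seq_along)
  df$pos <- ifelse(df$strand == "+", df$start, df$end - 1L)
  rownames(df) <- df$gene_id
  df[, c("gene_id", "chrom", "rank", "pos")]
}

#' Restrict a bundle to one subgenome
#'
#' @param bundle A [genome_bundle()].
#' @param subgenome `"G1"`, `"G2"` or `"G3"`.
#' @return A [genome_bundle()] containing only that subgenome's chromosomes.
#' @export
subset_bundle <- function(bundle, subgenome) {
  chroms <- names(bundle$subgenome_map)[bundle$subgenome_map == subgenome]
  genes <- Filter(function(g) g$locus$chrom %in% chroms, bundle$genes)
  genome_bundle(bundle$sequences[chroms], genes,
                bundle$subgenome_map[chroms])
}

# Cosine similarity between amino-acid 3-mer count profiles.
kmer_cosine <- function(seqs_a, seqs_b, k = 3L) {
  ma <- aa_kmer_matrix(seqs_a, k); mb <- aa_kmer_matrix(seqs_b, k)
  vocab <- union(colnames(ma), colnames(mb))
  pad <- function(m) {
    out <- matrix(0L, nrow(m), length(vocab), dimnames = list(rownames(m), vocab))
    out[, colnames(m)] <- m
    out
  }
  ma <- pad(ma); mb <- pad(mb)
  na <- sqrt(rowSums(ma^2)); nb <- sqrt(rowSums(mb^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  tcrossprod(ma / na, mb / nb)
}

#' Reciprocal-best-hit anchors between two gene sets
#'
#' Best hits use Smith-Waterman scores; a 3-mer cosine prescreen limits
#' alignment to the `top_k` most similar candidates per gene (exact for any
#' realistic divergence; disable by setting `top_k` to the full set size).
#' Self-pairs are excluded when the two bundles share gene ids.
#'
#' @param bundle_a,bundle_b [genome_bundle()]s with proteins populated.
#' @param params A [scan_params()].
#' @param top_k Candidates per gene scored by full alignment (default 3).
#' @return Data frame of anchors: `gene_a`, `gene_b`, chromosome, rank and
#'   5'-position on both sides, `score`.
#' @export
find_anchors <- function(bundle_a, bundle_b, params = scan_params(),
                         top_k = 3L) {
  pa <- vapply(bundle_a$genes, `[[`, character(1), "protein")
  pb <- vapply(bundle_b$genes, `[[`, character(1), "protein")
  pa <- pa[nchar(pa) >= 10]; pb <- pb[nchar(pb) >= 10]
  if (!length(pa) || !length(pb)) return(empty_anchor_df())
  sim <- kmer_cosine(pa, pb)
  same <- intersect(names(pa), names(pb))
  if (length(same)) sim[cbind(match(same, names(pa)), match(same, names(pb)))] <- -Inf
  top_k <- min(top_k, ncol(sim), nrow(sim))
  cand <- matrix(FALSE, nrow(sim), ncol(sim))
  for (i in seq_len(nrow(sim)))
    cand[i, order(sim[i, ], decreasing = TRUE)[seq_len(top_k)]] <- TRUE
  for (j in seq_len(ncol(sim)))
    cand[order(sim[, j], decreasing = TRUE)[seq_len(top_k)], j] <- TRUE
  if (length(same)) cand[cbind(match(same, names(pa)), match(same, names(pb)))] <- FALSE

  score <- matrix(NA_real_, nrow(sim), ncol(sim))
  idx <- which(cand, arr.ind = TRUE)
  m <- .subst_matrix(params$matrix)
  # single vectorized call over all candidate pairs
  if (nrow(idx)) {
    score[idx] <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pa[idx[, 1]]),
      Biostrings::AAStringSet(pb[idx[, 2]]),
      substitutionMatrix = m, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "local", scoreOnly = TRUE)
  }
  ra <- gene_rank_table(bundle_a); rb <- gene_rank_table(bundle_b)
  # best hit per gene, tie-break: higher score, then smaller partner rank
  best_a <- apply(score, 1, function(s)
    if (all(is.na(s))) NA_integer_ else which.max(s))
  best_b <- apply(score, 2, function(s)
    if (all(is.na(s))) NA_integer_ else which.max(s))
  rows <- list()
  for (i in seq_along(best_a)) {
    j <- best_a[i]
    if (is.na(j) || is.na(best_b[j]) || best_b[j] != i) next
    ga <- names(pa)[i]; gb <- names(pb)[j]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb,
      chrom_a = ra[ga, "chrom"], chrom_b = rb[gb, "chrom"],
      rank_a = ra[ga, "rank"], rank_b = rb[gb, "rank"],
      pos_a = ra[ga, "pos"], pos_b = rb[gb, "pos"],
      score = score[i, j], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_anchor_df())
  do.call(rbind, rows)
}

empty_anchor_df <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             chrom_a = character(), chrom_b = character(),
             rank_a = integer(), rank_b = integer(),
             pos_a = integer(), pos_b = integer(), score = numeric())
}

#' Chain anchors into collinear runs
#'
#' Dynamic programming over gene-order rank pairs per chromosome pair: a
#' link is allowed when the rank gap on both sides is in `(0, max_gap]`
#' (strictly increasing on side b for plus chains, strictly decreasing for
#' minus chains).  Maximal-scoring chains are extracted greedily by score;
#' chains below `min_size` anchors are dropped, and each anchor belongs to
#' at most one chain.
#'
#' @param anchors Data frame from [find_anchors()].
#' @param min_size Minimum anchors per chain (default 5).
#' @param max_gap Maximum rank gap between adjacent anchors (default 25).
#' @return List of chains; each has `anchors` (data frame rows), `chrom_a`,
#'   `chrom_b`, `orientation`, `size`, `score`.
#' @export
chain_collinear <- function(anchors, min_size = 5L, max_gap = 25L) {
  chains <- list()
  if (!nrow(anchors)) return(chains)
  key <- paste(anchors$chrom_a, anchors$chrom_b)
  for (k in unique(key)) {
    sub <- anchors[key == k, , drop = FALSE]
    avail <- rep(TRUE, nrow(sub))
    repeat {
      best <- NULL
      for (orient in c("plus", "minus")) {
        ch <- best_chain(sub[avail, , drop = FALSE], orient, max_gap)
        if (!is.null(ch) && (is.null(best) || ch$score > best$score)) best <- ch
      }
      if (is.null(best) || nrow(best$anchors) < min_size) break
      chains[[length(chains) + 1L]] <- list(
        anchors = best$anchors, chrom_a = best$anchors$chrom_a[1],
        chrom_b = best$anchors$chrom_b[1], orientation = best$orientation,
        size = nrow(best$anchors), score = best$score)
      drop <- paste(best$anchors$gene_a, best$anchors$gene_b)
      avail[paste(sub$gene_a, sub$gene_b) %in% drop] <- FALSE
      if (!any(avail)) break
    }
  }
  # deterministic order: by score desc then chromosomes
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, `[[`, character(1), "chrom_a"),
               vapply(chains, `[[`, character(1), "chrom_b"))
  chains[ord]
}

# Single maximal-scoring chain in one orientation (DP, O(n^2)).
best_chain <- function(sub, orientation, max_gap) {
  n <- nrow(sub)
  if (!n) return(NULL)
  ord <- order(sub$rank_a, sub$rank_b)
  sub <- sub[ord, , drop = FALSE]
  dp <- sub$score
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- sub$rank_a[j] - sub$rank_a[i]
      db <- if (orientation == "plus") sub$rank_b[j] - sub$rank_b[i]
            else sub$rank_b[i] - sub$rank_b[j]
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap &&
          dp[i] + sub$score[j] > dp[j]) {
        dp[j] <- dp[i] + sub$score[j]
        prev[j] <- i
      }
    }
  }
  end <- which.max(dp)
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(anchors = sub[path, , drop = FALSE], orientation = orientation,
       score = dp[end])
}

#' Detect homeolog groups across the three subgenomes
#'
#' Family genes connected by chain-supported anchors across subgenomes are
#' merged into groups under the constraint of at most one gene per subgenome
#' per group (conflicting merges resolved by higher anchor score).  Family
#' genes whose reciprocal best hit was ambiguous (for example, twin isotypes
#' with near-identical sequence) are rescued by collinear-position
#' projection: the chain spanning the gene's neighbourhood projects its rank
#' interval onto the partner chromosome, and a unique family gene inside
#' that interval joins the group.
#'
#' @param pair_results Named list, one entry per subgenome pair, each a list
#'   with `anchors` (from [find_anchors()]) and `chains` (from
#'   [chain_collinear()]).
#' @param family_ids Character vector of family gene ids.
#' @param ranks Combined [gene_rank_table()] of the full bundle.
#' @param subgenomes Named vector gene_id -> subgenome.
#' @param families Optional named vector gene_id -> family label; rescue
#'   only pairs genes of the same family.
#' @return List with `groups` (list of gene-id vectors), `triplets`,
#'   `pairs`, `singletons` (counts), and `edges` (the evidence table).
#' @export
detect_homeolog_groups <- function(pair_results, family_ids, ranks,
                                   subgenomes, families = NULL) {
  edges <- list()
  for (pr in pair_results) {
    chained <- chain_anchor_keys(pr$chains)
    a <- pr$anchors
    if (!nrow(a)) next
    in_chain <- paste(a$gene_a, a$gene_b) %in% chained
    fam_edge <- a$gene_a %in% family_ids & a$gene_b %in% family_ids
    keep <- in_chain & fam_edge
    if (any(keep))
      edges[[length(edges) + 1L]] <- data.frame(
        gene_a = a$gene_a[keep], gene_b = a$gene_b[keep],
        score = a$score[keep], support = "chain", stringsAsFactors = FALSE)
    # positional rescue for family genes without a chain-supported edge
    linked <- c(a$gene_a[keep], a$gene_b[keep])
    for (side in c("a", "b")) {
      here <- if (side == "a") unique(a$chrom_a) else unique(a$chrom_b)
      fam_here <- family_ids[ranks[family_ids, "chrom"] %in% here]
      for (g in setdiff(fam_here, linked)) {
        cand <- project_gene(g, pr$chains, ranks, side, family_ids, families)
        if (!is.null(cand))
          edges[[length(edges) + 1L]] <- data.frame(
            gene_a = if (side == "a") g else cand,
            gene_b = if (side == "a") cand else g,
            score = 0, support = "position", stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(gene_a = character(), gene_b = character(), score = numeric(),
               support = character())
  # constrained union-find: best edges first, <= 1 gene per subgenome
  parent <- stats::setNames(family_ids, family_ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  members <- stats::setNames(as.list(family_ids), family_ids)
  ord <- order(-edges$score, edges$gene_a, edges$gene_b)
  conflicts <- 0L
  for (e in ord) {
    ga <- edges$gene_a[e]; gb <- edges$gene_b[e]
    if (!ga %in% family_ids || !gb %in% family_ids) next
    ra <- find(ga); rb <- find(gb)
    if (ra == rb) next
    sgs_a <- subgenomes[members[[ra]]]; sgs_b <- subgenomes[members[[rb]]]
    if (length(intersect(sgs_a, sgs_b))) { conflicts <- conflicts + 1L; next }
    parent[[rb]] <- ra
    members[[ra]] <- c(members[[ra]], members[[rb]])
    members[[rb]] <- NULL
  }
  groups <- unname(members[!vapply(members, is.null, logical(1))])
  sizes <- lengths(groups)
  list(groups = groups,
       triplets = sum(sizes == 3), pairs = sum(sizes == 2),
       singletons = sum(sizes == 1), edges = edges, conflicts = conflicts)
}

chain_anchor_keys <- function(chains) {
  unlist(lapply(chains, function(c) paste(c$anchors$gene_a, c$anchors$gene_b)))
}

# Project gene g through the chain covering its neighbourhood; returns the
# unique same-family gene inside the projected rank interval, or NULL.
project_gene <- function(g, chains, ranks, side, family_ids, families) {
  chrom_g <- ranks[g, "chrom"]; r_g <- ranks[g, "rank"]
  this_chrom <- if (side == "a") "chrom_a" else "chrom_b"
  this_rank <- if (side == "a") "rank_a" else "rank_b"
  other_rank <- if (side == "a") "rank_b" else "rank_a"
  other_gene <- if (side == "a") "gene_b" else "gene_a"
  for (ch in chains) {
    an <- ch$anchors
    if (an[[this_chrom]][1] != chrom_g) next
    lo <- an[an[[this_rank]] < r_g, , drop = FALSE]
    hi <- an[an[[this_rank]] > r_g, , drop = FALSE]
    if (!nrow(lo) || !nrow(hi)) next
    b1 <- lo[[other_rank]][which.max(lo[[this_rank]])]
    b2 <- hi[[other_rank]][which.min(hi[[this_rank]])]
    rng <- sort(c(b1, b2))
    other_chrom <- if (side == "a") an$chrom_b[1] else an$chrom_a[1]
    cand <- family_ids[ranks[family_ids, "chrom"] == other_chrom &
                       ranks[family_ids, "rank"] > rng[1] &
                       ranks[family_ids, "rank"] < rng[2]]
    if (!is.null(families)) cand <- cand[families[cand] == families[[g]]]
    if (length(cand) == 1L) return(cand)
  }
  NULL
}

#' Infer ancestral-block borders from labelled anchors
#'
#' Segments the position-sorted anchor sequence of one chromosome into
#' maximal runs of one block label, tolerating up to `max_interlopers`
#' contiguous foreign anchors inside a run.  The border between adjacent
#' runs is the midpoint of the gap between their terminal anchors (when the
#' gap exceeds `max_gap_bp` the stretch between them stays unassigned).
#' Runs with fewer than `min_run` anchors are flagged as minor fragments.
#'
#' @param anchors Data frame with columns `pos` and `block` (label), sorted
#'   or sortable by position, all on `chrom`.
#' @param chrom Chromosome id.
#' @param min_run Minimum anchors for a full (non-minor) block (default 3).
#' @param max_interlopers Tolerated contiguous foreign anchors (default 2).
#' @param max_gap_bp Gap above which the space between runs is unassigned.
#' @param chrom_len Optional chromosome length for terminal gaps.
#' @return List with `blocks` (data frame `chrom`, `start`, `end`, `block`,
#'   `n_anchors`, `minor_fragment`), `gaps`, and `interlopers` (logged
#'   foreign anchors inside runs).
#' @export
infer_block_borders <- function(anchors, chrom, min_run = 3L,
                                max_interlopers = 2L, max_gap_bp = 5e4,
                                chrom_len = NA_integer_) {
  a <- anchors[!is.na(anchors$block), , drop = FALSE]
  if (nrow(a) < nrow(anchors)) warning("ignoring ", nrow(anchors) - nrow(a),
                                       " unlabelled anchor(s)")
  if (!nrow(a)) return(list(blocks = data.frame(), gaps = data.frame(),
                            interlopers = data.frame()))
  a <- a[order(a$pos), , drop = FALSE]
  runs <- list(); interlopers <- list()
  i <- 1L; n <- nrow(a)
  while (i <= n) {
    lab <- a$block[i]
    last_same <- i; j <- i + 1L; pending <- integer(0)
    while (j <= n) {
      if (a$block[j] == lab) {
        if (length(pending)) interlopers[[length(interlopers) + 1L]] <-
          data.frame(idx = pending, run_label = lab)
        pending <- integer(0); last_same <- j
      } else {
        pending <- c(pending, j)
        if (length(pending) > max_interlopers) break
      }
      j <- j + 1L
    }
    members <- which(seq_len(n) >= i & seq_len(n) <= last_same & a$block == lab)
    runs[[length(runs) + 1L]] <- list(
      label = lab, first = i, last = last_same, n = length(members))
    i <- last_same + 1L
  }
  pad <- 500L
  spac <- diff(a$pos)
  if (length(spac)) pad <- as.integer(max(500, stats::median(spac) / 2))
  blocks <- data.frame(); gaps <- data.frame()
  for (r in seq_along(runs)) {
    ru <- runs[[r]]
    start_pos <- a$pos[ru$first]; end_pos <- a$pos[ru$last]
    # left edge
    if (r == 1L) {
      start <- max(0L, start_pos - pad)
      if (start > 0)
        gaps <- rbind(gaps, data.frame(chrom = chrom, start = 0L, end = start))
    } else {
      g <- start_pos - a$pos[runs[[r - 1L]]$last]
      start <- if (g <= max_gap_bp) (start_pos + a$pos[runs[[r - 1L]]$last]) %/% 2L
               else start_pos - pad
    }
    # right edge
    if (r == length(runs)) {
      end <- end_pos + pad
      if (!is.na(chrom_len)) {
        end <- min(end, chrom_len)
        if (end < chrom_len)
          gaps <- rbind(gaps, data.frame(chrom = chrom, start = end,
                                         end = chrom_len))
      }
    } else {
      g <- a$pos[runs[[r + 1L]]$first] - end_pos
      if (g <= max_gap_bp) end <- (a$pos[runs[[r + 1L]]$first] + end_pos) %/% 2L
      else {
        end <- end_pos + pad
        gaps <- rbind(gaps, data.frame(chrom = chrom, start = end,
                                       end = a$pos[runs[[r + 1L]]$first] - pad))
      }
    }
    blocks <- rbind(blocks, data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      block = ru$label, n_anchors = ru$n,
      minor_fragment = ru$n < min_run, stringsAsFactors = FALSE))
  }
  list(blocks = blocks, gaps = gaps,
       interlopers = if (length(interlopers)) do.call(rbind, interlopers)
                     else data.frame())
}

#' Allocate a gene to an ancestral block
#'
#' Uses the gene's 5'-end coordinate, the convention for placing genes on
#' block maps.
#'
#' @param gene A [gene_record()].
#' @param block_map Data frame of block annotations (`chrom`, `start`,
#'   `end`, `block`).
#' @return The block label, or `"unassigned"` when the 5' end falls in a
#'   gap.
#' @export
assign_gene_to_block <- function(gene, block_map) {
  bm <- block_map[block_map$chrom == gene$locus$chrom, , drop = FALSE]
  if (!nrow(bm)) stop("chromosome ", gene$locus$chrom, " absent from block map")
  p <- gene_five_prime(gene)
  hit <- which(bm$start <= p & p < bm$end)
  if (!length(hit)) return("unassigned")
  bm$block[hit[1]]
}

#' Compare sizes of one block across subgenomes
#'
#' @param block_map Block annotation data frame (`chrom`, `start`, `end`,
#'   `block`).
#' @param block_label Block letter to compare.
#' @param subgenome_map Named chromosome -> subgenome vector.
#' @param ratio_threshold Flag when max/min size ratio exceeds this
#'   (default 1.5).
#' @return List with `table` (subgenome, size_bp), `ratio` and `flagged`.
#' @export
compare_homologous_blocks <- function(block_map, block_label, subgenome_map,
                                      ratio_threshold = 1.5) {
  bm <- block_map[block_map$block == block_label, , drop = FALSE]
  if (!nrow(bm)) stop("block ", block_label, " absent from map")
  bm$subgenome <- unname(subgenome_map[bm$chrom])
  sizes <- tapply(bm$end - bm$start, bm$subgenome, sum)
  tab <- data.frame(subgenome = names(sizes), size_bp = as.numeric(sizes),
                    stringsAsFactors = FALSE)
  ratio <- if (nrow(tab) > 1) max(tab$size_bp) / min(tab$size_bp) else 1
  list(table = tab, ratio = ratio, flagged = ratio > ratio_threshold)
}
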