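# Distance phylogenetics (neighbor joining), protein alignment, codon
# alignment and Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.

#' Pairwise distances from a protein alignment
#'
#' Gap columns are removed pairwise (pairwise deletion).
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @param model `"p_distance"` (mismatch fraction) or `"poisson"`
#'   (`-ln(1 - p)`).
#' @return Symmetric distance matrix; a Poisson distance with `p = 1` is
#'   undefined and reported as `NA` with a warning.
#' @export
protein_distance <- function(alignment, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  if (length(unique(nchar(alignment))) != 1) stop("rows differ in length")
  n <- length(alignment)
  labs <- names(alignment) %||% paste0("s", seq_len(n))
  chars <- lapply(alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "-" & b != "-"
    if (!any(ok)) stop("no comparable sites between ", labs[i], " and ", labs[j])
    p <- sum(a[ok] != b[ok]) / sum(ok)
    v <- if (model == "p_distance") p else {
      if (p >= 1) { warning("p = 1: Poisson distance undefined for ",
                            labs[i], "/", labs[j]); NA_real_ }
      else -log(1 - p)
    }
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion with a deterministic
#' tie-break (lexicographically smallest label pair).  Negative branch
#' estimates are clamped to zero (recorded in the `clamped` attribute).
#' Exactly recovers topology and branch lengths from additive matrices.
#'
#' @param d Symmetric distance matrix with labelled rows, >= 3 taxa.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  sub <- stats::setNames(labs, labs)  # cluster id -> newick fragment
  D <- d; rownames(D) <- colnames(D) <- labs
  clamped <- 0L
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(rownames(D)[ij]), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0 || vj < 0) clamped <- clamped + 1L
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    new_id <- paste0("(", sub[[li]], ":", fmt(vi), ",", sub[[lj]], ":",
                     fmt(vj), ")")
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    nm <- c(rownames(D)[keep], new_id)
    rownames(D2) <- colnames(D2) <- nm
    sub <- c(sub[rownames(D)[keep]], stats::setNames(new_id, new_id))
    D <- D2
  }
  l <- rownames(D)
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (min(v1, v2, v3) < 0) clamped <- clamped + 1L
  nwk <- paste0("(", sub[[l[1]]], ":", fmt(v1), ",", sub[[l[2]]], ":",
                fmt(v2), ",", sub[[l[3]]], ":", fmt(v3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Assign a class (or isotype) label by clade membership
#'
#' Roots the tree (midpoint by default, or on a supplied outgroup), then
#' walks up from the query: the smallest ancestral clade containing at least
#' one reference decides — if all its references share one label, that label
#' is returned, otherwise `"ambiguous"` (deferring to locus-context
#' resolution).
#'
#' @param tree An [ape::phylo] containing `query` and the reference tips.
#' @param ref_labels Named character vector tip -> class label.
#' @param query Query tip label.
#' @param outgroup Optional outgroup tip for rooting.
#' @return The class label or `"ambiguous"`.
#' @export
assign_class_by_clade <- function(tree, ref_labels, query, outgroup = NULL) {
  if (!query %in% tree$tip.label) stop("query ", query, " not in tree")
  rooted <- if (!is.null(outgroup)) ape::root(tree, outgroup, resolve.root = TRUE)
            else phangorn::midpoint(tree)
  qi <- match(query, rooted$tip.label)
  node <- rooted$edge[rooted$edge[, 2] == qi, 1]
  repeat {
    tips <- ape::extract.clade(rooted, node)$tip.label
    refs <- intersect(tips, names(ref_labels))
    refs <- setdiff(refs, query)
    if (length(refs)) {
      labs <- unique(ref_labels[refs])
      return(if (length(labs) == 1) unname(labs) else "ambiguous")
    }
    up <- rooted$edge[rooted$edge[, 2] == node, 1]
    if (!length(up)) return("ambiguous")
    node <- up
  }
}

# ---- protein multiple alignment (progressive, profile-profile NW) --------

#' Global alignment of two proteins
#'
#' Needleman-Wunsch under affine gaps via the Biostrings C implementation.
#'
#' @param a,b Protein strings.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Character vector of the two aligned rows.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_extend = 1) {
  m <- .subst_matrix()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(clean_protein(a)), Biostrings::AAString(clean_protein(b)),
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

#' Progressive multiple alignment of proteins
#'
#' A stand-in for heuristic aligners sufficient for highly conserved
#' families: guide order from average-linkage clustering of 3-mer cosine
#' distances, then profile-profile Needleman-Wunsch merges (linear gap).
#'
#' @param seqs Named character vector of proteins.
#' @param gap Linear gap penalty per residue (default 10).
#' @return Named character vector of aligned rows (equal length).
#' @export
align_proteins <- function(seqs, gap = 10) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  if (n == 1) return(seqs)
  if (n == 2) return(stats::setNames(align_pair(seqs[[1]], seqs[[2]]), names(seqs)))
  sim <- kmer_cosine(seqs, seqs)
  dd <- stats::as.dist(1 - sim)
  hc <- stats::hclust(dd, method = "average")
  profiles <- lapply(seq_len(n), function(i) stats::setNames(seqs[i], names(seqs)[i]))
  merged <- vector("list", nrow(hc$merge))
  get_prof <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    A <- get_prof(hc$merge[s, 1]); B <- get_prof(hc$merge[s, 2])
    merged[[s]] <- profile_align(A, B, gap)
  }
  merged[[nrow(hc$merge)]]
}

# Align two blocks of already-aligned rows with linear-gap NW on
# profile-profile BLOSUM62 scores.
profile_align <- function(A, B, gap = 10) {
  m62 <- .subst_matrix()
  aas <- rownames(m62)
  freq <- function(rows) {
    L <- nchar(rows[1])
    ch <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    f <- matrix(0, length(aas), L, dimnames = list(aas, NULL))
    for (a in aas) f[a, ] <- colMeans(ch == a)
    f
  }
  fa <- freq(A); fb <- freq(B)
  S <- t(fa) %*% m62 %*% fb               # L1 x L2 column score matrix
  L1 <- ncol(fa); L2 <- ncol(fb)
  H <- matrix(-Inf, L1 + 1, L2 + 1)
  H[1, ] <- -gap * (0:L2); H[, 1] <- -gap * (0:L1)
  ptr <- matrix(0L, L1 + 1, L2 + 1)       # 1 diag, 2 up (gap in B), 3 left
  for (i in seq_len(L1)) {
    diag_v <- H[i, 1:L2] + S[i, ]
    up_v <- H[i, 2:(L2 + 1)] - gap
    best <- pmax(diag_v, up_v)
    p <- ifelse(diag_v >= up_v, 1L, 2L)
    # left moves resolved with a running maximum
    row <- numeric(L2 + 1); row[1] <- H[i + 1, 1]
    pr <- integer(L2 + 1)
    for (j in seq_len(L2)) {
      left <- row[j] - gap
      if (best[j] >= left) { row[j + 1] <- best[j]; pr[j + 1] <- p[j] }
      else { row[j + 1] <- left; pr[j + 1] <- 3L }
    }
    H[i + 1, ] <- row; ptr[i + 1, ] <- pr
  }
  # traceback
  i <- L1; j <- L2; path <- list()
  while (i > 0 || j > 0) {
    mv <- if (i == 0) 3L else if (j == 0) 2L else ptr[i + 1, j + 1]
    path[[length(path) + 1L]] <- mv
    if (mv == 1L) { i <- i - 1; j <- j - 1 }
    else if (mv == 2L) i <- i - 1
    else j <- j - 1
  }
  path <- rev(unlist(path))
  splice <- function(rows, take) {
    ch <- strsplit(rows, "", fixed = TRUE)
    out <- lapply(ch, function(v) {
      res <- character(length(path)); k <- 0L
      for (t in seq_along(path)) {
        if (take[t]) { k <- k + 1L; res[t] <- v[k] } else res[t] <- "-"
      }
      paste(res, collapse = "")
    })
    stats::setNames(unlist(out), names(rows))
  }
  c(splice(A, path %in% c(1L, 2L)), splice(B, path %in% c(1L, 3L)))
}

# ---- codon alignment and NG86 -------------------------------------------

#' Thread two CDSs through their protein alignment
#'
#' Codon columns with a gap in either row are dropped; a retained stop codon
#' (other than a shared terminal stop, which is trimmed) is an error.
#'
#' @param cds_a,cds_b Coding sequences (optionally with terminal stop).
#' @param protein_alignment Character vector of the two aligned protein
#'   rows; computed with [align_pair()] when `NULL`.
#' @return List with `codons_a`, `codons_b` (equal-length codon vectors).
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment = NULL) {
  strip <- function(cds) {
    cods <- split_codons(cds)
    if (length(cods) && .codon_table()[cods[length(cods)]] == "*")
      cods <- cods[-length(cods)]
    internal <- which(.codon_table()[cods] == "*")
    if (length(internal))
      stop("internal stop codon at codon ", internal[1])
    cods
  }
  ca <- strip(cds_a); cb <- strip(cds_b)
  pa <- translate_cds(paste(ca, collapse = ""))$protein
  pb <- translate_cds(paste(cb, collapse = ""))$protein
  if (is.null(protein_alignment)) protein_alignment <- align_pair(pa, pb)
  ra <- strsplit(protein_alignment[1], "")[[1]]
  rb <- strsplit(protein_alignment[2], "")[[1]]
  if (paste(ra[ra != "-"], collapse = "") != pa)
    stop("protein alignment row 1 does not match translation of cds_a")
  if (paste(rb[rb != "-"], collapse = "") != pb)
    stop("protein alignment row 2 does not match translation of cds_b")
  ia <- cumsum(ra != "-"); ib <- cumsum(rb != "-")
  keep <- ra != "-" & rb != "-"
  ka <- ca[ia[keep]]; kb <- cb[ib[keep]]
  tab <- .codon_table()
  bad <- which(tab[ka] == "*" | tab[kb] == "*")
  if (length(bad))
    stop("internal stop codon in retained column ", bad[1])
  list(codons_a = ka, codons_b = kb)
}

# Per-codon synonymous site count under the stop-exclusion convention:
# enumerate all 9 single-nucleotide neighbours, drop those creating stops,
# renormalize so S + N = 3 per codon.
.ng86_env <- new.env(parent = emptyenv())

ng86_site_table <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env$sites)
  tab <- .codon_table()
  bases <- c("A", "C", "G", "T")
  out <- stats::setNames(numeric(length(sense_codons())), sense_codons())
  for (cod in sense_codons()) {
    ch <- strsplit(cod, "")[[1]]
    syn <- 0L; valid <- 0L
    for (p in 1:3) for (b in setdiff(bases, ch[p])) {
      nb <- ch; nb[p] <- b
      ncod <- paste(nb, collapse = "")
      if (tab[[ncod]] == "*") next
      valid <- valid + 1L
      if (tab[[ncod]] == tab[[cod]]) syn <- syn + 1L
    }
    out[[cod]] <- if (valid) 3 * syn / valid else 0
  }
  .ng86_env$sites <- out
  out
}

# Fractional synonymous/nonsynonymous differences between two codons:
# average over all orderings of the single-nucleotide steps, excluding
# pathways through stop codons (all pathways used if every one is blocked).
ng86_diff_pair <- function(c1, c2) {
  key <- paste(c1, c2)
  if (is.null(.ng86_env$diffs)) .ng86_env$diffs <- new.env(parent = emptyenv())
  if (exists(key, envir = .ng86_env$diffs, inherits = FALSE))
    return(get(key, envir = .ng86_env$diffs))
  tab <- .codon_table()
  p <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- c(sd = 0, nd = 0)
  if (length(p)) {
    perms <- perms_of(p)
    paths <- list()
    for (ord in perms) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in ord) {
        prev <- paste(cur, collapse = "")
        cur[pos] <- tgt[pos]
        nxt <- paste(cur, collapse = "")
        if (tab[[nxt]] == "*" && nxt != c2) { blocked <- TRUE }
        if (tab[[prev]] == tab[[nxt]] && tab[[nxt]] != "*") sd <- sd + 1
        else nd <- nd + 1
      }
      paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd, blocked = blocked)
    }
    pm <- do.call(rbind, paths)
    use <- pm[pm[, "blocked"] == 0, , drop = FALSE]
    if (!nrow(use)) use <- pm
    res <- c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
  }
  assign(key, res, envir = .ng86_env$diffs)
  res
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Site counts enumerate all nine single-nucleotide neighbours per codon
#' (stop-creating changes excluded, fractions renormalized so sites sum to
#' 3 per codon); multi-difference codons average synonymous/nonsynonymous
#' differences over all orderings of single steps with equal weights
#' (pathways through stops excluded); proportions are Jukes-Cantor
#' corrected, `d = -3/4 ln(1 - 4/3 p)`.
#'
#' @param aln A codon alignment from [codon_align()], or a list with
#'   `codons_a`/`codons_b`.
#' @return Object of class `kaks_result`: `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `ratio`, `flags`.
#' @export
ng86_kaks <- function(aln) {
  ka <- aln$codons_a; kb <- aln$codons_b
  if (!length(ka)) stop("empty codon alignment")
  st <- ng86_site_table()
  S <- (sum(st[ka]) + sum(st[kb])) / 2
  N <- 3 * length(ka) - S
  Sd <- 0; Nd <- 0
  diff <- which(ka != kb)
  for (i in diff) {
    d <- ng86_diff_pair(ka[i], kb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  Ks <- jc(ps); Ka <- jc(pn)
  flags <- character()
  if (is.na(Ks)) flags <- c(flags, "ks_saturated")
  if (is.na(Ka)) flags <- c(flags, "ka_saturated")
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(ratio) && !("ks_saturated" %in% flags))
    flags <- c(flags, "ratio_undefined")
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka, ratio = ratio, flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (S = %.1f, N = %.1f)\n",
              x$Ka, x$Ks, ifelse(is.na(x$ratio), "undef", sprintf("%.3f", x$ratio)),
              x$S_sites, x$N_sites))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: protein alignment, codon threading, NG86.
#'
#' @param cds_a,cds_b Coding sequences.
#' @return A `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b) ng86_kaks(codon_align(cds_a, cds_b))

#' Summarize Ka/Ks across groups
#'
#' @param results Named list of lists of `kaks_result` (one list per group).
#' @param ka_bound,ks_bound Declared bounds; pairs breaching them are
#'   flagged (defaults 0.04 and 0.2, the conserved-family regime).
#' @return Data frame per group: n, mean/max Ka, mean/max Ks, max ratio and
#'   counts of bound exceedances.
#' @export
kaks_summary <- function(results, ka_bound = 0.04, ks_bound = 0.2) {
  rows <- lapply(names(results), function(g) {
    rs <- results[[g]]
    if (!length(rs)) return(data.frame(
      group = g, n = 0L, mean_ka = NA_real_, max_ka = NA_real_,
      mean_ks = NA_real_, max_ks = NA_real_, max_ratio = NA_real_,
      n_ka_exceed = 0L, n_ks_exceed = 0L, stringsAsFactors = FALSE))
    ka <- vapply(rs, `[[`, numeric(1), "Ka")
    ks <- vapply(rs, `[[`, numeric(1), "Ks")
    ratio <- vapply(rs, `[[`, numeric(1), "ratio")
    data.frame(group = g, n = length(rs),
               mean_ka = mean(ka, na.rm = TRUE), max_ka = max(ka, na.rm = TRUE),
               mean_ks = mean(ks, na.rm = TRUE), max_ks = max(ks, na.rm = TRUE),
               max_ratio = if (all(is.na(ratio))) NA_real_ else max(ratio, na.rm = TRUE),
               n_ka_exceed = sum(ka > ka_bound, na.rm = TRUE),
               n_ks_exceed = sum(ks > ks_bound, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
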