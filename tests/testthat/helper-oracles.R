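# Independent oracles, written against the definitions rather than the
# implementation code paths they check.

# Plain-recursion Smith-Waterman with affine gaps (gap of length L costs
# open + L * ext), memoized over three states.  Used only on tiny inputs.
oracle_sw_score <- function(a, b, subst, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (consuming a)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in a (consuming b)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- subst[av[i], bv[j]]
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Exhaustive maximum-score collinear chain: enumerates every subset order
# via depth-first extension.  Feasible for <= 12 anchors.
oracle_best_chain <- function(ra, rb, score, orientation, max_gap) {
  n <- length(ra)
  best <- 0
  extend <- function(last, total) {
    best <<- max(best, total)
    for (nxt in seq_len(n)) {
      if (!is.na(last)) {
        da <- ra[nxt] - ra[last]
        db <- if (orientation == "plus") rb[nxt] - rb[last] else rb[last] - rb[nxt]
        if (da <= 0 || da > max_gap || db <= 0 || db > max_gap) next
      }
      extend(nxt, total + score[nxt])
    }
  }
  extend(NA, 0)
  best
}

# NG86 per-codon synonymous site count, re-derived independently: count
# positions weighted by the synonymous fraction of non-stop single-base
# neighbours, scaled so each codon carries 3 sites.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn <- 0; tot <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (substr(codon, pos, pos) == b) next
      nb <- codon
      substr(nb, pos, pos) <- b
      if (code[[nb]] == "*") next
      tot <- tot + 1
      if (code[[nb]] == code[[codon]]) syn <- syn + 1
    }
  }
  if (tot == 0) 0 else 3 * syn / tot
}

# Random additive (tree-metric) distance matrix plus its generating tree.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = stats::cophenetic(tr))
}
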