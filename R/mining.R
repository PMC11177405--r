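# Family mining: local protein alignment against reference isotype queries,
# Karlin-Altschul E-value thresholding, hit filtering and a conserved-motif
# (PWM) scan confirming family identity.
#
# Alignment is full Smith-Waterman with affine gaps (via Biostrings'
# C implementation); the BLAST word length is kept only as a configuration
# echo.  A k-mer prescreen skips targets that cannot reach the E-value
# threshold; it can be disabled for exhaustive scanning.

#' Scan parameters
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend` (BLAST convention for 11/1).
#' @param evalue_max Reporting threshold (default 1e-5).
#' @param word_len Seed length echo (default 3); alignment itself is exact.
#' @param karlin_lambda,karlin_k Karlin-Altschul constants; defaults are the
#'   published gapped BLOSUM62/11/1 values (lambda 0.267, K 0.041).
#' @param min_coverage,min_hit_len Hit filters (defaults 0.5 and 100 aa).
#' @return List of class `scan_params`.
#' @export
scan_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                        evalue_max = 1e-5, word_len = 3,
                        karlin_lambda = 0.267, karlin_k = 0.041,
                        min_coverage = 0.5, min_hit_len = 100) {
  stopifnot(evalue_max > 0, gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 evalue_max = evalue_max, word_len = word_len,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 min_coverage = min_coverage, min_hit_len = min_hit_len),
            class = "scan_params")
}

# BLOSUM62 with unknown residues scoring 0 against everything.
.subst_matrix <- local({
  cache <- NULL
  function(name = "BLOSUM62") {
    if (name != "BLOSUM62") stop("only BLOSUM62 is available")
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L; m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

clean_protein <- function(p) {
  known <- rownames(.subst_matrix())
  s <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
  bad <- !s %in% known
  if (any(bad)) {
    warning("unknown residue symbol(s) treated as X: ",
            paste(unique(s[bad]), collapse = ""))
    s[bad] <- "X"
  }
  paste(s, collapse = "")
}

#' Optimal local alignment of two proteins
#'
#' Full Smith-Waterman under affine gaps; identity and coverage are computed
#' on the traceback.  Unknown residue symbols are treated as `X` (score 0
#' against anything) with a warning.
#'
#' @param a,b Protein strings (`a` is the query for coverage purposes).
#' @param params A [scan_params()].
#' @return List of class `similarity_hit`: `query_id`, `target_id`,
#'   `raw_score`, `bit_score`, `evalue` (`NA` until set by a database scan),
#'   `identity_frac`, `query_coverage`, `query_span`, `target_span`.
#' @export
smith_waterman <- function(a, b, params = scan_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- clean_protein(a); b <- clean_protein(b)
  m <- .subst_matrix(params$matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = m, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "local")
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(structure(list(query_id = NA, target_id = NA, raw_score = 0,
                          bit_score = 0, evalue = NA_real_, identity_frac = 0,
                          query_coverage = 0, query_span = c(0L, 0L),
                          target_span = c(0L, 0L)),
                     class = "similarity_hit"))
  }
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  va <- strsplit(pa, "")[[1]]; vs <- strsplit(ps, "")[[1]]
  ident <- sum(va == vs & va != "-") / length(va)
  qs <- c(al@pattern@range@start,
          al@pattern@range@start + al@pattern@range@width - 1L)
  ts <- c(al@subject@range@start,
          al@subject@range@start + al@subject@range@width - 1L)
  bit <- (params$karlin_lambda * sc - log(params$karlin_k)) / log(2)
  structure(list(query_id = NA, target_id = NA, raw_score = sc,
                 bit_score = bit, evalue = NA_real_, identity_frac = ident,
                 query_coverage = (qs[2] - qs[1] + 1) / nchar(a),
                 query_span = qs, target_span = ts,
                 align_length = length(va)),
            class = "similarity_hit")
}

# Amino-acid k-mer count matrix (rows = sequences).
aa_kmer_matrix <- function(seqs, k = 5L) {
  all_kmers <- new.env()
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  })
  vocab <- unique(unlist(counts, use.names = FALSE))
  m <- matrix(0L, length(seqs), length(vocab),
              dimnames = list(names(seqs), vocab))
  for (i in seq_along(counts)) {
    t <- table(counts[[i]])
    m[i, names(t)] <- as.integer(t)
  }
  m
}

#' Scan a proteome with reference queries
#'
#' Each target is reported once with its best query; E-values follow
#' `K * m * n * exp(-lambda * S)` with `n` the total database length.
#'
#' @param queries,targets Named character vectors of protein sequences.
#' @param params A [scan_params()].
#' @param prescreen Skip targets sharing fewer than two 5-mers with every
#'   query (such targets cannot approach the default threshold).  Set
#'   `FALSE` for exhaustive scanning.
#' @return Data frame of hits passing `evalue_max`, sorted by E-value:
#'   `query_id`, `target_id`, `raw_score`, `bit_score`, `evalue`,
#'   `identity_frac`, `query_coverage`, `hit_len`.
#' @export
scan_proteome <- function(queries, targets, params = scan_params(),
                          prescreen = TRUE) {
  stopifnot(length(queries) >= 1)
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  db_len <- sum(nchar(targets))
  cand <- rep(TRUE, length(targets))
  qrank <- NULL   # per-target query ranking for the prescreened path
  if (prescreen && length(targets) > 1) {
    km <- function(s, k = 5L) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, 1:(n - k + 1L), k:n))
    }
    # family members retain hundreds of intact 5-mers at any realistic
    # divergence; unrelated proteins share < 1 with the query union by chance
    qkm <- lapply(queries, km)
    tkm <- lapply(targets, km)
    shared <- vapply(tkm, function(tk)
      vapply(qkm, function(qk) sum(tk %in% qk), integer(1)),
      integer(length(queries)))
    shared <- matrix(shared, nrow = length(queries))  # queries x targets
    cand <- apply(shared, 2, max) >= 5L
    qrank <- apply(shared, 2, function(s) order(s, decreasing = TRUE),
                   simplify = FALSE)
  }
  keep_t <- which(cand)
  if (!length(keep_t))
    return(data.frame(query_id = character(), target_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), identity_frac = numeric(),
                      query_coverage = numeric(), hit_len = integer()))
  # vectorized scoring; with the prescreen only the top-3 queries per target
  # (by shared 5-mers) are aligned, which identifies the best query reliably
  grid <- if (is.null(qrank))
    expand.grid(qi = seq_along(queries), ti = keep_t)
  else do.call(rbind, lapply(keep_t, function(ti)
    data.frame(qi = qrank[[ti]][seq_len(min(3L, length(queries)))], ti = ti)))
  m <- .subst_matrix(params$matrix)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(queries[grid$qi])),
    Biostrings::AAStringSet(unname(targets[grid$ti])),
    substitutionMatrix = m, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "local", scoreOnly = TRUE)
  rows <- list()
  for (ti in keep_t) {
    here <- grid$ti == ti
    qi_best <- grid$qi[here][which.max(sc[here])]
    best <- smith_waterman(queries[[qi_best]], targets[[ti]], params)
    best$query_id <- names(queries)[qi_best]
    ev <- params$karlin_k * nchar(queries[[best$query_id]]) * db_len *
      exp(-params$karlin_lambda * best$raw_score)
    if (ev <= params$evalue_max) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = best$query_id, target_id = names(targets)[ti],
        raw_score = best$raw_score, bit_score = best$bit_score, evalue = ev,
        identity_frac = best$identity_frac,
        query_coverage = best$query_coverage,
        hit_len = best$align_length, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(), target_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), identity_frac = numeric(),
                      query_coverage = numeric(), hit_len = integer()))
  out <- do.call(rbind, rows)
  out[order(out$evalue, out$target_id), , drop = FALSE]
}

#' Filter scan hits
#'
#' Keeps hits with `query_coverage >= min_coverage` and aligned length
#' `>= min_hit_len`; the discard log states the triggered reason.
#'
#' @param hits Data frame from [scan_proteome()].
#' @param params A [scan_params()].
#' @return List with `kept` and `discarded` (with a `reason` column).
#' @export
filter_hits <- function(hits, params = scan_params()) {
  if (!nrow(hits)) return(list(kept = hits, discarded = cbind(hits, reason = character())))
  reason <- rep(NA_character_, nrow(hits))
  reason[hits$hit_len < params$min_hit_len] <- "short"
  cov_bad <- hits$query_coverage < params$min_coverage & is.na(reason)
  reason[cov_bad] <- "coverage"
  list(kept = hits[is.na(reason), , drop = FALSE],
       discarded = cbind(hits[!is.na(reason), , drop = FALSE],
                         reason = reason[!is.na(reason)]))
}

#' Build position-weight-matrix motif models from reference proteins
#'
#' Takes `n_motifs` evenly spaced ungapped windows from an alignment of the
#' reference family proteins (the sequences must be equal length or
#' pre-aligned), turns each into a PWM with pseudocounts, and sets the score
#' threshold to a margin below the weakest training sequence, so every
#' training member hits all motifs.
#'
#' @param ref_proteins Character vector of aligned (equal-length) reference
#'   proteins.
#' @param n_motifs,motif_len Number and width of motif windows.
#' @param pseudocount Added to each PWM cell before normalization.
#' @param threshold_frac Score threshold as a fraction of the weakest
#'   training score (default 0.6: diverged family members pass, random
#'   sequences score far below).
#' @return List of motif models (`motif_id`, `pwm`, `length`, `threshold`,
#'   `anchor` = expected position), class `motif_models`.
#' @export
build_motif_models <- function(ref_proteins, n_motifs = 11, motif_len = 15,
                               pseudocount = 0.2, threshold_frac = 0.6) {
  lens <- nchar(ref_proteins)
  L <- min(lens)
  ref <- substr(ref_proteins, 1, L)
  if (L < n_motifs * motif_len)
    stop("reference proteins too short for requested motifs")
  aas <- setdiff(rownames(.subst_matrix()), c("*", "-"))
  starts <- round(seq(1, L - motif_len + 1, length.out = n_motifs))
  models <- lapply(seq_along(starts), function(i) {
    win <- substring(ref, starts[i], starts[i] + motif_len - 1L)
    mat <- matrix(pseudocount, length(aas), motif_len, dimnames = list(aas, NULL))
    for (w in win) {
      chars <- strsplit(w, "")[[1]]
      for (j in seq_len(motif_len))
        if (chars[j] %in% aas) mat[chars[j], j] <- mat[chars[j], j] + 1
    }
    pwm <- sweep(mat, 2, colSums(mat), "/")
    lod <- log2(pwm / (1 / length(aas)))
    train_scores <- vapply(win, function(w) score_motif_window(lod, w), numeric(1))
    list(motif_id = paste0("m", i), pwm = lod, length = motif_len,
         threshold = threshold_frac * min(train_scores), anchor = starts[i])
  })
  class(models) <- "motif_models"
  models
}

score_motif_window <- function(lod, window) {
  chars <- strsplit(window, "")[[1]]
  s <- 0
  for (j in seq_along(chars)) {
    if (chars[j] %in% rownames(lod)) s <- s + lod[chars[j], j]
    else s <- s + min(lod[, j])
  }
  s
}

#' Scan a protein with motif models
#'
#' @param protein Protein string.
#' @param models A `motif_models` object (see [build_motif_models()]).
#' @param min_motifs Minimum motifs that must hit, in order-consistent
#'   positions, for `is_family_like` (default 8).
#' @return List with `hits` (data frame motif_id/position/score) and
#'   `is_family_like`.
#' @export
motif_scan <- function(protein, models, min_motifs = 8) {
  L <- nchar(protein)
  shortest <- min(vapply(models, `[[`, numeric(1), "length"))
  if (L < shortest) {
    warning("protein shorter than shortest motif")
    return(list(hits = data.frame(), is_family_like = FALSE))
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  rows <- list()
  for (mo in models) {
    w <- mo$length
    if (L < w) next
    aas <- rownames(mo$pwm)
    ridx <- match(chars, aas)
    colmin <- apply(mo$pwm, 2, min)
    nw <- L - w + 1L
    # score all windows at once via matrix lookup
    pos <- outer(seq_len(nw) - 1L, seq_len(w), "+")   # nw x w residue index
    val <- matrix(mo$pwm[cbind(as.vector(ridx[pos]),
                               rep(seq_len(w), each = nw))], nw, w)
    unk <- matrix(is.na(ridx[pos]), nw, w)
    if (any(unk)) val[unk] <- matrix(rep(colmin, each = nw), nw, w)[unk]
    scores <- rowSums(val)
    best <- which.max(scores)
    if (scores[best] >= mo$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = mo$motif_id, position = best, score = scores[best],
        anchor = mo$anchor, stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame()
  ok <- FALSE
  if (nrow(hits) >= min_motifs) {
    # order consistency: motif positions must increase with anchor order
    hits <- hits[order(hits$anchor), , drop = FALSE]
    inc <- c(TRUE, diff(hits$position) > 0)
    ok <- sum(inc) >= min_motifs
  }
  list(hits = hits, is_family_like = ok)
}

#' Mine family members from a bundle's proteome
#'
#' Runs the reference queries against every annotated protein, applies the
#' length/coverage filters and the conserved-motif confirmation.
#'
#' @param bundle A [genome_bundle()].
#' @param queries Named character vector of reference isotype proteins.
#' @param params A [scan_params()].
#' @param models Optional: a single `motif_models` object applied to every
#'   hit, or a named list of `motif_models` keyed by query id.  By default
#'   each query trains its own model set, and a hit is confirmed against the
#'   models of its best query.
#' @param min_motifs Passed to [motif_scan()].
#' @return Data frame of confirmed family members (hit columns plus
#'   `n_motifs`), one row per gene.
#' @export
mine_family <- function(bundle, queries, params = scan_params(),
                        models = NULL, min_motifs = 8) {
  prots <- vapply(bundle$genes, `[[`, character(1), "protein")
  prots <- prots[nchar(prots) > 0]
  hits <- scan_proteome(queries, prots, params)
  flt <- filter_hits(hits, params)
  if (is.null(models))
    models <- lapply(queries, build_motif_models)
  kept <- flt$kept
  if (!nrow(kept)) return(cbind(kept, n_motifs = integer()))
  pick_models <- function(qid) {
    if (inherits(models, "motif_models")) models else models[[qid]]
  }
  scan <- lapply(seq_len(nrow(kept)), function(i)
    motif_scan(prots[[kept$target_id[i]]], pick_models(kept$query_id[i]),
               min_motifs))
  fam <- vapply(scan, `[[`, logical(1), "is_family_like")
  nm <- vapply(scan, function(x) nrow(x$hits), integer(1))
  out <- cbind(kept, n_motifs = nm)
  out[fam, , drop = FALSE]
}
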