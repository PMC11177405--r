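# Synthetic allohexaploid generator with full ground truth.
#
# The generator states a small but complete world: three diverged subgenomes
# carrying block-structured chromosomes, a multi-isotype gene family with
# class-specific exon counts, post-polyploidy events (gene loss,
# pseudogenization, tandem and transposed duplication), codon evolution at a
# controlled Ka/Ks, and tissue expression with subgenome bias plus
# salt-stress down-regulation.  All randomness flows from a single seed.

#' Default family specification
#'
#' A tubulin-like family: six alpha isotypes split over classes I (4 exons)
#' and II (5 exons), ten beta isotypes (3 exons), two gamma isotypes
#' (10 exons).  `TUA5` is generated as an identical-sequence twin of `TUA3`
#' (a recent local duplicate), mirroring isotype pairs that encode
#' near-identical proteins and can only be told apart by locus context.
#'
#' @return Data frame with columns `family`, `cls`, `isotype`, `exon_count`,
#'   `codon_length`, `twin_of`.
#' @export
default_family_spec <- function() {
  data.frame(
    family = c(rep("TUA", 6), rep("TUB", 10), rep("TUG", 2)),
    cls = c("I", "I", "I", "II", "II", "II",
            "I", "II", "II", "II", "II", "III", "III", "III-like", "IV", "IV",
            "1", "2"),
    isotype = c("TUA2", "TUA4", "TUA6", "TUA1", "TUA3", "TUA5",
                "TUB6", "TUB2", "TUB3", "TUB7", "TUB8", "TUB4", "TUB9",
                "TUB10", "TUB1", "TUB5", "TUG1", "TUG2"),
    exon_count = c(rep(4L, 3), rep(5L, 3), rep(3L, 10), rep(10L, 2)),
    codon_length = c(rep(450L, 6), rep(449L, 10), rep(474L, 2)),
    twin_of = c(NA, NA, NA, NA, NA, "TUA3",
                NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed Master seed; every downstream random draw derives from it.
#' @param n_ancestral_chroms,blocks_per_chrom,genes_per_block Ancestral
#'   karyotype dimensions (defaults 3 x 3 x 30).
#' @param family_spec See [default_family_spec()].
#' @param divergence Named expected substitutions/site per subgenome
#'   (defaults G1 = 0.06, G2 = 0.08, G3 = 0.04).
#' @param omega Target Ka/Ks of the coding mutation process (default 0.05,
#'   the strong-purifying regime of conserved structural genes).
#' @param event_rates Per family gene per subgenome probabilities of
#'   `loss`, `pseudogenize`, `tandem_dup`, `transpose`
#'   (defaults 0.02, 0.05, 0.01, 0.01).
#' @param expression List: `meanlog`, `sdlog` of the per-isotype lognormal
#'   tissue profile, `noise_sd` (per-gene lognormal noise, log scale),
#'   `bias` (named per-subgenome multipliers), `salt_fc` (fold-change applied
#'   to designated isotypes under stress, default 2), `salt_down_isotypes`.
#' @param filler_codons Protein length of non-family filler genes.
#' @param tandem_max_bp Cap on tandem-duplication distance (default 5e5).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_ancestral_chroms = 3L,
                              blocks_per_chrom = 3L,
                              genes_per_block = 30L,
                              family_spec = default_family_spec(),
                              divergence = c(G1 = 0.06, G2 = 0.08, G3 = 0.04),
                              omega = 0.05,
                              event_rates = c(loss = 0.02, pseudogenize = 0.05,
                                              tandem_dup = 0.01, transpose = 0.01),
                              expression = list(meanlog = log(50), sdlog = 0.6,
                                                noise_sd = 0.1,
                                                bias = c(G1 = 1.15, G2 = 1.2, G3 = 0.8),
                                                salt_fc = 2,
                                                salt_down_isotypes = c("TUB1", "TUB7")),
                              filler_codons = 300L,
                              tandem_max_bp = 5e5) {
  stopifnot(all(event_rates >= 0 & event_rates <= 1), all(divergence > 0),
            omega > 0, all(family_spec$exon_count >= 1))
  cfg <- list(seed = as.integer(seed), n_ancestral_chroms = n_ancestral_chroms,
              blocks_per_chrom = blocks_per_chrom,
              genes_per_block = genes_per_block, family_spec = family_spec,
              divergence = divergence, omega = omega, event_rates = event_rates,
              expression = expression, filler_codons = filler_codons,
              tandem_max_bp = tandem_max_bp)
  class(cfg) <- "simulation_config"
  cfg
}

random_sense_codons <- function(n) {
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

# Random CDS: start codon, n - 1 sense codons, stop.  Protein length n.
random_cds <- function(n_codons) {
  paste0("ATG", random_sense_codons(n_codons - 1L), "TAA")
}

#' Simulate the ancestral genome
#'
#' Builds chromosomes as sequences of labelled blocks (letters `A`, `B`, ...
#' assigned in order across the genome) of filler genes, with family genes
#' placed at deterministic slots (two evenly spaced slots per block, filled
#' round-robin).
#'
#' @param config A [simulation_config()].
#' @return List with `bundle` (chromosomes `AK1`, `AK2`, ...), `block_map`
#'   (true block intervals), and `family` (data frame of family gene truth).
#' @export
simulate_ancestor <- function(config) {
  set.seed(config$seed)
  fam <- config$family_spec
  n_blocks <- config$n_ancestral_chroms * config$blocks_per_chrom
  if (nrow(fam) > 2L * n_blocks)
    stop("family_spec larger than available family slots (2 per block)")
  # deterministic slot assignment: round-robin over blocks, slots at 1/3, 2/3
  slot_pos <- pmax(2L, round(config$genes_per_block * c(1 / 3, 2 / 3)))
  fam$block_idx <- ((seq_len(nrow(fam)) - 1L) %% n_blocks) + 1L
  fam$slot <- slot_pos[((seq_len(nrow(fam)) - 1L) %/% n_blocks) + 1L]

  sequences <- character(); genes <- list()
  block_rows <- list(); fam_rows <- list()
  block_global <- 0L
  # pre-generate family CDSs so twins can share sequence
  fam_cds <- list()
  for (i in seq_len(nrow(fam))) {
    tw <- fam$twin_of[i]
    fam_cds[[fam$isotype[i]]] <-
      if (!is.na(tw)) fam_cds[[tw]] else random_cds(fam$codon_length[i])
  }

  for (k in seq_len(config$n_ancestral_chroms)) {
    chrom <- paste0("AK", k)
    parts <- character(); pos <- 0L
    for (b in seq_len(config$blocks_per_chrom)) {
      block_global <- block_global + 1L
      letter <- LETTERS[block_global]
      block_start <- pos
      for (j in seq_len(config$genes_per_block)) {
        ig <- random_dna(sample(500:1100, 1L))
        parts <- c(parts, ig); pos <- pos + nchar(ig)
        fi <- which(fam$block_idx == block_global & fam$slot == j)
        if (length(fi)) {
          fi <- fi[1L]
          gid <- paste0("anc_", fam$isotype[fi])
          cds <- fam_cds[[fam$isotype[fi]]]
          g <- build_gene(gid, chrom, pos, cds, fam$exon_count[fi],
                          strand = sample(c("+", "-"), 1L),
                          family = fam$family[fi], isotype = fam$isotype[fi],
                          cls = fam$cls[fi])
          fam_rows[[length(fam_rows) + 1L]] <- data.frame(
            gene_id = gid, family = fam$family[fi], isotype = fam$isotype[fi],
            cls = fam$cls[fi], block = letter, chrom = chrom,
            stringsAsFactors = FALSE)
        } else {
          gid <- sprintf("anc_%s_%s_%02d", chrom, letter, j)
          g <- build_gene(gid, chrom, pos, random_cds(config$filler_codons), 1L,
                          strand = sample(c("+", "-"), 1L))
        }
        parts <- c(parts, attr(g, "gseq")); pos <- pos + nchar(attr(g, "gseq"))
        attr(g, "gseq") <- NULL
        genes[[gid]] <- g
      }
      tail_ig <- random_dna(sample(500:1100, 1L))
      parts <- c(parts, tail_ig); pos <- pos + nchar(tail_ig)
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        chrom = chrom, start = block_start, end = pos, block = letter,
        ak_chrom = chrom, stringsAsFactors = FALSE)
    }
    sequences[[chrom]] <- paste(parts, collapse = "")
  }
  bundle <- genome_bundle(sequences, genes)
  for (gid in names(bundle$genes)) {
    cp <- extract_cds_and_protein(bundle$genes[[gid]], bundle)
    bundle$genes[[gid]]$cds <- cp$cds
    bundle$genes[[gid]]$protein <- cp$protein
  }
  list(bundle = bundle, block_map = do.call(rbind, block_rows),
       family = do.call(rbind, fam_rows))
}

# Construct a gene at chromosome offset `at` from a CDS split into
# `exon_count` exons with random intron lengths.  Returns the gene_record
# with the genomic sequence of the locus attached as attribute "gseq".
build_gene <- function(gene_id, chrom, at, cds, exon_count, strand = "+",
                       family = "other", isotype = NA_character_,
                       cls = NA_character_) {
  L <- nchar(cds)
  if (exon_count > 1L) {
    # cut points keeping every exon >= 30 bp
    cuts <- sort(sample(seq(30L, L - 30L), exon_count - 1L))
    while (any(diff(c(0L, cuts, L)) < 30L))
      cuts <- sort(sample(seq(30L, L - 30L), exon_count - 1L))
  } else cuts <- integer(0)
  exon_len <- diff(c(0L, cuts, L))
  intron_len <- if (exon_count > 1L) sample(80:300, exon_count - 1L, replace = TRUE)
                else integer(0)
  # forward-orientation gene sequence and relative exon offsets
  off <- 0L; rel <- matrix(0L, exon_count, 2); gparts <- character()
  cpos <- 0L
  for (i in seq_len(exon_count)) {
    rel[i, ] <- c(off, off + exon_len[i])
    gparts <- c(gparts, substr(cds, cpos + 1L, cpos + exon_len[i]))
    cpos <- cpos + exon_len[i]; off <- off + exon_len[i]
    if (i < exon_count) {
      gparts <- c(gparts, random_dna(intron_len[i])); off <- off + intron_len[i]
    }
  }
  gseq <- paste(gparts, collapse = "")
  glen <- nchar(gseq)
  if (strand == "-") {
    gseq <- revcomp(gseq)
    rel <- cbind(glen - rel[, 2], glen - rel[, 1])
  }
  exons <- lapply(seq_len(exon_count), function(i)
    genomic_interval(chrom, at + rel[i, 1], at + rel[i, 2], strand))
  g <- gene_record(gene_id, genomic_interval(chrom, at, at + glen, strand),
                   exons, name = isotype, family = family, isotype = isotype,
                   cls = cls)
  attr(g, "gseq") <- gseq
  g
}

# Codon-acceptance mutation process: propose single-nucleotide changes at
# rate t per site; accept synonymous proposals, accept nonsynonymous with
# probability omega, reject proposals creating stop codons.  First (start)
# and last (stop) codons are held fixed.
mutate_cds <- function(cds, t, omega) {
  s <- strsplit(cds, "", fixed = TRUE)[[1]]
  L <- length(s)
  n_prop <- stats::rpois(1L, t * L)
  if (n_prop == 0L) return(cds)
  tab <- .codon_table()
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(L, n_prop, replace = TRUE)
  acc_u <- stats::runif(n_prop)
  n_cod <- L %/% 3L
  for (i in seq_len(n_prop)) {
    p <- pos[i]
    ci <- (p - 1L) %/% 3L + 1L
    if (ci <= 1L || ci >= n_cod) next        # conserve start/stop codons
    new_base <- sample(bases[bases != s[p]], 1L)
    cstart <- 3L * ci - 2L
    old_cod <- paste(s[cstart:(cstart + 2L)], collapse = "")
    new_s <- s[cstart:(cstart + 2L)]; new_s[p - cstart + 1L] <- new_base
    new_cod <- paste(new_s, collapse = "")
    aa_old <- tab[[old_cod]]; aa_new <- tab[[new_cod]]
    if (is.na(aa_new) || aa_new == "*") next  # reject stops
    if (aa_old == aa_new || acc_u[i] < omega) s[p] <- new_base
  }
  paste(s, collapse = "")
}

# Map CDS positions (1-based, transcription order) to 0-based genomic
# positions for a gene.
cds_genomic_positions <- function(gene) {
  out <- integer(0)
  for (e in gene$exons) {
    pos <- if (gene$locus$strand == "+") seq(e$start, e$end - 1L)
           else seq(e$end - 1L, e$start)
    out <- c(out, pos)
  }
  out
}

#' Evolve one subgenome from the ancestor
#'
#' Coding sequences evolve under the codon-acceptance process (synonymous
#' changes neutral, nonsynonymous accepted with probability `omega`, stops
#' rejected); introns and intergenic DNA mutate neutrally at rate `t` per
#' site.  Exon coordinates are untouched (no indels).
#'
#' @param ancestor Result of [simulate_ancestor()] (or a `genome_bundle`).
#' @param t Expected proposals per site.
#' @param omega Nonsynonymous acceptance probability.
#' @param seed RNG seed for this subgenome.
#' @return A diverged [genome_bundle()].
#' @export
evolve_subgenome <- function(ancestor, t, omega, seed) {
  bundle <- if (inherits(ancestor, "genome_bundle")) ancestor else ancestor$bundle
  if (t == 0) return(bundle)
  set.seed(seed)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (chrom in names(bundle$sequences)) {
    s <- strsplit(bundle$sequences[[chrom]], "", fixed = TRUE)[[1]]
    genes_here <- Filter(function(g) g$locus$chrom == chrom, bundle$genes)
    cds_mask <- logical(length(s))
    for (g in genes_here)
      for (e in g$exons) cds_mask[(e$start + 1L):e$end] <- TRUE
    # neutral substitution of non-coding sites
    nc <- which(!cds_mask)
    hit <- nc[stats::runif(length(nc)) < t]
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      repl <- vapply(s[hit], function(b) sample(bases[bases != b], 1L),
                     character(1), USE.NAMES = FALSE)
      s[hit] <- repl
    }
    # codon process per gene, written back through the exon map
    for (gid in names(genes_here)) {
      g <- bundle$genes[[gid]]
      new_cds <- mutate_cds(g$cds, t, omega)
      if (!identical(new_cds, g$cds)) {
        gpos <- cds_genomic_positions(g)
        nt <- strsplit(new_cds, "", fixed = TRUE)[[1]]
        if (g$locus$strand == "-") nt <- unname(comp[nt])
        s[gpos + 1L] <- nt
      }
      bundle$genes[[gid]]$cds <- new_cds
      bundle$genes[[gid]]$protein <- translate_cds(new_cds)$protein
    }
    bundle$sequences[[chrom]] <- paste(s, collapse = "")
  }
  bundle
}

#' Assemble the allohexaploid and apply post-polyploidy events
#'
#' Renames chromosomes per subgenome, merges the three diverged bundles, and
#' applies stochastic events per family gene per subgenome: `loss` removes
#' the annotation, `pseudogenize` injects a premature stop, `tandem_dup`
#' copies the gene a short distance downstream inside the same block,
#' `transpose` copies it into a different block.  Everything is recorded in
#' the returned ground truth.
#'
#' @param bundles Named list `list(G1 = , G2 = , G3 = )` of diverged bundles.
#' @param ancestor Result of [simulate_ancestor()].
#' @param config A [simulation_config()].
#' @param seed RNG seed for event placement.
#' @return List with `bundle` (merged [genome_bundle()]) and `truth` (list:
#'   `genes` per-gene truth table, `events`, `block_map`, `relations`).
#' @export
assemble_allohexaploid <- function(bundles, ancestor, config, seed) {
  set.seed(seed)
  sequences <- character(); genes <- list(); sub_map <- character()
  block_rows <- list(); gene_rows <- list()
  for (sg in c("G1", "G2", "G3")) {
    b <- bundles[[sg]]
    for (old in names(b$sequences)) {
      new <- sprintf("%s_chr%s", sg, sub("^AK", "", old))
      sequences[[new]] <- b$sequences[[old]]
      sub_map[[new]] <- sg
      bm <- ancestor$block_map[ancestor$block_map$chrom == old, , drop = FALSE]
      bm$chrom <- new
      block_rows[[length(block_rows) + 1L]] <- bm
    }
    for (gid in names(b$genes)) {
      g <- b$genes[[gid]]
      new_chrom <- sprintf("%s_chr%s", sg, sub("^AK", "", g$locus$chrom))
      g <- shift_gene(g, 0L, new_chrom)
      g$gene_id <- paste0(sg, "_", sub("^anc_", "", gid))
      g$subgenome <- sg
      genes[[g$gene_id]] <- g
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, subgenome = sg, ancestral_gene = gid,
        family = g$family, isotype = g$isotype, cls = g$cls,
        status = "functional", origin = "homeolog", parent_gene = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  bundle <- genome_bundle(sequences, genes, sub_map)
  block_map <- do.call(rbind, block_rows)
  truth_genes <- do.call(rbind, gene_rows)
  rownames(truth_genes) <- truth_genes$gene_id
  events <- list()

  fam_ids <- truth_genes$gene_id[truth_genes$family != "other"]
  rates <- config$event_rates
  for (gid in fam_ids) {
    sg <- truth_genes[gid, "subgenome"]
    u <- stats::runif(4)
    if (u[1] < rates[["loss"]]) {
      bundle$genes[[gid]] <- NULL
      truth_genes[gid, "status"] <- "lost"
      events[[length(events) + 1L]] <- data.frame(
        type = "loss", subgenome = sg, gene = gid, new_gene = NA_character_,
        chrom = NA_character_, pos = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    if (u[2] < rates[["pseudogenize"]]) {
      bundle <- inject_premature_stop(bundle, gid)
      truth_genes[gid, "status"] <- "pseudogene"
      events[[length(events) + 1L]] <- data.frame(
        type = "pseudogenize", subgenome = sg, gene = gid,
        new_gene = NA_character_, chrom = bundle$genes[[gid]]$locus$chrom,
        pos = bundle$genes[[gid]]$locus$start, stringsAsFactors = FALSE)
    }
    if (u[3] < rates[["tandem_dup"]]) {
      res <- duplicate_gene(bundle, block_map, gid, mode = "tandem",
                            max_bp = config$tandem_max_bp)
      bundle <- res$bundle; block_map <- res$block_map
      truth_genes <- rbind(truth_genes, data.frame(
        gene_id = res$new_id, subgenome = sg, ancestral_gene = NA_character_,
        family = truth_genes[gid, "family"], isotype = truth_genes[gid, "isotype"],
        cls = truth_genes[gid, "cls"],
        status = truth_genes[gid, "status"],   # a copy of a pseudogene is one
        origin = "tandem_paralog", parent_gene = gid, stringsAsFactors = FALSE))
      rownames(truth_genes) <- truth_genes$gene_id
      events[[length(events) + 1L]] <- data.frame(
        type = "tandem_dup", subgenome = sg, gene = gid, new_gene = res$new_id,
        chrom = res$chrom, pos = res$pos, stringsAsFactors = FALSE)
    }
    if (u[4] < rates[["transpose"]]) {
      res <- duplicate_gene(bundle, block_map, gid, mode = "transpose")
      bundle <- res$bundle; block_map <- res$block_map
      truth_genes <- rbind(truth_genes, data.frame(
        gene_id = res$new_id, subgenome = sg, ancestral_gene = NA_character_,
        family = truth_genes[gid, "family"], isotype = truth_genes[gid, "isotype"],
        cls = truth_genes[gid, "cls"],
        status = truth_genes[gid, "status"],
        origin = "transposed_paralog", parent_gene = gid,
        stringsAsFactors = FALSE))
      rownames(truth_genes) <- truth_genes$gene_id
      events[[length(events) + 1L]] <- data.frame(
        type = "transpose", subgenome = sg, gene = gid, new_gene = res$new_id,
        chrom = res$chrom, pos = res$pos, stringsAsFactors = FALSE)
    }
  }
  # true block label per gene (5'-end containment)
  truth_genes$block <- NA_character_
  for (i in seq_len(nrow(truth_genes))) {
    gid <- truth_genes$gene_id[i]
    g <- bundle$genes[[gid]]
    if (is.null(g)) next
    p <- gene_five_prime(g)
    bm <- block_map[block_map$chrom == g$locus$chrom, , drop = FALSE]
    hit <- which(bm$start <= p & p < bm$end)
    if (length(hit)) truth_genes$block[i] <- bm$block[hit[1]]
  }
  relations <- truth_relations(truth_genes)
  list(bundle = bundle,
       truth = list(genes = truth_genes,
                    events = if (length(events)) do.call(rbind, events) else NULL,
                    block_map = block_map, relations = relations))
}

shift_gene <- function(g, by, chrom = g$locus$chrom) {
  g$locus$chrom <- chrom; g$locus$start <- g$locus$start + by
  g$locus$end <- g$locus$end + by
  g$exons <- lapply(g$exons, function(e) {
    e$chrom <- chrom; e$start <- e$start + by; e$end <- e$end + by; e
  })
  g
}

# Replace a codon 20-80% into the CDS with TAA, editing the chromosome.
inject_premature_stop <- function(bundle, gid) {
  g <- bundle$genes[[gid]]
  n_cod <- nchar(g$cds) %/% 3L
  ci <- sample(seq(max(2L, floor(0.2 * n_cod)), floor(0.8 * n_cod)), 1L)
  cds <- g$cds
  substr(cds, 3L * ci - 2L, 3L * ci) <- "TAA"
  gpos <- cds_genomic_positions(g)[(3L * ci - 2L):(3L * ci)]
  s <- strsplit(bundle$sequences[[g$locus$chrom]], "", fixed = TRUE)[[1]]
  # genomic base at gpos[j] is the complement of cds base j on minus strand
  nt <- c("T", "A", "A")
  if (g$locus$strand == "-") nt <- c("A", "T", "T")
  s[gpos + 1L] <- nt
  bundle$sequences[[g$locus$chrom]] <- paste(s, collapse = "")
  g$cds <- cds
  g$protein <- translate_cds(cds)$protein
  bundle$genes[[gid]] <- g
  bundle
}

# Copy a gene into a new position: tandem (same block, downstream, <= max_bp)
# or transpose (different block).  Inserts sequence and shifts downstream
# coordinates.
duplicate_gene <- function(bundle, block_map, gid, mode, max_bp = 5e5) {
  g <- bundle$genes[[gid]]
  src_chrom <- g$locus$chrom
  p5 <- gene_five_prime(g)
  bm_src <- block_map[block_map$chrom == src_chrom, , drop = FALSE]
  src_block <- bm_src$block[bm_src$start <= p5 & p5 < bm_src$end][1]
  if (mode == "tandem") {
    target_chrom <- src_chrom
    row <- bm_src[bm_src$block == src_block, , drop = FALSE]
    lo <- g$locus$end + 100L
    hi <- min(row$end - 50L, g$locus$end + max_bp)
    if (hi <= lo) { lo <- max(row$start + 50L, g$locus$start - max_bp); hi <- g$locus$start - 100L }
    ins <- pick_intergenic_point(bundle, target_chrom, lo, hi)
  } else {
    others <- block_map[block_map$block != src_block &
                        bundle$subgenome_map[block_map$chrom] ==
                          bundle$subgenome_map[[src_chrom]], , drop = FALSE]
    row <- others[sample.int(nrow(others), 1L), , drop = FALSE]
    target_chrom <- row$chrom
    ins <- pick_intergenic_point(bundle, target_chrom, row$start + 50L, row$end - 50L)
  }
  seg <- substr(bundle$sequences[[src_chrom]], g$locus$start + 1L, g$locus$end)
  L <- nchar(seg)
  chromseq <- bundle$sequences[[target_chrom]]
  bundle$sequences[[target_chrom]] <-
    paste0(substr(chromseq, 1L, ins), seg, substr(chromseq, ins + 1L, nchar(chromseq)))
  # shift downstream annotations on the target chromosome
  for (oid in names(bundle$genes)) {
    og <- bundle$genes[[oid]]
    if (og$locus$chrom == target_chrom && og$locus$start >= ins)
      bundle$genes[[oid]] <- shift_gene(og, L)
  }
  sel <- block_map$chrom == target_chrom
  block_map$end[sel & block_map$start < ins & block_map$end >= ins] <-
    block_map$end[sel & block_map$start < ins & block_map$end >= ins] + L
  block_map$start[sel & block_map$start >= ins] <-
    block_map$start[sel & block_map$start >= ins] + L
  block_map$end[sel & block_map$start > ins] <-
    block_map$end[sel & block_map$start > ins] + L
  new_id <- paste0(gid, if (mode == "tandem") "_td" else "_tp")
  ng <- shift_gene(g, ins - g$locus$start, target_chrom)
  ng$gene_id <- new_id
  bundle$genes[[new_id]] <- ng
  list(bundle = bundle, block_map = block_map, new_id = new_id,
       chrom = target_chrom, pos = ins)
}

# A safe insertion point in [lo, hi] on `chrom` that no gene overlaps.
pick_intergenic_point <- function(bundle, chrom, lo, hi) {
  genes_here <- Filter(function(g) g$locus$chrom == chrom, bundle$genes)
  starts <- vapply(genes_here, function(g) g$locus$start, integer(1))
  ends <- vapply(genes_here, function(g) g$locus$end, integer(1))
  lo <- as.integer(lo); hi <- as.integer(hi)
  for (try in seq_len(200L)) {
    p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (!any(starts < p & p < ends)) return(p)
  }
  # fall back to the first gene boundary in range
  cand <- sort(ends[ends >= lo & ends <= hi])
  if (length(cand)) return(cand[1] + 10L)
  stop("no intergenic insertion point found on ", chrom)
}

# Homeology groups (one per ancestral family gene) from the per-gene table.
truth_relations <- function(truth_genes) {
  fam <- truth_genes[truth_genes$family != "other" &
                     truth_genes$status != "lost", , drop = FALSE]
  home <- fam[fam$origin == "homeolog", , drop = FALSE]
  split(home$gene_id, home$ancestral_gene)
}

#' Simulate a full allohexaploid family genome
#'
#' Convenience wrapper: ancestor, three diverged subgenomes, allohexaploid
#' assembly with events, and the expression matrix.
#'
#' @param config A [simulation_config()].
#' @return List with `bundle`, `truth`, `ancestor`, `expression` (matrix with
#'   per-condition metadata attribute) and `config`.
#' @export
simulate_family_genome <- function(config = simulation_config()) {
  anc <- simulate_ancestor(config)
  seeds <- config$seed * 1000L + 1:4
  bundles <- list(
    G1 = evolve_subgenome(anc, config$divergence[["G1"]], config$omega, seeds[1]),
    G2 = evolve_subgenome(anc, config$divergence[["G2"]], config$omega, seeds[2]),
    G3 = evolve_subgenome(anc, config$divergence[["G3"]], config$omega, seeds[3]))
  asm <- assemble_allohexaploid(bundles, anc, config, seeds[4])
  expr <- simulate_expression(asm$truth, config, config$seed * 1000L + 5L)
  list(bundle = asm$bundle, truth = asm$truth, ancestor = anc,
       expression = expr, config = config)
}

#' Simulate the expression matrix
#'
#' Functional genes draw a per-isotype lognormal tissue profile scaled by
#' subgenome bias and per-gene noise; pseudogenes get near-zero leakage.
#' Salt stress columns divide designated isotypes by `salt_fc`; no gene is
#' ever up-regulated under stress.
#'
#' @param truth Ground truth from [assemble_allohexaploid()].
#' @param config A [simulation_config()].
#' @param seed RNG seed.
#' @return Numeric matrix genes x conditions, with attributes `tissues` and
#'   `salt_pairs` (data frame organ/control/stress).
#' @export
simulate_expression <- function(truth, config, seed) {
  set.seed(seed)
  ex <- config$expression
  stopifnot(all(ex$bias > 0))
  tissues <- c("GS", "C", "YL", "SL", "S", "R", "B", "F",
               "ESD", "EMSD", "LMSD", "LSD")
  organs <- c("Root", "Shoot")
  tg <- truth$genes[truth$genes$family != "other" &
                    truth$genes$status != "lost", , drop = FALSE]
  conds <- c(tissues, as.vector(t(outer(organs, c("ctrl", "salt"), paste, sep = "_"))))
  m <- matrix(0, nrow(tg), length(conds), dimnames = list(tg$gene_id, conds))
  isotypes <- unique(tg$isotype)
  prof <- matrix(stats::rlnorm(length(isotypes) * length(tissues),
                               ex$meanlog, ex$sdlog),
                 length(isotypes), length(tissues),
                 dimnames = list(isotypes, tissues))
  salt_base <- matrix(stats::rlnorm(length(isotypes) * length(organs),
                                    ex$meanlog, ex$sdlog),
                      length(isotypes), length(organs),
                      dimnames = list(isotypes, organs))
  for (i in seq_len(nrow(tg))) {
    iso <- tg$isotype[i]; sg <- tg$subgenome[i]
    if (tg$status[i] == "pseudogene") {
      m[i, ] <- stats::runif(length(conds), 0, 0.5)
      # pseudogene leakage also never rises under stress
      for (o in organs)
        m[i, paste0(o, "_salt")] <- m[i, paste0(o, "_ctrl")]
      next
    }
    noise <- exp(stats::rnorm(length(tissues), 0, ex$noise_sd))
    m[i, tissues] <- prof[iso, ] * ex$bias[[sg]] * noise
    for (o in organs) {
      ctrl <- salt_base[iso, o] * ex$bias[[sg]] * exp(stats::rnorm(1, 0, ex$noise_sd))
      down <- iso %in% ex$salt_down_isotypes
      m[i, paste0(o, "_ctrl")] <- ctrl
      m[i, paste0(o, "_salt")] <- if (down) ctrl / ex$salt_fc else ctrl
    }
  }
  attr(m, "tissues") <- tissues
  attr(m, "salt_pairs") <- data.frame(
    organ = organs, control = paste0(organs, "_ctrl"),
    stress = paste0(organs, "_salt"), stringsAsFactors = FALSE)
  m
}

#' Write simulation artifacts to a directory
#'
#' Emits exactly the formats the analysis stages read: genome FASTA, GFF3,
#' subgenome TSV, reference isotype protein FASTA (ancestral family
#' proteins), expression TSV, a truth-labelled syntelog/anchor TSV, and the
#' ground truth as JSON.
#'
#' @param sim Result of [simulate_family_genome()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fasta"),
             gff3 = file.path(dir, "genes.gff3"),
             subgenomes = file.path(dir, "subgenomes.tsv"),
             queries = file.path(dir, "reference_isotypes.faa"),
             expression = file.path(dir, "expression.tsv"),
             anchors = file.path(dir, "true_syntelogs.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genome_bundle(sim$bundle, paths["fasta"], paths["gff3"], paths["subgenomes"])
  anc_fam <- Filter(function(g) g$family != "other", sim$ancestor$bundle$genes)
  aa <- Biostrings::AAStringSet(vapply(anc_fam, `[[`, character(1), "protein"))
  names(aa) <- vapply(anc_fam, `[[`, character(1), "isotype")
  Biostrings::writeXStringSet(aa, paths["queries"], width = 60L)
  m <- sim$expression
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # block-labelled syntelog pairs across subgenomes (ancestral-gene identity)
  tg <- sim$truth$genes
  keep <- tg$status != "lost" & !is.na(tg$ancestral_gene)
  tg <- tg[keep, , drop = FALSE]
  pairs <- list()
  for (anc_id in unique(tg$ancestral_gene)) {
    mem <- tg[tg$ancestral_gene == anc_id, , drop = FALSE]
    if (nrow(mem) < 2) next
    cmb <- utils::combn(seq_len(nrow(mem)), 2)
    pairs[[anc_id]] <- data.frame(
      gene_a = mem$gene_id[cmb[1, ]], gene_b = mem$gene_id[cmb[2, ]],
      block = mem$block[cmb[1, ]], stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, pairs), paths["anchors"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_out <- sim$truth
  truth_out$relations <- lapply(truth_out$relations, as.list)
  jsonlite::write_json(truth_out, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(paths)
}
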