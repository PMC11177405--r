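# Shared fixtures, built once per test run.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# A tiny two-gene bundle for core-model tests: one plus-strand and one
# minus-strand gene, hand-laid-out coordinates.
make_toy_bundle <- function() {
  # chr1: 100 bp pad | exon1 (9bp) | 20 bp intron | exon2 (6bp) | pad
  cds <- "ATGGCTGCTAAGTAA"             # M A A K *
  ex1 <- substr(cds, 1, 9); ex2 <- substr(cds, 10, 15)
  intron <- paste(rep("T", 20), collapse = "")
  seq1 <- paste0(strrep("A", 100), ex1, intron, ex2, strrep("G", 50))
  gplus <- gene_record(
    "gplus",
    genomic_interval("chr1", 100L, 100L + 9L + 20L + 6L, "+"),
    list(genomic_interval("chr1", 100L, 109L, "+"),
         genomic_interval("chr1", 129L, 135L, "+")),
    family = "TUA", isotype = "TUA1", cls = "II")
  # chr2: same cds on the minus strand, single exon
  seq2 <- paste0(strrep("C", 40),
                 as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))),
                 strrep("C", 40))
  gminus <- gene_record(
    "gminus", genomic_interval("chr2", 40L, 55L, "-"),
    list(genomic_interval("chr2", 40L, 55L, "-")),
    family = "TUB", isotype = "TUB1", cls = "I")
  b <- genome_bundle(c(chr1 = seq1, chr2 = seq2),
                     list(gplus = gplus, gminus = gminus),
                     c(chr1 = "G1", chr2 = "G2"))
  for (gid in names(b$genes)) {
    cp <- extract_cds_and_protein(b$genes[[gid]], b)
    b$genes[[gid]]$cds <- cp$cds
    b$genes[[gid]]$protein <- cp$protein
  }
  b
}

# The default simulated world (seed 1), shared by several test files.
shared_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_family_genome(simulation_config(seed = 1))
    sim
  }
})

reference_queries <- function(sim) {
  anc_fam <- Filter(function(g) g$family != "other", sim$ancestor$bundle$genes)
  stats::setNames(vapply(anc_fam, `[[`, character(1), "protein"),
                  vapply(anc_fam, `[[`, character(1), "isotype"))
}

# Full synteny stage on a simulated bundle; memoized per call site.
run_synteny <- function(bundle) {
  sgs <- sort(unique(bundle$subgenome_map))
  sb <- lapply(stats::setNames(sgs, sgs), function(s) subset_bundle(bundle, s))
  out <- list()
  for (pr in utils::combn(sgs, 2, simplify = FALSE)) {
    a <- find_anchors(sb[[pr[1]]], sb[[pr[2]]])
    out[[paste(pr, collapse = "-")]] <- list(anchors = a,
                                             chains = chain_collinear(a))
  }
  out
}

shared_synteny <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- run_synteny(shared_sim()$bundle)
    res
  }
})

family_metadata <- function(sim) {
  tg <- sim$truth$genes
  fam <- tg[tg$family != "other" & tg$status != "lost", , drop = FALSE]
  list(ids = fam$gene_id,
       families = stats::setNames(fam$family, fam$gene_id),
       isotypes = stats::setNames(fam$isotype, fam$gene_id),
       status = stats::setNames(fam$status, fam$gene_id))
}
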