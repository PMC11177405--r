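test_that("anchors are reciprocal best hits and never self-pairs", {
  sim <- shared_sim()
  syn <- shared_synteny()
  for (pr in syn) {
    a <- pr$anchors
    expect_false(any(a$gene_a == a$gene_b))
    expect_false(anyDuplicated(a$gene_a) > 0)
    expect_false(anyDuplicated(a$gene_b) > 0)
  }
  # a gene lost in G2 leaves its G1 copy with no anchor in that comparison
  # (twin isotypes excluded: an identical-sequence twin legitimately takes
  # over as the reciprocal best hit)
  tg <- sim$truth$genes
  lost_g2 <- tg$gene_id[tg$status == "lost" & tg$subgenome == "G2" &
                        !tg$isotype %in% c("TUA3", "TUA5")]
  if (length(lost_g2)) {
    partner <- sub("^G2_", "G1_", lost_g2)
    a12 <- syn[["G1-G2"]]$anchors
    expect_false(any(partner %in% a12$gene_a))
  }
})

test_that("anchors recover ancestral gene identity on the simulated bundle", {
  syn <- shared_synteny()
  anc_of <- function(g) sub("^G[123]_", "", g)
  for (pr in syn) {
    a <- pr$anchors
    # twin isotypes (identical ancestral sequence) are legitimately
    # ambiguous for RBH; everything else must match
    twins <- c("TUA3", "TUA5")
    nt <- !(anc_of(a$gene_a) %in% twins)
    expect_gte(mean(anc_of(a$gene_a[nt]) == anc_of(a$gene_b[nt])), 0.995)
  }
})

test_that("chaining handles diagonals, interlopers and inversions", {
  mk <- function(ra, rb, score = 10) data.frame(
    gene_a = paste0("a", seq_along(ra)), gene_b = paste0("b", seq_along(ra)),
    chrom_a = "cA", chrom_b = "cB", rank_a = ra, rank_b = rb,
    pos_a = ra * 1000L, pos_b = rb * 1000L, score = score)
  # perfect diagonal
  ch <- chain_collinear(mk(1:5, 1:5), min_size = 5)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$size, 5)
  expect_equal(ch[[1]]$orientation, "plus")
  # off-diagonal anchor is excluded
  a <- rbind(mk(1:5, 1:5), mk(3, 50)[1, ])
  ch2 <- chain_collinear(a, min_size = 5)
  expect_length(ch2, 1)
  expect_equal(ch2[[1]]$size, 5)
  expect_false(50 %in% ch2[[1]]$anchors$rank_b)
  # inversion
  ch3 <- chain_collinear(mk(1:5, 5:1), min_size = 5)
  expect_length(ch3, 1)
  expect_equal(ch3[[1]]$orientation, "minus")
  # chains are strictly monotone on both rank axes
  for (c in c(ch, ch2, ch3)) {
    expect_true(all(diff(c$anchors$rank_a) > 0))
    db <- diff(c$anchors$rank_b)
    expect_true(all(db > 0) || all(db < 0))
  }
})

test_that("chain extraction equals exhaustive search on anchor sets <= 12", {
  set.seed(111)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    a <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                    chrom_a = "cA", chrom_b = "cB",
                    rank_a = sample(1:20, n), rank_b = sample(1:20, n),
                    pos_a = 0L, pos_b = 0L,
                    score = sample(5:20, n, replace = TRUE))
    for (orient in c("plus", "minus")) {
      got <- hexatub:::best_chain(a, orient, max_gap = 25)
      want <- oracle_best_chain(a$rank_a, a$rank_b, a$score, orient, 25)
      expect_equal(got$score, want, info = paste("seed case", k, orient))
    }
  }
})

test_that("homeolog groups on the default bundle match ground truth", {
  sim <- shared_sim()
  syn <- shared_synteny()
  meta <- family_metadata(sim)
  ranks <- gene_rank_table(sim$bundle)
  subg <- vapply(sim$bundle$genes, function(g)
    hexatub:::subgenome_of(g, sim$bundle), character(1))
  grp <- detect_homeolog_groups(syn, meta$ids, ranks, subg, meta$families)
  truth <- sim$truth$relations
  expect_equal(grp$triplets, sum(lengths(truth) == 3))
  expect_equal(grp$pairs, sum(lengths(truth) == 2))
  got <- lapply(grp$groups[lengths(grp$groups) > 1], sort)
  want <- lapply(truth[lengths(truth) > 1], sort)
  expect_setequal(lapply(got, paste, collapse = "|"),
                  lapply(want, paste, collapse = "|"))
})

test_that("block borders: clean split, interloper tolerance, minor fragments", {
  a <- data.frame(pos = c(seq(1000, 10000, by = 1000),
                          seq(20000, 29000, by = 1000)),
                  block = rep(c("A", "B"), each = 10))
  res <- infer_block_borders(a, "chr")
  expect_equal(nrow(res$blocks), 2)
  expect_equal(res$blocks$block, c("A", "B"))
  expect_equal(res$blocks$end[1], (10000 + 20000) %/% 2)
  expect_equal(res$blocks$start[2], res$blocks$end[1])
  expect_false(any(res$blocks$minor_fragment))
  # single embedded foreign anchor stays inside the run and is logged
  a2 <- data.frame(pos = seq(1000, 9000, by = 1000),
                   block = c(rep("A", 4), "B", rep("A", 4)))
  res2 <- infer_block_borders(a2, "chr")
  expect_equal(res2$blocks$block, "A")
  expect_equal(nrow(res2$interlopers), 1)
  # two isolated anchors -> minor fragment
  a3 <- data.frame(pos = c(seq(1000, 9000, by = 1000), 15000, 16000),
                   block = c(rep("A", 9), "F", "F"))
  res3 <- infer_block_borders(a3, "chr")
  fb <- res3$blocks[res3$blocks$block == "F", ]
  expect_true(fb$minor_fragment)
  # annotations never overlap and are sorted
  for (r in list(res, res2, res3)) {
    bl <- r$blocks
    if (nrow(bl) > 1) expect_true(all(bl$start[-1] >= bl$end[-nrow(bl)]))
  }
  expect_warning(infer_block_borders(
    data.frame(pos = c(1, 2), block = c("A", NA)), "chr"), "unlabelled")
})

test_that("gene-to-block allocation uses the 5'-end and reports gaps", {
  bm <- data.frame(chrom = "chr", start = c(0L, 10000L), end = c(5000L, 20000L),
                   block = c("C", "D"))
  g_in <- gene_record("g1", genomic_interval("chr", 2000L, 2500L, "+"),
                      list(genomic_interval("chr", 2000L, 2500L, "+")))
  expect_equal(assign_gene_to_block(g_in, bm), "C")
  g_gap <- gene_record("g2", genomic_interval("chr", 6000L, 6500L, "+"),
                       list(genomic_interval("chr", 6000L, 6500L, "+")))
  expect_equal(assign_gene_to_block(g_gap, bm), "unassigned")
  # minus-strand gene whose start lies in C but 5' end in D
  g_minus <- gene_record("g3", genomic_interval("chr", 4500L, 10500L, "-"),
                         list(genomic_interval("chr", 4500L, 10500L, "-")))
  expect_equal(assign_gene_to_block(g_minus, bm), "D")
  g_off <- gene_record("g4", genomic_interval("other", 0L, 10L, "+"),
                       list(genomic_interval("other", 0L, 10L, "+")))
  expect_error(assign_gene_to_block(g_off, bm), "absent")
})

test_that("homologous block size comparison flags large ratios", {
  bm <- data.frame(chrom = c("c1", "c2", "c3"), start = 0L,
                   end = c(3600000L, 3650000L, 3700000L), block = "X")
  sgm <- c(c1 = "G1", c2 = "G2", c3 = "G3")
  res <- compare_homologous_blocks(bm, "X", sgm)
  expect_equal(res$ratio, 3700000 / 3600000, tolerance = 1e-9)
  expect_false(res$flagged)
  bm2 <- data.frame(chrom = c("c1", "c2", "c3"), start = 0L,
                    end = c(1e6L, 2e6L, 3e6L), block = "Y")
  res2 <- compare_homologous_blocks(bm2, "Y", sgm)
  expect_equal(res2$ratio, 3)
  expect_true(res2$flagged)
  bm3 <- data.frame(chrom = "c1", start = 0L, end = 100L, block = "Z")
  res3 <- compare_homologous_blocks(bm3, "Z", sgm)
  expect_equal(res3$ratio, 1)
  expect_error(compare_homologous_blocks(bm, "Q", sgm), "absent")
})
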