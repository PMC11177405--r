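test_that("context similarity: identical, disjoint and partial flanks", {
  # 21 genes on each of two chromosomes; orthogroups shared by rank
  mk_ranks <- function(chrom, ids) data.frame(
    gene_id = ids, chrom = chrom, rank = seq_along(ids),
    pos = seq_along(ids) * 1000L, row.names = ids)
  ra <- mk_ranks("cA", paste0("a", 1:21))
  rb <- mk_ranks("cB", paste0("b", 1:21))
  ranks <- rbind(ra, rb)
  og_same <- c(stats::setNames(paste0("OG", 1:21), paste0("a", 1:21)),
               stats::setNames(paste0("OG", 1:21), paste0("b", 1:21)))
  cs <- context_similarity("a11", "b11", ranks, og_same, window = 10)
  expect_equal(cs$jaccard, 1.0)
  expect_equal(cs$order_agreement, 1.0)
  og_disj <- c(stats::setNames(paste0("OG", 1:21), paste0("a", 1:21)),
               stats::setNames(paste0("XG", 1:21), paste0("b", 1:21)))
  cs0 <- context_similarity("a11", "b11", ranks, og_disj, window = 10)
  expect_equal(cs0$jaccard, 0)
  expect_equal(cs0$order_agreement, 0)
  # 5 shared of 15 union (5 shared + 2x5 private twice = window 5 usable):
  # use window 10 with 5 shared groups in same order
  og_part <- og_disj
  og_part[paste0("b", c(7, 9, 12, 14, 16))] <-
    og_same[paste0("a", c(7, 9, 12, 14, 16))]
  csp <- context_similarity("a11", "b11", ranks, og_part, window = 10)
  expect_equal(csp$jaccard, 5 / (20 + 20 - 5))
  expect_equal(csp$order_agreement, 1.0)
})

test_that("relation classification follows the rule cascade", {
  # homeolog: different subgenomes, chain support, block match
  call <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "G2", block_a = "C", block_b = "C",
    chain_support = TRUE, clade_agreement = TRUE,
    status_a = "functional", status_b = "functional"))
  expect_equal(call$relation, "homeolog")
  expect_length(call$flags, 0)
  # disrupted homeolog when one member is a pseudogene
  call2 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "G3", block_a = "V", block_b = "V",
    chain_support = TRUE, status_a = "functional", status_b = "pseudogene"))
  expect_equal(call2$relation, "disrupted_homeolog")
  # tandem: same subgenome, same block, 488 kbp apart
  call3 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G3", subgenome_b = "G3", block_a = "X", block_b = "X",
    distance_bp = 488000))
  expect_equal(call3$relation, "tandem_paralog")
  # transposed: same subgenome, block T vs the siblings' block V
  call4 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G3", subgenome_b = "G3", block_a = "T", block_b = "V"))
  expect_equal(call4$relation, "transposed_paralog")
  # homeoparalog: different subgenomes, different isotype lineages
  call5 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "G3", block_a = "D", block_b = "E",
    chain_support = FALSE, isotype_a = "TUB9", isotype_b = "TUB4"))
  expect_equal(call5$relation, "homeoparalog")
  # cross-species ortholog
  call6 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "At", cross_species = TRUE,
    block_a = "C", block_b = "C", chain_support = TRUE))
  expect_equal(call6$relation, "ortholog")
  # conflict flag: chain support without clade agreement
  call7 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "G2", block_a = "C", block_b = "C",
    chain_support = TRUE, clade_agreement = FALSE))
  expect_true("conflict" %in% call7$flags)
  # totality: an evidence-free pair still gets exactly one relation
  call8 <- classify_relation(c("x", "y"), list(
    subgenome_a = "G1", subgenome_b = "G2"))
  expect_length(call8$relation, 1)
  expect_true("low_confidence" %in% call8$flags)
})

test_that("relation classification is exact on forced simulator events", {
  cfg <- simulation_config(seed = 13,
                           event_rates = c(loss = 0, pseudogenize = 0,
                                           tandem_dup = 0.25, transpose = 0.25))
  sim <- simulate_family_genome(cfg)
  tg <- sim$truth$genes
  dups <- tg[tg$origin %in% c("tandem_paralog", "transposed_paralog"), ,
             drop = FALSE]
  expect_gt(nrow(dups), 4)
  for (k in seq_len(nrow(dups))) {
    child <- dups$gene_id[k]; parent <- dups$parent_gene[k]
    ev <- list(
      subgenome_a = tg[parent, "subgenome"], subgenome_b = tg[child, "subgenome"],
      block_a = tg[parent, "block"], block_b = tg[child, "block"],
      distance_bp = abs(sim$bundle$genes[[child]]$locus$start -
                        sim$bundle$genes[[parent]]$locus$start))
    got <- classify_relation(c(parent, child), ev)$relation
    expect_equal(got, dups$origin[k], info = child)
  }
})

test_that("isotype resolution prefers clades and falls back to context", {
  # clade uniquely names the isotype
  r <- resolve_isotype("q", "TUB7", c("TUB7", "TUB8"),
                       c(TUB7 = "ref7", TUB8 = "ref8"), NULL, NULL)
  expect_equal(r$isotype, "TUB7")
  expect_equal(r$evidence, "clade")
  # ambiguous clade resolved by locus context (twin isotypes)
  ids_q <- paste0("q", 1:21); ids_5 <- paste0("r5_", 1:21); ids_3 <- paste0("r3_", 1:21)
  ranks <- rbind(
    data.frame(gene_id = ids_q, chrom = "cq", rank = 1:21, pos = 1:21 * 1000L,
               row.names = ids_q),
    data.frame(gene_id = ids_5, chrom = "c5", rank = 1:21, pos = 1:21 * 1000L,
               row.names = ids_5),
    data.frame(gene_id = ids_3, chrom = "c3", rank = 1:21, pos = 1:21 * 1000L,
               row.names = ids_3))
  og <- c(stats::setNames(paste0("OG", 1:21), ids_q),
          stats::setNames(paste0("OG", 1:21), ids_5),   # TUA5 locus: same context
          stats::setNames(paste0("ZG", 1:21), ids_3))   # TUA3 locus: different
  r2 <- resolve_isotype("q11", "ambiguous", c("TUA3", "TUA5"),
                        c(TUA3 = "r3_11", TUA5 = "r5_11"), ranks, og)
  expect_equal(r2$isotype, "TUA5")
  expect_equal(r2$evidence, "context")
  # permutation invariance in reference ordering
  r3 <- resolve_isotype("q11", "ambiguous", c("TUA5", "TUA3"),
                        c(TUA5 = "r5_11", TUA3 = "r3_11"), ranks, og)
  expect_equal(r3$isotype, r2$isotype)
  # no reference above the context floor -> unresolved
  r4 <- resolve_isotype("q11", "ambiguous", "TUA3", c(TUA3 = "r3_11"),
                        ranks, og)
  expect_true(is.na(r4$isotype))
})

test_that("twin isotypes resolve 100% correctly via context on the simulation", {
  sim <- shared_sim()
  # reference genome = ancestor; orthogroups from RBH between the G1
  # subgenome and the ancestor
  g1 <- subset_bundle(sim$bundle, "G1")
  anc <- sim$ancestor$bundle
  anchors <- find_anchors(g1, anc)
  og <- build_orthogroups(list(anchors))
  ranks <- rbind(gene_rank_table(g1), gene_rank_table(anc))
  twins <- c("TUA3", "TUA5")
  ref_genes <- c(TUA3 = "anc_TUA3", TUA5 = "anc_TUA5")
  for (iso in twins) {
    gid <- paste0("G1_", iso)
    r <- resolve_isotype(gid, "ambiguous", twins, ref_genes, ranks, og)
    expect_equal(r$isotype, iso, info = gid)
  }
})

test_that("missing-ortholog detection flags single-species absences", {
  inv <- read_gene_inventory()
  cs_tab <- data.frame(isotype = inv$isotype, status = inv$status)
  # the model diploid's tubulin isotype inventory (no TUB10, no TUB2 gene
  # lineage of its own beyond the TUB2/3 local duplication; TUG1/2 present)
  at_tab <- data.frame(
    isotype = c(paste0("TUA", 1:6), paste0("TUB", c(1, 3:9)), "TUG1", "TUG2"),
    status = "functional")
  rep <- detect_missing_orthologs(list(Cs = cs_tab, At = at_tab))
  expect_equal(rep$matrix["TUB10", "At"], "absent")
  expect_equal(rep$matrix["TUB10", "Cs"], "present")
  expect_true("TUB10" %in% rep$flags$isotype)
  # all-present case yields no flags
  rep2 <- detect_missing_orthologs(list(a = at_tab, b = at_tab))
  expect_equal(nrow(rep2$flags), 0)
  # constructed trio with one loss
  t1 <- data.frame(isotype = c("I1", "I2"), status = "functional")
  t2 <- data.frame(isotype = "I1", status = "functional")
  rep3 <- detect_missing_orthologs(list(s1 = t1, s2 = t2, s3 = t1))
  expect_equal(rep3$flags$isotype, "I2")
  expect_equal(rep3$flags$species, "s2")
})

test_that("gene naming follows the family convention", {
  df <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    isotype = c("TUA5", "TUA1", "TUA2", "TUA2", "TUA2"),
    subgenome = c("G1", "unplaced", "G1", "G2", "G3"),
    status = c("pseudogene", "functional", "functional", "functional",
               "functional"))
  out <- name_genes(df)
  expect_equal(out$name,
               c("TUA5p-A", "TUA1-Un", "TUA2-A", "TUA2-B", "TUA2-C"))
  # collision handling
  df2 <- df[c(3, 3), ]
  expect_warning(out2 <- name_genes(df2), "collision")
  expect_false(anyDuplicated(out2$name) > 0)
})
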