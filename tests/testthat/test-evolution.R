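test_that("protein distances: p-distance and Poisson", {
  al <- c(a = strrep("A", 450), b = strrep("A", 450))
  d <- protein_distance(al)
  expect_equal(d["a", "b"], 0)
  # 10 mismatches over 450 compared sites
  bchars <- strsplit(al[["b"]], "")[[1]]
  bchars[1:10] <- "R"
  al2 <- c(a = al[["a"]], b = paste(bchars, collapse = ""))
  expect_equal(protein_distance(al2)["a", "b"], 10 / 450, tolerance = 1e-9)
  expect_equal(protein_distance(al2, "poisson")["a", "b"], -log(1 - 10 / 450))
  # gap columns deleted pairwise
  al3 <- c(a = "AR-ND", b = "ARCND")
  expect_equal(protein_distance(al3)["a", "b"], 0)
  # p = 1 under Poisson is undefined
  al4 <- c(a = "AAAA", b = "RRRR")
  expect_warning(d4 <- protein_distance(al4, "poisson"), "undefined")
  expect_true(is.na(d4["a", "b"]))
  expect_error(protein_distance(c(a = "A-", b = "-A")), "no comparable")
})

test_that("NJ solves the worked 4-taxon additive case", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  # topology AB|CD with external branches 1,2,3,4 and internal branch 1
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("NJ is invariant to taxon order and clamps negative branches", {
  set.seed(121)
  ra <- random_additive_matrix(7)
  t1 <- nj_tree(ra$d)
  perm <- sample(rownames(ra$d))
  t2 <- nj_tree(ra$d[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  expect_equal(stats::cophenetic(t2)[rownames(ra$d), rownames(ra$d)],
               stats::cophenetic(t1)[rownames(ra$d), rownames(ra$d)],
               tolerance = 1e-8)
})

test_that("clade assignment distinguishes classes, defers on mixtures", {
  # two clean reference clades and one query next to class II
  d <- matrix(10, 5, 5)
  diag(d) <- 0
  labs <- c("r1a", "r1b", "r2a", "r2b", "q")
  dimnames(d) <- list(labs, labs)
  d["r1a", "r1b"] <- d["r1b", "r1a"] <- 1
  d["r2a", "r2b"] <- d["r2b", "r2a"] <- 1
  d["q", "r2a"] <- d["r2a", "q"] <- 2
  d["q", "r2b"] <- d["r2b", "q"] <- 2
  tr <- nj_tree(d)
  refs <- c(r1a = "I", r1b = "I", r2a = "II", r2b = "II")
  expect_equal(assign_class_by_clade(tr, refs, "q"), "II")
  # merged mixed clade -> ambiguous
  refs_mixed <- c(r2a = "TUA3", r2b = "TUA5")
  expect_equal(assign_class_by_clade(tr, refs_mixed, "q"), "ambiguous")
  expect_error(assign_class_by_clade(tr, refs, "nope"), "not in tree")
})

test_that("simulated classes are recovered perfectly at divergence 0.1", {
  sim <- shared_sim()
  queries <- reference_queries(sim)
  ev <- evolve_subgenome(sim$ancestor, 0.1, 0.05, 555)
  fam <- Filter(function(g) g$family == "TUA", ev$genes)
  # exclude the identical-sequence twin pair: distance methods cannot split
  # TUA3/TUA5 and clading hands them to locus-context resolution
  fam <- Filter(function(g) !g$isotype %in% c("TUA3", "TUA5"), fam)
  refs <- queries[grep("^TUA", names(queries))]
  fspec <- default_family_spec()
  ref_labels <- stats::setNames(fspec$cls[match(names(refs), fspec$isotype)],
                                names(refs))
  for (g in fam) {
    seqs <- c(refs, stats::setNames(g$protein, "query"))
    al <- align_proteins(seqs)
    tr <- nj_tree(protein_distance(al))
    want <- fspec$cls[fspec$isotype == g$isotype]
    expect_equal(assign_class_by_clade(tr, ref_labels, "query"), want,
                 info = g$isotype)
  }
})

test_that("codon threading drops gap columns and rejects stops", {
  # gap-free pair
  ca <- codon_align("ATGAAACCC", "ATGAAGCCC")
  expect_length(ca$codons_a, 3)
  # a 2-residue gap drops 2 codon columns
  a <- "ATGAAATTTGGGCCC"; b <- "ATGGGGCCC"
  ca2 <- codon_align(a, b, c("MKFGP", "M--GP"))
  expect_length(ca2$codons_a, 3)
  # internal stop in a retained column is fatal
  expect_error(codon_align("ATGTAACCC", "ATGAAACCC", c("M*P", "MKP")),
               "stop")
  # mismatched protein alignment is fatal
  expect_error(codon_align("ATGAAACCC", "ATGAAGCCC", c("MKX", "MKP")),
               "does not match")
})

test_that("NG86 site counts match the independent enumeration oracle", {
  st <- hexatub:::ng86_site_table()
  for (cod in hexatub:::sense_codons())
    expect_equal(st[[cod]], oracle_syn_sites(cod), info = cod)
  # the two worked examples
  expect_equal(st[["GGG"]], 1.0)
  expect_equal(st[["TTT"]], 1 / 3)
  # S + N = 3 per codon by construction of the renormalization
  expect_equal(unname(st + (3 - st)), rep(3, 61))
})

test_that("NG86 results are symmetric and handle degenerate input", {
  set.seed(131)
  cods <- hexatub:::sense_codons()
  a <- paste(c("ATG", sample(cods, 40, TRUE)), collapse = "")
  b <- paste(c("ATG", sample(cods, 40, TRUE)), collapse = "")
  r_ab <- ng86_kaks(list(codons_a = hexatub:::split_codons(a),
                         codons_b = hexatub:::split_codons(b)))
  r_ba <- ng86_kaks(list(codons_a = hexatub:::split_codons(b),
                         codons_b = hexatub:::split_codons(a)))
  expect_equal(r_ab$Ka, r_ba$Ka)
  expect_equal(r_ab$Ks, r_ba$Ks)
  expect_equal(r_ab$S_sites + r_ab$N_sites, 3 * 41)
  # identical sequences
  r0 <- kaks_pair("ATGGCTAAGTAA", "ATGGCTAAGTAA")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true("ratio_undefined" %in% r0$flags)
  # single nonsynonymous change: Ks exactly 0, Ka > 0
  set.seed(132)
  cds <- paste(c("ATG", sample(cods, 28, TRUE), "TAA"), collapse = "")
  # CGG <-> TGG is R <-> W: a purely nonsynonymous single-step difference
  r1 <- kaks_pair(paste0("ATG", "CGG", substr(cds, 7, nchar(cds))),
                  paste0("ATG", "TGG", substr(cds, 7, nchar(cds))))
  expect_equal(r1$Ks, 0)
  expect_gt(r1$Ka, 0)
})

test_that("multi-difference codons average over step orderings", {
  # TTT (F) vs GTA (V): both single-step orders pass through non-stop
  # codons; enumerate by hand: paths TTT->GTT->GTA and TTT->TTA->GTA
  d <- hexatub:::ng86_diff_pair("TTT", "GTA")
  # path 1: TTT->GTT (F->V, nonsyn), GTT->GTA (V->V, syn) = 1 nonsyn 1 syn
  # path 2: TTT->TTA (F->L, nonsyn), TTA->GTA (L->V, nonsyn) = 2 nonsyn
  expect_equal(d[["sd"]], 0.5)
  expect_equal(d[["nd"]], 1.5)
})

test_that("Ka/Ks summary reports group statistics and bound exceedances", {
  mk <- function(ka, ks) structure(
    list(Ka = ka, Ks = ks, ratio = ifelse(ks > 0, ka / ks, NA_real_)),
    class = "kaks_result")
  res <- list(alpha = list(mk(0.01, 0.10), mk(0.035, 0.19)),
              beta = list(mk(0.07, 0.13)),
              empty = list())
  s <- kaks_summary(res)
  expect_equal(s$n, c(2, 1, 0))
  expect_equal(s$max_ka, c(0.035, 0.07, NA))
  expect_equal(s$n_ka_exceed, c(0, 1, 0))
  expect_equal(s$max_ratio[1], 0.035 / 0.19, tolerance = 1e-9)
})

test_that("homeolog Ka/Ks on the simulation sits in the conserved regime", {
  sim <- shared_sim()
  tg <- sim$truth$genes
  fun <- tg$gene_id[tg$status == "functional"]
  rel <- lapply(sim$truth$relations, intersect, fun)
  res <- list()
  for (grp in rel[lengths(rel) >= 2][1:6]) {
    cmb <- utils::combn(grp, 2)
    for (k in seq_len(ncol(cmb)))
      res[[length(res) + 1]] <- kaks_pair(sim$bundle$genes[[cmb[1, k]]]$cds,
                                          sim$bundle$genes[[cmb[2, k]]]$cds)
  }
  s <- kaks_summary(list(homeologs = res))
  expect_lt(s$mean_ka, 0.04)
  expect_lt(s$mean_ks, 0.2)
})
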