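test_that("interval and gene-record invariants are enforced", {
  expect_error(genomic_interval("c", 10, 10), "start < end")
  expect_error(genomic_interval("c", -1, 5), "start < end")
  expect_error(genomic_interval("c", 0, 5, "x"), "strand")
  loc <- genomic_interval("c", 0, 100, "+")
  expect_error(gene_record("g", loc,
                           list(genomic_interval("c", 0, 50, "+"),
                                genomic_interval("c", 40, 80, "+"))),
               "overlap")
  expect_error(gene_record("g", loc, list(genomic_interval("c", 50, 120, "+"))),
               "outside gene span")
  # minus-strand exons must be in transcription (descending) order
  expect_error(gene_record("g", genomic_interval("c", 0, 100, "-"),
                           list(genomic_interval("c", 0, 20, "-"),
                                genomic_interval("c", 40, 60, "-"))),
               "transcription order")
})

test_that("translation follows the standard code and stops at first stop", {
  expect_equal(translate_cds("ATGGCTTAA")$protein, "MA")
  expect_false(translate_cds("ATGGCTTAA")$premature_stop)
  # internal stop at codon 5 of a 10-codon cds -> 4 aa + premature flag
  cds <- paste0("ATG", "GCT", "GCT", "GCT", "TAA", strrep("GCT", 5))
  tr <- translate_cds(cds)
  expect_equal(nchar(tr$protein), 4)
  expect_true(tr$premature_stop)
})

test_that("CDS extraction handles both strands and errors past chromosome end", {
  b <- make_toy_bundle()
  plus <- extract_cds_and_protein(b$genes$gplus, b)
  expect_equal(plus$cds, "ATGGCTGCTAAGTAA")
  expect_equal(plus$protein, "MAAK")
  minus <- extract_cds_and_protein(b$genes$gminus, b)
  expect_equal(minus$cds, plus$cds)   # strand symmetry
  expect_equal(minus$protein, "MAAK")
  broken <- b$genes$gplus
  broken$exons[[2]]$end <- nchar(b$sequences[["chr1"]]) + 10L
  broken$locus$end <- broken$exons[[2]]$end
  expect_error(extract_cds_and_protein(broken, b), "beyond end")
})

test_that("genome bundle round-trips through FASTA/GFF3 bit-exactly", {
  sim <- shared_sim()
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa"); gff <- file.path(d, "g.gff3")
  tsv <- file.path(d, "s.tsv")
  write_genome_bundle(sim$bundle, fa, gff, tsv)
  b2 <- read_genome_bundle(fa, gff, tsv)
  expect_setequal(names(b2$genes), names(sim$bundle$genes))
  for (gid in sample(names(sim$bundle$genes), 25)) {
    g1 <- sim$bundle$genes[[gid]]; g2 <- b2$genes[[gid]]
    expect_identical(c(g1$locus$start, g1$locus$end), c(g2$locus$start, g2$locus$end))
    expect_identical(lapply(g1$exons, function(e) c(e$start, e$end)),
                     lapply(g2$exons, function(e) c(e$start, e$end)))
    expect_identical(g1$cds, g2$cds)
    expect_identical(g1$protein, g2$protein)
  }
  # and writing again reproduces the files byte-identically
  fa2 <- file.path(d, "g2.fa"); gff2 <- file.path(d, "g2.gff3")
  write_genome_bundle(b2, fa2, gff2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(gff), readLines(gff2))
})

test_that("reader rejects inconsistent annotation", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 50)), fa)
  gff <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chrX\tsrc\tgene\t1\t60\t.\t+\t.\tID=g1",
               "chrX\tsrc\tmRNA\t1\t60\t.\t+\t.\tID=m1;Parent=g1",
               "chrX\tsrc\tCDS\t1\t60\t.\t+\t0\tID=c1;Parent=m1"), gff)
  expect_error(read_genome_bundle(fa, gff), "unknown chromosome")
  gff2 <- file.path(d, "bad2.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t60\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t1\t60\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tID=c1;Parent=m1"), gff2)
  expect_error(read_genome_bundle(fa, gff2), "g1")
})

test_that("genes on unmapped scaffolds come back as unplaced", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">Scaff00574", strrep("ATGGCTTAAC", 6)), fa)
  gff <- file.path(d, "g.gff3")
  writeLines(c("##gff-version 3",
               "Scaff00574\tsrc\tgene\t1\t9\t.\t+\t.\tID=gU",
               "Scaff00574\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=mU;Parent=gU",
               "Scaff00574\tsrc\tCDS\t1\t9\t.\t+\t0\tID=cU;Parent=mU"), gff)
  b <- read_genome_bundle(fa, gff, NULL)
  expect_equal(b$genes$gU$subgenome, "unplaced")
})

test_that("derive_structure computes exon/intron arithmetic", {
  g <- gene_record("g", genomic_interval("c", 0, 300, "+"),
                   list(genomic_interval("c", 0, 100, "+"),
                        genomic_interval("c", 200, 300, "+")))
  st <- derive_structure(g)
  expect_equal(st$exon_lengths, c(100, 100))
  expect_equal(st$intron_lengths, 100)
  expect_equal(st$exon_count, 2)
  g1 <- gene_record("g1", genomic_interval("c", 5, 50, "+"),
                    list(genomic_interval("c", 5, 50, "+")))
  expect_equal(derive_structure(g1)$intron_lengths, integer(0))
})

test_that("structure invariants hold on every simulated functional gene", {
  sim <- shared_sim()
  tg <- sim$truth$genes
  fun <- tg$gene_id[tg$status == "functional"]
  for (gid in sample(fun, 40)) {
    g <- sim$bundle$genes[[gid]]
    st <- derive_structure(g)
    expect_equal(sum(st$exon_lengths), nchar(g$cds))
    expect_equal(nchar(g$protein), nchar(g$cds) / 3 - 1)
    expect_equal(sum(st$exon_lengths) + sum(st$intron_lengths),
                 g$locus$end - g$locus$start)
  }
})

test_that("family structure conformity flags deviations", {
  mk <- function(id, fam, cls, n_ex) {
    len <- 100L * n_ex
    exons <- lapply(seq_len(n_ex), function(i)
      genomic_interval("c", (i - 1L) * 100L, (i - 1L) * 100L + 50L, "+"))
    gene_record(id, genomic_interval("c", 0L, len, "+"), exons,
                family = fam, cls = cls)
  }
  genes <- list(mk("tug", "TUG", NA, 10), mk("tub", "TUB", "I", 3),
                mk("tua", "TUA", "II", 4), mk("anon", "other", NA, 2))
  rep <- suppressWarnings(validate_family_structure(genes))
  expect_equal(rep$pass, c(TRUE, TRUE, FALSE))
  expect_warning(validate_family_structure(genes), "anon")
})

test_that("pseudogene diagnosis applies the three rules", {
  ref <- strrep("A", 450)
  mk_gene <- function(cds) {
    g <- gene_record("g", genomic_interval("c", 0L, 10L, "+"),
                     list(genomic_interval("c", 0L, 10L, "+")))
    g$cds <- cds
    g
  }
  set.seed(7)
  intact <- paste0("ATG", paste(sample(hexatub:::sense_codons(), 449, TRUE),
                                collapse = ""), "TAA")
  expect_equal(diagnose_pseudogene(mk_gene(intact), ref)$status, "functional")
  # 183-aa product of a 450-aa reference: 0.407 < 0.6
  frag <- paste0("ATG", paste(sample(hexatub:::sense_codons(), 182, TRUE),
                              collapse = ""), "TAA")
  d <- diagnose_pseudogene(mk_gene(frag), ref)
  expect_equal(d$status, "pseudogene")
  expect_true("short_product" %in% d$reasons)
  # 444/450 stays functional (the near-full-length case)
  near <- paste0("ATG", paste(sample(hexatub:::sense_codons(), 443, TRUE),
                              collapse = ""), "TAA")
  expect_equal(diagnose_pseudogene(mk_gene(near), ref)$status, "functional")
  # internal stop at codon 200 of 450
  stopcds <- intact
  substr(stopcds, 598, 600) <- "TAA"
  d2 <- diagnose_pseudogene(mk_gene(stopcds), ref)
  expect_true("premature_stop" %in% d2$reasons)
  # frameshift
  fs <- paste0(intact, "AC")
  expect_true("frameshift" %in% diagnose_pseudogene(mk_gene(fs), ref)$reasons)
  expect_error(diagnose_pseudogene(mk_gene(""), ref), "empty")
})

test_that("simulator-pseudogenized genes are diagnosed as pseudogenes", {
  cfg <- simulation_config(seed = 3,
                           event_rates = c(loss = 0, pseudogenize = 0.5,
                                           tandem_dup = 0, transpose = 0))
  sim <- simulate_family_genome(cfg)
  tg <- sim$truth$genes
  ps <- tg$gene_id[tg$status == "pseudogene"]
  expect_gt(length(ps), 5)
  for (gid in ps) {
    g <- sim$bundle$genes[[gid]]
    ref <- sim$ancestor$bundle$genes[[paste0("anc_", tg[gid, "isotype"])]]$protein
    expect_equal(diagnose_pseudogene(g, ref)$status, "pseudogene")
  }
})
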