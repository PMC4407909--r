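two_locus_baits <- function(seed = 20) {
  set.seed(seed)
  data.frame(bait_id = c("uce-1_p1", "uce-2_p1"),
             locus_id = c("uce-1", "uce-2"), index = 1L,
             chrom = "chr1", start = 0L, end = 120L,
             residues = c(random_seq(120), random_seq(120)),
             stringsAsFactors = FALSE)
}

test_that("a contig containing a bait verbatim is credited to its locus", {
  baits <- two_locus_baits()
  contig <- paste0(random_seq(200), baits$residues[1], random_seq(150))
  db <- match_contigs_to_loci(list(taxA = c(node_1 = contig)), baits)
  expect_true(db$presence["uce-1", "taxA"])
  expect_false(db$presence["uce-2", "taxA"])
  expect_identical(db$name_map$contig_id, "node_1")
})

test_that("bait ids must parse to a locus", {
  expect_error(match_contigs_to_loci(list(t = c(n = "ACGT")),
                                     c(badname = "ACGTACGT")),
               "not parseable")
})

test_that("chimeric contigs hitting two loci are removed entirely", {
  baits <- two_locus_baits()
  chimera <- paste0(baits$residues[1], random_seq(30), baits$residues[2])
  db <- match_contigs_to_loci(list(taxA = c(node_1 = chimera)), baits)
  expect_false(any(db$presence))
  expect_identical(db$removal_log$reason, "multi-locus")
  expect_identical(db$removal_log$item, "node_1")
})

test_that("a locus matched by two distinct contigs is marked absent", {
  baits <- two_locus_baits()
  c1 <- paste0(random_seq(100), baits$residues[1], random_seq(100))
  c2 <- paste0(random_seq(60), baits$residues[1], random_seq(40))
  db <- match_contigs_to_loci(list(taxA = c(node_1 = c1, node_2 = c2)), baits)
  expect_false(db$presence["uce-1", "taxA"])
  expect_setequal(db$removal_log$reason, "duplicate-contig")
  # every input contig with a bait hit is accounted for
  expect_setequal(db$removal_log$item, "uce-1")
})

test_that("match database construction is invariant to contig order", {
  baits <- two_locus_baits()
  set.seed(21)
  contigs <- c(node_1 = paste0(random_seq(50), baits$residues[1], random_seq(50)),
               node_2 = paste0(random_seq(50), baits$residues[2], random_seq(50)),
               node_3 = random_seq(300))
  db1 <- match_contigs_to_loci(list(t = contigs), baits)
  db2 <- match_contigs_to_loci(list(t = rev(contigs)), baits)
  expect_identical(db1$presence, db2$presence)
  expect_identical(db1$name_map[order(db1$name_map$locus_id), ]$contig_id,
                   db2$name_map[order(db2$name_map$locus_id), ]$contig_id)
})

test_that("completeness thresholds reproduce the printed worked values", {
  pres <- matrix(TRUE, nrow = 2, ncol = 14,
                 dimnames = list(c("uce-1", "uce-2"), paste0("t", 1:14)))
  pres["uce-2", 1:5] <- FALSE  # present in 9 of 14 taxa
  db <- fake_match_db(pres)
  expect_identical(get_match_counts(db, paste0("t", 1:14), 0.70), "uce-1")
  # 0.70 * 14 -> at least 10; 9 is not enough, 10 is
  pres["uce-2", 5] <- TRUE
  expect_identical(get_match_counts(fake_match_db(pres), paste0("t", 1:14), 0.70),
                   c("uce-1", "uce-2"))
  # 0.75 * 44 -> at least 33
  pres44 <- matrix(FALSE, nrow = 1, ncol = 44,
                   dimnames = list("uce-1", paste0("t", 1:44)))
  pres44[1, 1:33] <- TRUE
  expect_identical(get_match_counts(fake_match_db(pres44), paste0("t", 1:44), 0.75),
                   "uce-1")
  pres44[1, 33] <- FALSE
  expect_identical(get_match_counts(fake_match_db(pres44), paste0("t", 1:44), 0.75),
                   character(0))
  expect_error(get_match_counts(db, c("t1", "nope"), 0.7), "nope")
})

test_that("a full-presence filter keeps only universally shared loci", {
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 2,
                 dimnames = list(c("uce-1", "uce-2"), c("a", "b")))
  expect_identical(get_match_counts(fake_match_db(pres), c("a", "b"), 1.0),
                   "uce-1")
})

test_that("get_fastas emits locus-major records and flags missing data", {
  pres <- matrix(TRUE, 2, 3, dimnames = list(c("uce-1", "uce-2"),
                                             c("ta", "tb", "tc")))
  nm <- expand.grid(taxon = c("ta", "tb", "tc"), locus_id = c("uce-1", "uce-2"),
                    stringsAsFactors = FALSE)
  nm$contig_id <- paste0("n_", nm$locus_id, "_", nm$taxon)
  db <- fake_match_db(pres, nm)
  seqs <- lapply(setNames(c("ta", "tb", "tc"), c("ta", "tb", "tc")), function(t) {
    setNames(c(random_seq(30), random_seq(30)),
             paste0("n_", c("uce-1", "uce-2"), "_", t))
  })
  recs <- get_fastas(db, seqs, c("uce-1", "uce-2"))
  expect_length(recs, 6)
  expect_identical(names(recs)[1:3], c("uce-1_ta", "uce-1_tb", "uce-1_tc"))
  # an absent pair is skipped, not placeholdered
  pres["uce-2", "tb"] <- FALSE
  recs5 <- get_fastas(fake_match_db(pres, nm), seqs, c("uce-1", "uce-2"))
  expect_length(recs5, 5)
  expect_false("uce-2_tb" %in% names(recs5))
  # regrouping re-parsed records reproduces presence exactly
  groups <- split_by_locus(recs5)
  expect_identical(lapply(groups, names),
                   list(`uce-1` = c("ta", "tb", "tc"), `uce-2` = c("ta", "tc")))
  # a credited pair without a retrievable sequence is an error
  seqs$ta <- seqs$ta[-1]
  expect_error(get_fastas(fake_match_db(pres, nm), seqs, "uce-1"), "missing")
})

test_that("genome slicing keeps the flank and clamps at sequence ends", {
  set.seed(22)
  genome_mid <- c(chr1 = random_seq(5000))
  loc <- buffer_region(data.frame(chrom = "chr1", start = 2400, end = 2460),
                       genome_mid, locus_id = "uce-1")
  baits <- tile_baits(loc)
  res <- slice_from_genome(genome_mid, baits, flank = 1000)
  expect_equal(nchar(res$slices[["uce-1"]]), 2180)
  expect_identical(res$slices[["uce-1"]],
                   toupper(substr(genome_mid[[1]], loc$start - 1000 + 1,
                                  loc$end + 1000)))
  # locus 300 bp from the 5' end: clamped to 300 + 180 + 1000
  near5 <- c(chr1 = paste0(random_seq(300), toupper(loc$residues),
                           random_seq(3000)))
  res2 <- slice_from_genome(near5, baits, flank = 1000)
  expect_equal(nchar(res2$slices[["uce-1"]]), 1480)
})

test_that("a locus matching two genomic sites is dropped during slicing", {
  set.seed(23)
  locus_seq <- random_seq(180)
  genome <- c(chr1 = paste0(random_seq(600), locus_seq, random_seq(800),
                            locus_seq, random_seq(600)))
  baits <- data.frame(bait_id = "uce-1_p1", locus_id = "uce-1", index = 1L,
                      chrom = "chr1", start = 0L, end = 120L,
                      residues = substr(locus_seq, 1, 120),
                      stringsAsFactors = FALSE)
  res <- slice_from_genome(genome, baits, flank = 100)
  expect_false("uce-1" %in% names(res$slices))
  expect_identical(res$log$reason, "multiple-genomic-sites")
})

test_that("minus-strand genomic sites are sliced in bait orientation", {
  set.seed(24)
  locus_seq <- random_seq(180)
  genome <- c(chr1 = paste0(random_seq(400), revcomp(locus_seq), random_seq(400)))
  baits <- data.frame(bait_id = "uce-1_p1", locus_id = "uce-1", index = 1L,
                      chrom = "chr1", start = 0L, end = 120L,
                      residues = substr(locus_seq, 1, 120),
                      stringsAsFactors = FALSE)
  res <- slice_from_genome(genome, baits, flank = 50)
  expect_true(grepl(substr(locus_seq, 1, 120), res$slices[["uce-1"]], fixed = TRUE))
})

test_that("divergence brackets the identity threshold for recovery", {
  spec <- synth_spec(genome_length = 16000, n_elements = 10,
                     element_length_range = c(60, 120))
  gp <- make_genome_pair(spec, seed = 25)
  regions <- scan_alignment(gp$blocks)
  design <- design_baits(regions, gp$genome_a)
  # at 25% divergence expected identity (~0.75) sits below the threshold:
  # recovery collapses, and the rare bait whose best local alignment
  # fluctuates above 80% still points at the true ortholog
  far <- make_contigs(gp$genome_a, design$loci, divergence = 0.25, seed = 26)
  db_far <- match_contigs_to_loci(list(t = far$contigs), design$baits)
  expect_lte(sum(db_far$presence), 1)
  if (nrow(db_far$name_map)) {
    expect_identical(
      far$truth$locus_id[far$truth$contig_id == db_far$name_map$contig_id[1]],
      db_far$name_map$locus_id[1])
  }
  # at 5% divergence recovery is essentially complete and specific
  near <- make_contigs(gp$genome_a, design$loci, divergence = 0.05, seed = 26,
                       n_decoys = 3)
  db_near <- match_contigs_to_loci(list(t = near$contigs), design$baits)
  expect_gte(sum(db_near$presence), 9)
  credited <- db_near$name_map$contig_id
  truth_targets <- near$truth$contig_id[near$truth$type == "target"]
  expect_true(all(credited %in% truth_targets))
})

test_that("the two-table relational store round-trips", {
  baits <- two_locus_baits()
  contig <- paste0(random_seq(50), baits$residues[2], random_seq(50))
  db <- match_contigs_to_loci(list(taxA = c(node_9 = contig)), baits)
  dir <- withr::local_tempdir()
  write_match_db(db, dir)
  expect_true(file.exists(file.path(dir, "presence.csv")))
  back <- read_match_db(dir)
  expect_identical(back$presence, db$presence)
  expect_identical(back$name_map$contig_id, db$name_map$contig_id)
})
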