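make_design_genome <- function(len = 5000, seed = 1) {
  set.seed(seed)
  c(chr1 = random_seq(len))
}

region_row <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end)
}

test_that("buffering pads short regions equally with the odd base going 3'", {
  g <- make_design_genome()
  # 60 bp mid-sequence -> 180 bp with 60 each side
  loc <- buffer_region(region_row(1000, 1060), g, locus_id = "uce-1")
  expect_equal(c(loc$start, loc$end), c(940, 1120))
  expect_equal(nchar(loc$residues), 180)
  expect_identical(loc$residues, substr(g[["chr1"]], 941, 1120))
  # >= target length passes through unchanged
  loc2 <- buffer_region(region_row(1000, 1200), g)
  expect_equal(c(loc2$start, loc2$end), c(1000, 1200))
  # 61 bp: 119 to add, 59 on the 5' side and 60 on the 3'
  loc3 <- buffer_region(region_row(1000, 1061), g)
  expect_equal(c(loc3$start, loc3$end), c(1000 - 59, 1061 + 60))
})

test_that("buffering clamps at sequence ends, shifting the deficit", {
  g <- make_design_genome()
  loc <- buffer_region(region_row(10, 70), g)  # 5' clamp
  expect_equal(loc$start, 0)
  expect_equal(loc$end, 180)
  expect_false(loc$flagged)
  short <- c(chr1 = random_seq(100))
  locf <- buffer_region(region_row(20, 80), short)
  expect_equal(c(locf$start, locf$end), c(0, 100))
  expect_true(locf$flagged)
})

locus_row <- function(g, start, L, id = "uce-1") {
  data.frame(locus_id = id, chrom = "chr1", start = start, end = start + L,
             residues = substr(g[["chr1"]], start + 1, start + L),
             flagged = FALSE, stringsAsFactors = FALSE)
}

test_that("tiling follows the 2X closed form for exactly tileable loci", {
  g <- make_design_genome(6000)
  for (L in seq(120, 1020, by = 60)) {
    loc <- locus_row(g, 2000, L, "uce-9")
    baits <- tile_baits(loc)
    expect_equal(nrow(baits), (L - 120) / 60 + 1)
    expect_equal(baits$start - loc$start, seq(0, L - 120, by = 60))
  }
  # the canonical buffered locus yields 2 baits at offsets 0 and 60
  loc180 <- buffer_region(region_row(2000, 2060), g, locus_id = "uce-1")
  expect_equal(tile_baits(loc180)$start - loc180$start, c(0, 60))
})

test_that("non-tileable loci get a final flush bait and full coverage", {
  g <- make_design_genome()
  for (L in c(121, 150, 199, 275)) {
    loc <- locus_row(g, 1000, L, "uce-2")
    baits <- tile_baits(loc)
    expect_equal(max(baits$end), loc$end)  # flush with the 3' end
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(baits))) {
      covered[(baits$start[i] - loc$start + 1):(baits$end[i] - loc$start)] <- TRUE
    }
    expect_true(all(covered))
  }
  # a whole sequence shorter than a bait: flagged locus, then no baits
  tiny <- buffer_region(region_row(10, 70), c(chr1 = random_seq(80)),
                        locus_id = "uce-3")
  expect_true(tiny$flagged)
  expect_equal(nrow(tile_baits(tiny)), 0)
})

test_that("bait filters apply strict ambiguity, repeat and GC rules", {
  set.seed(10)
  at <- strrep("AT", 60)
  with_n <- paste0(substr(at, 1, 119), "N")
  gc85 <- paste0(strrep("G", 85), strrep("A", 35))   # 0.7083 > 0.70
  gc84 <- paste0(strrep("G", 84), strrep("A", 36))   # 0.70 exactly
  lower30 <- paste0(tolower(substr(at, 1, 30)), substr(at, 31, 120))  # 0.25
  lower31 <- paste0(tolower(substr(at, 1, 31)), substr(at, 32, 120))
  res <- filter_baits(c(at, with_n, gc85, gc84, lower30, lower31))
  expect_identical(res$pass, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(res$reasons[2], "ambiguity")
  expect_identical(res$reasons[3], "gc")
  expect_identical(res$reasons[6], "repeat")
  multi <- filter_baits(paste0(strrep("g", 85), strrep("N", 35)))
  expect_setequal(strsplit(multi$reasons, ",")[[1]],
                  c("ambiguity", "repeat", "gc"))
})

test_that("exact duplicate baits collapse to the lowest locus and index", {
  set.seed(11)
  seq1 <- random_seq(120)
  baits <- data.frame(
    bait_id = c("uce-2_p1", "uce-1_p1", "uce-10_p1"),
    locus_id = c("uce-2", "uce-1", "uce-10"), index = 1L,
    chrom = "chr1", start = 0L, end = 120L,
    residues = seq1, stringsAsFactors = FALSE)
  dd <- dedupe_baits(baits)
  expect_identical(dd$kept$bait_id, "uce-1_p1")
  expect_setequal(dd$removed$bait_id, c("uce-2_p1", "uce-10_p1"))
})

test_that("same-locus tiling neighbours are exempt from the near-dup screen", {
  g <- make_design_genome()
  loc <- buffer_region(region_row(1000, 1060), g, locus_id = "uce-1")
  baits <- tile_baits(loc)  # neighbours share 60/120 = 0.50, not > 0.50
  dd <- dedupe_baits(baits)
  expect_equal(nrow(dd$kept), 2)
  # cross-locus near-duplicates are both removed
  near <- substitute_evenly(baits$residues[1], 12)  # 90% identity, full length
  cross <- rbind(baits[1, ],
                 data.frame(bait_id = "uce-5_p1", locus_id = "uce-5",
                            index = 1L, chrom = "chr1", start = 500L,
                            end = 620L, residues = near,
                            stringsAsFactors = FALSE))
  dd2 <- dedupe_baits(cross)
  expect_equal(nrow(dd2$kept), 0)
})

test_that("the design pipeline wires buffer, tile, filter and dedupe", {
  set.seed(12)
  spec <- synth_spec(genome_length = 40000, n_elements = 45,
                     element_length_range = c(60, 60), min_spacing = 400)
  gp <- make_genome_pair(spec, seed = 12)
  regions <- scan_alignment(gp$blocks)
  design <- design_baits(regions, gp$genome_a)
  # 45 singleton 60-bp loci buffered to 180 bp -> 2 baits each before filters
  expect_equal(unname(design$report["baits_tiled"]), 90)
  expect_equal(design$report[["loci"]], 45)
  # every emitted bait re-slices from the design genome at its coordinates
  for (i in seq_len(nrow(design$baits))) {
    b <- design$baits[i, ]
    expect_identical(toupper(b$residues),
                     toupper(substr(gp$genome_a[[b$chrom]], b$start + 1, b$end)))
  }
})

test_that("a fully soft-masked locus yields no baits and is dropped", {
  spec <- synth_spec(genome_length = 20000, n_elements = 8,
                     n_masked_elements = 1)
  gp <- make_genome_pair(spec, seed = 13)
  regions <- scan_alignment(gp$blocks)
  design <- design_baits(regions, gp$genome_a)
  expect_length(design$dropped_loci, 1)
  expect_equal(length(unique(design$baits$locus_id)), 7)
})

test_that("an empty conserved set designs zero baits with a warning", {
  g <- make_design_genome()
  expect_warning(out <- design_baits(region_row(1, 2)[0, ], g), "empty")
  expect_equal(nrow(out$baits), 0)
})
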