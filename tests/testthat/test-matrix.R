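aln <- function(id, ...) locus_alignment(id, c(...))

test_that("locus alignments validate shape and taxon labels", {
  expect_error(locus_alignment("uce-1", c(a = "ACGT")), "length")
  expect_error(locus_alignment("uce-1", c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(locus_alignment("uce-1", c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("completeness thresholds use ceil(fraction * N)", {
  expect_equal(min_taxa_threshold(0.70, 14), 10L)
  expect_equal(min_taxa_threshold(0.75, 44), 33L)
  alns <- list(aln("uce-1", a = "AC", b = "AC", c = "AC"),
               aln("uce-2", a = "GT", b = "GT"))
  expect_length(min_taxa_filter(alns, 4, 0.75), 1)   # needs >= 3 rows
  expect_length(min_taxa_filter(alns, 4, 0.50), 2)
  expect_length(min_taxa_filter(alns, 3, 1.0), 1)    # only complete ones
})

test_that("parsimony-informative columns follow the two-by-two rule", {
  expect_equal(informative_sites(aln("u", a = "A", b = "A", c = "C", d = "C")), 1)
  expect_equal(informative_sites(aln("u", a = "A", b = "A", c = "A", d = "C")), 0)
  # gaps, ? and ambiguity codes are missing data, never a state
  expect_equal(informative_sites(aln("u", a = "R", b = "R", c = "C", d = "C")), 0)
  expect_equal(informative_sites(aln("u", a = "-", b = "-", c = "C", d = "C")), 0)
  expect_equal(informative_sites(aln("u", a = "?", b = "?", c = "C", d = "C")), 0)
  # case-insensitive states
  expect_equal(informative_sites(aln("u", a = "a", b = "A", c = "c", d = "C")), 1)
})

test_that("informative-site counts equal the exhaustive column oracle", {
  set.seed(31)
  for (rep in 1:100) {
    ntaxa <- sample(4:8, 1)
    ncols <- sample(5:60, 1)
    rows <- vapply(seq_len(ntaxa), function(i) {
      random_seq(ncols, alphabet = c("A", "C", "G", "T", "-", "?", "N", "R", "a"))
    }, character(1))
    names(rows) <- paste0("t", seq_len(ntaxa))
    a <- locus_alignment("u", rows)
    expect_equal(informative_sites(a), informative_oracle(rows))
  }
})

test_that("informative_sites is invariant under row and column permutation", {
  set.seed(32)
  rows <- setNames(vapply(1:6, function(i) random_seq(40), character(1)),
                   paste0("t", 1:6))
  base <- informative_sites(locus_alignment("u", rows))
  expect_equal(informative_sites(locus_alignment("u", sample(rows))), base)
  perm <- sample(40)
  shuffled <- vapply(rows, function(r) {
    paste(strsplit(r, "")[[1]][perm], collapse = "")
  }, character(1))
  expect_equal(informative_sites(locus_alignment("u", shuffled)), base)
})

test_that("summary statistics match the closed-form CI half-width", {
  alns <- list(aln("uce-1", a = strrep("A", 100), b = strrep("A", 100)),
               aln("uce-2", a = strrep("C", 200), b = strrep("C", 200)),
               aln("uce-3", a = strrep("G", 300), b = strrep("G", 300)))
  s <- summary_stats(alns)
  expect_equal(s$overall$mean_length, 200)
  expect_equal(s$overall$ci95_length, 1.96 * 100 / sqrt(3), tolerance = 1e-12)
  one <- summary_stats(alns[1])
  expect_equal(one$overall$mean_length, 100)
  expect_equal(one$overall$ci95_length, 0)
  expect_true(one$overall$single_alignment)
})

test_that("total informative sites are additive under concatenation", {
  set.seed(33)
  alns <- lapply(1:4, function(i) {
    rows <- setNames(vapply(1:5, function(j) random_seq(30), character(1)),
                     paste0("t", 1:5))
    locus_alignment(sprintf("uce-%d", i), rows)
  })
  sm <- concat_alignments(alns)
  expect_equal(summary_stats(alns)$overall$total_informative,
               informative_sites(sm$rows))
})

test_that("concatenation orders loci, fills absences with ? and records charsets", {
  alns <- list(aln("uce-2", a = strrep("G", 200), b = strrep("T", 200)),
               aln("uce-1", a = strrep("A", 100), c = strrep("C", 100)))
  sm <- concat_alignments(alns)
  expect_identical(sm$charsets$locus_id, c("uce-1", "uce-2"))
  expect_equal(nchar(sm$rows[["a"]]), 300)
  expect_identical(sm$rows[["c"]], paste0(strrep("C", 100), strrep("?", 200)))
  expect_identical(sm$rows[["b"]], paste0(strrep("?", 100), strrep("T", 200)))
  expect_equal(sm$charsets$start, c(1L, 101L))
  expect_equal(sm$charsets$end, c(100L, 300L))
  expect_error(concat_alignments(list(alns[[1]], alns[[1]])), "duplicate")
})

test_that("per-charset extraction reproduces each input alignment", {
  set.seed(34)
  alns <- lapply(1:3, function(i) {
    taxa <- sample(paste0("t", 1:6), sample(3:5, 1))
    rows <- setNames(vapply(taxa, function(t) random_seq(20 * i), character(1)),
                     taxa)
    locus_alignment(sprintf("uce-%d", i), rows)
  })
  sm <- concat_alignments(alns)
  for (a in alns) {
    back <- extract_charset(sm, a$locus_id)
    expect_identical(back$rows[sort(names(a$rows))],
                     a$rows[sort(names(a$rows))])
  }
  expect_error(extract_charset(sm, "uce-99"), "unknown locus")
})

test_that("edge trimming removes low-identity ends and nothing else", {
  clean <- aln("u", a = strrep("ACGT", 15), b = strrep("ACGT", 15),
               c = strrep("ACGT", 15))
  expect_identical(edge_trim(clean)$rows, clean$rows)
  # 20 leading all-gap columns are removed
  gappy <- locus_alignment("u", vapply(clean$rows, function(r) {
    paste0(strrep("-", 20), r)
  }, character(1)))
  expect_identical(edge_trim(gappy)$rows, clean$rows)
  # random noise never reaches 50% mean pairwise identity
  set.seed(35)
  noise <- locus_alignment("u", setNames(
    vapply(1:4, function(i) random_seq(60), character(1)), paste0("t", 1:4)))
  expect_warning(res <- edge_trim(noise), "entire alignment")
  expect_null(res)
})
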