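# Independent oracles and tiny fixture builders used across the suite.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute exactly k positions (chosen deterministically spread) so the
# global identity of the pair is known by construction
substitute_evenly <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- round(seq(1, length(chars), length.out = k))
  chars[idx] <- vapply(chars[idx], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  paste(chars, collapse = "")
}

# build a 2..k-row gapless/gappy MAF block from aligned texts
block_from_texts <- function(texts, srcs = NULL, starts = NULL,
                             strands = NULL, src_size = 10000L) {
  n <- length(texts)
  maf_block(data.frame(
    src = srcs %||% paste0("seq", seq_len(n)),
    start = starts %||% rep(0L, n),
    size = nchar(gsub("-", "", texts, fixed = TRUE)),
    strand = strands %||% rep("+", n),
    src_size = rep(src_size, n),
    text = texts, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive column-by-column oracle for conserved runs: walks columns one
# at a time, tracking the current run, entirely independent of rle()
conserved_runs_oracle <- function(texts, min_len) {
  mat <- do.call(rbind, strsplit(toupper(texts), "", fixed = TRUE))
  runs <- list()
  run_start <- NA
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ok <- col[1] %in% c("A", "C", "G", "T") && length(unique(col)) == 1
    if (ok && is.na(run_start)) run_start <- j
    if (!ok && !is.na(run_start)) {
      runs[[length(runs) + 1]] <- c(run_start, j - 1)
      run_start <- NA
    }
  }
  if (!is.na(run_start)) runs[[length(runs) + 1]] <- c(run_start, ncol(mat))
  runs <- Filter(function(r) (r[2] - r[1] + 1) > min_len, runs)
  runs  # list of 1-based inclusive column ranges
}

# per-column parsimony-informative oracle via table()
informative_oracle <- function(rows) {
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  count <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    tab <- tab[names(tab) %in% c("A", "C", "G", "T")]
    if (sum(tab >= 2) >= 2) count <- count + 1L
  }
  count
}

# Smith-Waterman duplicate decision via Biostrings (match +1, mismatch -1,
# linear gap -2), both strands, coverage on the shorter sequence
sw_oracle_duplicate <- function(a, b, min_identity = 0.8, min_coverage = 0.5) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  shorter <- min(nchar(a), nchar(b))
  for (target in c(b, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(b))))) {
    pa <- Biostrings::pairwiseAlignment(a, target, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 0, gapExtension = 2)
    if (Biostrings::nchar(pa) == 0) next
    identity <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    span_a <- Biostrings::width(Biostrings::pattern(pa))
    span_b <- Biostrings::width(Biostrings::subject(pa))
    cov <- (if (nchar(a) <= nchar(b)) span_a else span_b) / shorter
    if (identity > min_identity && cov > min_coverage) return(TRUE)
  }
  FALSE
}

# minimal hand-built match_db for threshold/export tests
fake_match_db <- function(presence, name_map = NULL) {
  structure(list(presence = presence,
                 name_map = name_map %||% data.frame(
                   locus_id = character(), taxon = character(),
                   contig_id = character(), identity = numeric(),
                   strand = character(), stringsAsFactors = FALSE),
                 removal_log = data.frame(taxon = character(),
                                          item = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE),
                 params = list()),
            class = "match_db")
}
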