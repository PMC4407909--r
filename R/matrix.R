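# Per-locus alignment bookkeeping and supermatrix assembly. Alignments are
# named character vectors (taxon -> aligned residues) wrapped with a
# locus_id; the supermatrix records 1-based inclusive charsets in
# concatenation order.

#' Construct a per-locus alignment
#'
#' @param locus_id locus identifier (e.g. `"uce-1"`).
#' @param rows named character vector: taxon -> aligned residues
#'   (`A,C,G,T,-,?`, IUPAC ambiguity codes allowed).
#' @return object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, rows) {
  stopifnot(is.character(rows), length(rows) >= 2, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate taxon labels in ", locus_id)
  if (length(unique(nchar(rows))) != 1L) stop("ragged rows in ", locus_id)
  structure(list(locus_id = locus_id, rows = rows), class = "locus_alignment")
}

aln_rows <- function(a) if (inherits(a, "locus_alignment")) a$rows else a

#' Completeness threshold and filter
#'
#' An alignment passes when it contains data for at least
#' `ceiling(fraction * n_taxa_total)` taxa: a 70%-complete filter over 14
#' taxa requires at least 10, and a 75%-complete filter over 44 requires at
#' least 33.
#'
#' @param fraction completeness fraction in (0, 1].
#' @param n_taxa_total total number of taxa in the study.
#' @return `min_taxa_threshold`: the integer threshold.
#' @export
min_taxa_threshold <- function(fraction, n_taxa_total) {
  stopifnot(fraction > 0, fraction <= 1, n_taxa_total >= 1)
  as.integer(ceiling(fraction * n_taxa_total))
}

#' @rdname min_taxa_threshold
#' @param alignments list of `locus_alignment` objects.
#' @return `min_taxa_filter`: the subset of alignments meeting the threshold.
#' @export
min_taxa_filter <- function(alignments, n_taxa_total, fraction) {
  thr <- min_taxa_threshold(fraction, n_taxa_total)
  keep <- vapply(alignments, function(a) length(aln_rows(a)) >= thr, logical(1))
  message("stage=min_taxa_filter in=", length(alignments), " out=", sum(keep))
  alignments[keep]
}

aln_char_matrix <- function(a) {
  rows <- aln_rows(a)
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' states (A, C, G, T) are each carried by at least two taxa. Gaps, `?` and
#' ambiguity codes are missing data and never count as a state.
#'
#' @param alignment a `locus_alignment` or named character vector of rows.
#' @return integer count of informative columns.
#' @export
informative_sites <- function(alignment) {
  m <- aln_char_matrix(alignment)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1)
  sum(rowSums(counts >= 2) >= 2)
}

#' Summary statistics over a set of locus alignments
#'
#' Reports alignment counts, mean length with a 95% CI half-width
#' (1.96 x sample SD / sqrt(n)), mean taxon occupancy, and total
#' parsimony-informative sites, along with a per-locus table.
#'
#' @param alignments list of `locus_alignment` objects.
#' @return list with `overall` (one-row data.frame) and `per_locus`.
#' @export
summary_stats <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  per <- do.call(rbind, lapply(alignments, function(a) {
    rows <- aln_rows(a)
    data.frame(locus_id = if (inherits(a, "locus_alignment")) a$locus_id else NA,
               length = nchar(rows[[1]]), n_taxa = length(rows),
               informative_sites = informative_sites(a),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(per)
  ci <- function(x) if (n > 1) 1.96 * sd(x) / sqrt(n) else 0
  overall <- data.frame(
    n_loci = n, mean_length = mean(per$length), ci95_length = ci(per$length),
    mean_taxa = mean(per$n_taxa), ci95_taxa = ci(per$n_taxa),
    total_informative = sum(per$informative_sites),
    single_alignment = n == 1)
  list(overall = overall, per_locus = per)
}

#' Concatenate locus alignments into a supermatrix
#'
#' Loci are ordered lexicographically by id; taxa absent from a locus are
#' filled with `?` across that charset (distinguishing absent taxa from
#' alignment gaps `-`).
#'
#' @param alignments list of `locus_alignment` objects.
#' @param taxa_universe optional character vector fixing the row set and
#'   order; defaults to the union of taxa seen, sorted.
#' @return object of class `supermatrix`: list with `taxa`, `rows` (named
#'   character vector), `charsets` (locus_id, start, end; 1-based inclusive).
#' @export
concat_alignments <- function(alignments, taxa_universe = NULL) {
  stopifnot(length(alignments) >= 1)
  ids <- vapply(alignments, function(a) a$locus_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  alignments <- alignments[order(ids)]
  ids <- sort(ids)
  taxa <- taxa_universe %||% sort(unique(unlist(lapply(alignments,
                                                       function(a) names(a$rows)))))
  pieces <- matrix("", nrow = length(taxa), ncol = length(alignments),
                   dimnames = list(taxa, NULL))
  lens <- integer(length(alignments))
  for (k in seq_along(alignments)) {
    rows <- alignments[[k]]$rows
    extra <- setdiff(names(rows), taxa)
    if (length(extra)) stop("taxa outside universe: ", paste(extra, collapse = ", "))
    L <- nchar(rows[[1]])
    lens[k] <- L
    fill <- strrep("?", L)
    pieces[, k] <- fill
    pieces[names(rows), k] <- unname(rows)
  }
  ends <- cumsum(lens)
  charsets <- data.frame(locus_id = ids, start = ends - lens + 1L, end = ends,
                         stringsAsFactors = FALSE)
  rows <- apply(pieces, 1, paste, collapse = "")
  structure(list(taxa = taxa, rows = rows, charsets = charsets),
            class = "supermatrix")
}

supermatrix_from_rows <- function(rows, charsets) {
  structure(list(taxa = names(rows), rows = rows, charsets = charsets),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x", nchar(x$rows[[1]]), "sites,",
      nrow(x$charsets), "loci\n")
  invisible(x)
}

#' Extract one locus back out of a supermatrix
#'
#' @param sm a `supermatrix`.
#' @param locus_id charset to extract.
#' @param drop_missing drop taxa whose extracted row is all `?`.
#' @return a `locus_alignment`.
#' @export
extract_charset <- function(sm, locus_id, drop_missing = TRUE) {
  cs <- sm$charsets[sm$charsets$locus_id == locus_id, , drop = FALSE]
  if (nrow(cs) != 1) stop("unknown locus: ", locus_id)
  rows <- substr(sm$rows, cs$start, cs$end)
  names(rows) <- names(sm$rows)
  if (drop_missing) {
    rows <- rows[rows != strrep("?", cs$end - cs$start + 1L)]
  }
  locus_alignment(locus_id, rows)
}

# mean pairwise identity per column; gaps and missing count as mismatching
column_pairwise_identity <- function(m) {
  n <- nrow(m)
  total_pairs <- choose(n, 2)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1)
  match_pairs <- rowSums(choose(counts, 2))
  match_pairs / total_pairs
}

#' Edge-trim an alignment by sliding-window identity
#'
#' A simple fallback trimmer: columns are removed from each end until a
#' window of `window` columns reaches a mean pairwise identity of at least
#' `min_identity`; interior columns are never touched. This is not
#' equivalent to dedicated trimming tools (no internal trimming, no
#' gap-based heuristics) and pre-trimmed alignments can be supplied instead.
#'
#' @param alignment a `locus_alignment`.
#' @param window window width in columns, default 20.
#' @param min_identity mean pairwise identity required, default 0.5.
#' @return trimmed `locus_alignment`, or `NULL` with a warning when nothing
#'   passes.
#' @export
edge_trim <- function(alignment, window = 20, min_identity = 0.5) {
  m <- aln_char_matrix(alignment)
  nc <- ncol(m)
  stopifnot(nc >= window)
  colid <- column_pairwise_identity(m)
  wmean <- vapply(seq_len(nc - window + 1L), function(i) {
    mean(colid[i:(i + window - 1L)])
  }, numeric(1))
  # a kept edge needs a qualifying window whose boundary column itself
  # qualifies, so e.g. leading all-gap columns are never retained
  wi <- seq_along(wmean)
  ok_left <- which(wmean >= min_identity & colid[wi] >= min_identity)
  ok_right <- which(wmean >= min_identity & colid[wi + window - 1L] >= min_identity)
  if (!length(ok_left) || !length(ok_right)) {
    warning("edge_trim removed the entire alignment")
    return(NULL)
  }
  from <- min(ok_left)
  to <- max(ok_right) + window - 1L
  rows <- substr(aln_rows(alignment), from, to)
  names(rows) <- names(aln_rows(alignment))
  locus_alignment(alignment$locus_id, rows)
}

#' Split a monolithic UCE FASTA into per-locus alignments
#'
#' Records named `"uce-N_taxon"` (as written by [get_fastas()]) are grouped
#' by locus. Sequences must already be aligned within each locus for the
#' result to be valid `locus_alignment`s; unaligned groups are returned as
#' plain named vectors.
#'
#' @param records named character vector (or FASTA path).
#' @return named list: locus -> named character vector of taxon sequences.
#' @export
split_by_locus <- function(records) {
  if (is.character(records) && length(records) == 1 && file.exists(records[1])) {
    records <- read_fasta(records, check = FALSE)
  }
  locus <- sub("_[^_]+$", "", names(records))
  taxon <- sub("^.*_", "", names(records))
  out <- split(setNames(unname(records), taxon), locus)
  out[sort(names(out))]
}
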