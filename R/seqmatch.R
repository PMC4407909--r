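# Local-similarity engine: exact Smith-Waterman (match +1, mismatch -1,
# linear gap -2) computed in C++, both strands. All duplicate screening and
# bait/contig matching criteria in the toolkit reduce to identity and
# coverage decisions on these alignments.

sw_stats <- function(query, target) {
  r <- .sw_align(query, target)
  r$identity <- if (r$n_col > 0) r$n_match / r$n_col else 0
  r
}

#' Local alignment matches between a query and a set of targets
#'
#' Aligns `query` against each target on both strands and reports hits whose
#' identity (matching columns / aligned columns) and coverage (aligned span
#' on the coverage-basis sequence / its full length) meet the thresholds.
#' The better-scoring strand is reported per target. A trivial self-match
#' (target named identically to `query_id`) is excluded.
#'
#' @param query a single sequence (character string).
#' @param targets named character vector of target sequences.
#' @param min_identity,min_coverage thresholds in (0, 1].
#' @param coverage_basis `"query"` or `"target"`: which sequence's length the
#'   aligned span is divided by.
#' @param strict use strict `>` comparisons instead of `>=` (the duplicate
#'   screens follow a "more than" wording; contig matching uses `>=`).
#' @param query_id id of the query (for self-match exclusion and output).
#' @return data.frame with one row per matching target: `query_id`,
#'   `target_id`, `identity`, `coverage`, `strand`, spans (0-based
#'   half-open, target span always on the + strand), `score`.
#' @export
local_matches <- function(query, targets, min_identity = 0.8,
                          min_coverage = 0.8,
                          coverage_basis = c("query", "target"),
                          strict = FALSE, query_id = NA_character_) {
  coverage_basis <- match.arg(coverage_basis)
  stopifnot(nchar(query) > 0, min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  out <- empty_match_df()
  if (length(targets) == 0) return(out)
  stopifnot(!is.null(names(targets)))
  ok <- if (strict) function(x, t) x > t else function(x, t) x >= t
  for (tid in names(targets)) {
    if (!is.na(query_id) && identical(tid, query_id)) next
    tseq <- targets[[tid]]
    m <- nchar(tseq)
    fwd <- sw_stats(query, tseq)
    rev <- sw_stats(query, revcomp(tseq))
    for (strand in c("+", "-")) {
      r <- if (strand == "+") fwd else rev
      if (r$n_col == 0) next
      tspan <- c(r$t_start, r$t_end)
      if (strand == "-") tspan <- c(m - r$t_end, m - r$t_start)
      cov_len <- if (coverage_basis == "query") r$q_end - r$q_start else tspan[2] - tspan[1]
      cov <- cov_len / (if (coverage_basis == "query") nchar(query) else m)
      if (ok(r$identity, min_identity) && ok(cov, min_coverage)) {
        out <- rbind(out, data.frame(
          query_id = query_id, target_id = tid, identity = r$identity,
          coverage = cov, strand = strand, q_start = r$q_start,
          q_end = r$q_end, t_start = tspan[1], t_end = tspan[2],
          score = r$score, stringsAsFactors = FALSE))
      }
    }
  }
  # keep the better strand when both qualify for the same target
  if (nrow(out) > 1) {
    keep <- !logical(nrow(out))
    for (tid in unique(out$target_id)) {
      idx <- which(out$target_id == tid)
      if (length(idx) > 1) keep[idx[-which.max(out$score[idx])]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_match_df <- function() {
  data.frame(query_id = character(), target_id = character(),
             identity = numeric(), coverage = numeric(), strand = character(),
             q_start = integer(), q_end = integer(), t_start = integer(),
             t_end = integer(), score = numeric(), stringsAsFactors = FALSE)
}

#' Screen a set of regions for duplicate-like pairs
#'
#' All-against-all comparison; any pair that is *more than* `min_identity`
#' identical over *more than* `min_coverage` of the shorter member's length
#' causes removal of BOTH members (ambiguous paralogs are unsafe as capture
#' targets). Reverse-complement matches count.
#'
#' @param regions named character vector of region residues (unique ids), or
#'   a data.frame with columns `name` and `residues`.
#' @param min_identity,min_coverage thresholds, compared strictly (`>`).
#' @return list with `kept` and `removed` (character vectors of ids,
#'   partitioning the input) and `pairs` (data.frame of offending pairs).
#' @export
screen_duplicates <- function(regions, min_identity = 0.80, min_coverage = 0.50) {
  if (is.data.frame(regions)) {
    regions <- setNames(regions$residues, regions$name)
  }
  ids <- names(regions)
  if (is.null(ids) || anyDuplicated(ids)) stop("regions must carry unique ids")
  n <- length(regions)
  dup <- character(0)
  pairs <- data.frame(id1 = character(), id2 = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  ord <- order(ids)  # deterministic pair order regardless of input order
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in seq((a + 1), n)) {
      j <- ord[b]
      hit <- duplicate_pair(regions[[i]], regions[[j]],
                            min_identity, min_coverage)
      if (!is.null(hit)) {
        dup <- union(dup, c(ids[i], ids[j]))
        pairs <- rbind(pairs, data.frame(
          id1 = min(ids[i], ids[j]), id2 = max(ids[i], ids[j]),
          identity = hit$identity, coverage = hit$coverage,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(kept = setdiff(ids, dup), removed = ids[ids %in% dup], pairs = pairs)
}

# strict-threshold pair decision, coverage on the shorter member
duplicate_pair <- function(x, y, min_identity, min_coverage) {
  shorter <- min(nchar(x), nchar(y))
  for (tgt in c(y, revcomp(y))) {
    r <- sw_stats(x, tgt)
    if (r$n_col == 0) next
    span <- if (nchar(x) <= nchar(y)) r$q_end - r$q_start else r$t_end - r$t_start
    cov <- span / shorter
    if (r$identity > min_identity && cov > min_coverage) {
      return(list(identity = r$identity, coverage = cov))
    }
  }
  NULL
}
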