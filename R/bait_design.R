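#' Buffer a conserved region to the bait-design target length
#'
#' Regions shorter than `target_len` are padded with equal amounts of 5' and
#' 3' flanking sequence from the design genome (an odd remainder's extra
#' base goes 3'). When padding runs off a sequence end the deficit is
#' shifted to the other side; if the sequence itself is too short the locus
#' is returned clamped and flagged rather than erroring.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open on the design genome).
#' @param genome named character vector of design-genome sequences.
#' @param target_len buffered locus length, default 180.
#' @param locus_id id to assign (e.g. `"uce-1"`).
#' @return one-row data.frame: `locus_id`, `chrom`, `start`, `end`,
#'   `residues` (case preserved from the genome), `flagged`.
#' @export
buffer_region <- function(region, genome, target_len = 180,
                          locus_id = NA_character_) {
  chrom <- region$chrom
  if (!chrom %in% names(genome)) stop("region chrom not in genome: ", chrom)
  seqlen <- nchar(genome[[chrom]])
  s <- region$start
  e <- region$end
  stopifnot(s >= 0, e <= seqlen, s < e)
  pad <- target_len - (e - s)
  flagged <- FALSE
  if (pad > 0) {
    left <- pad %/% 2
    right <- pad - left       # odd remainder's extra base goes 3'
    s2 <- s - left
    e2 <- e + right
    if (s2 < 0) { e2 <- e2 - s2; s2 <- 0 }
    if (e2 > seqlen) { s2 <- s2 - (e2 - seqlen); e2 <- seqlen }
    if (s2 < 0) { s2 <- 0; flagged <- TRUE }
    s <- s2
    e <- e2
  }
  data.frame(locus_id = locus_id, chrom = chrom, start = s, end = e,
             residues = slice0(genome[[chrom]], s, e), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Tile enrichment baits across a locus
#'
#' Baits of `bait_len` start at offsets 0, `stride`, 2·`stride`, ...;
#' 2X tiling density is the default (120-nt baits overlapping by 60 bp). If
#' the last regular bait does not reach the locus 3' end one extra bait is
#' placed flush with the 3' end, so the whole locus is always covered. A
#' locus shorter than `bait_len` yields no baits.
#'
#' @param locus one-row data.frame from [buffer_region()].
#' @param bait_len bait length, default 120.
#' @param stride offset between bait starts, default 60.
#' @return data.frame with one row per bait: `bait_id` (`"uce-N_pK"`),
#'   `locus_id`, `index`, `chrom`, `start`, `end`, `residues` (case as in
#'   the locus; uppercased on final output).
#' @export
tile_baits <- function(locus, bait_len = 120, stride = 60) {
  L <- nchar(locus$residues)
  if (L < bait_len) return(empty_bait_df())
  offsets <- seq(0L, L - bait_len, by = stride)
  if (max(offsets) + bait_len < L) offsets <- c(offsets, L - bait_len)
  data.frame(
    bait_id = sprintf("%s_p%d", locus$locus_id, seq_along(offsets)),
    locus_id = locus$locus_id, index = seq_along(offsets),
    chrom = locus$chrom, start = locus$start + offsets,
    end = locus$start + offsets + bait_len,
    residues = substring(locus$residues, offsets + 1L, offsets + bait_len),
    stringsAsFactors = FALSE)
}

empty_bait_df <- function() {
  data.frame(bait_id = character(), locus_id = character(), index = integer(),
             chrom = character(), start = integer(), end = integer(),
             residues = character(), stringsAsFactors = FALSE)
}

#' Bait quality filters
#'
#' A bait fails if it contains any ambiguous base call, if its soft-masked
#' (lowercase) fraction exceeds `max_repeat`, or if its GC fraction
#' (case-insensitive) exceeds `max_gc`. Both filters are strict
#' inequalities, so a bait at exactly 25% repeat or 70% GC passes.
#'
#' @param residues character vector of bait sequences (case meaningful).
#' @param max_repeat maximum tolerated lowercase fraction, default 0.25.
#' @param max_gc maximum tolerated GC fraction, default 0.70.
#' @return data.frame with logical `pass` and a `reasons` character column
#'   (comma-joined subset of `ambiguity`, `repeat`, `gc`).
#' @export
filter_baits <- function(residues, max_repeat = 0.25, max_gc = 0.70) {
  n <- nchar(residues)
  ambig <- grepl("[^ACGTacgt]", residues)
  lower <- vapply(residues, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% letters)
  }, integer(1), USE.NAMES = FALSE) / n
  gc <- vapply(residues, function(s) {
    sum(strsplit(toupper(s), "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, integer(1), USE.NAMES = FALSE) / n
  reasons <- mapply(function(a, l, g) {
    paste(c(if (a) "ambiguity", if (l > max_repeat) "repeat",
            if (g > max_gc) "gc"), collapse = ",")
  }, ambig, lower, gc)
  data.frame(pass = !ambig & lower <= max_repeat & gc <= max_gc,
             reasons = unname(reasons), stringsAsFactors = FALSE)
}

#' Remove duplicate baits from a bait set
#'
#' Exact sequence duplicates (case-insensitive) are collapsed, keeping the
#' bait with the lowest locus number, then the lowest index. Remaining
#' cross-locus near-duplicates (identity > `min_identity` over coverage
#' > `min_coverage` of the shorter bait, either strand) cause removal of
#' both members; pairs from the same locus are exempt, because 2X tiling
#' guarantees neighbours overlap by half their length.
#'
#' @param baits data.frame from [tile_baits()] (rows may span many loci).
#' @param min_identity,min_coverage strict thresholds for the near-duplicate
#'   screen; defaults mirror the locus-level duplicate screen.
#' @return list with `kept` and `removed` data.frames and a `log` of
#'   removal reasons.
#' @export
dedupe_baits <- function(baits, min_identity = 0.80, min_coverage = 0.50) {
  if (anyDuplicated(baits$bait_id)) stop("bait ids must be unique")
  if (nrow(baits) == 0) {
    return(list(kept = baits, removed = baits, log = character(0)))
  }
  locus_num <- as.integer(sub("^uce-", "", baits$locus_id))
  ord <- order(locus_num, baits$index)
  baits <- baits[ord, , drop = FALSE]

  seqs_up <- toupper(baits$residues)
  exact_removed <- duplicated(seqs_up)
  log <- sprintf("%s exact-duplicate-of %s", baits$bait_id[exact_removed],
                 baits$bait_id[match(seqs_up[exact_removed], seqs_up)])
  surv <- baits[!exact_removed, , drop = FALSE]

  near <- logical(nrow(surv))
  n <- nrow(surv)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (surv$locus_id[i] == surv$locus_id[j]) next
        hit <- duplicate_pair(surv$residues[i], surv$residues[j],
                              min_identity, min_coverage)
        if (!is.null(hit)) {
          near[c(i, j)] <- TRUE
          log <- c(log, sprintf("%s near-duplicate %s (identity %.3f)",
                                surv$bait_id[i], surv$bait_id[j], hit$identity))
        }
      }
    }
  }
  removed <- rbind(baits[exact_removed, , drop = FALSE],
                   surv[near, , drop = FALSE])
  list(kept = surv[!near, , drop = FALSE], removed = removed, log = log)
}

#' Full bait-design pipeline: buffer, tile, filter, dedupe
#'
#' Takes screened (non-duplicated) conserved regions and a design genome,
#' assigns locus ids `uce-1..n` in genome order, buffers each region to
#' `buffer_to`, tiles baits, applies the ambiguity/repeat/GC filters, and
#' removes duplicate baits. Loci left with no surviving bait are dropped and
#' reported.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (e.g. the kept set
#'   after [screen_duplicates()]), or a path to a BED4 file.
#' @param genome named character vector (design genome), or FASTA path.
#' @param buffer_to,bait_len,stride,max_repeat,max_gc,min_identity,min_coverage
#'   stage parameters; defaults are the standard design values.
#' @param out optional FASTA path for the final bait set (residues
#'   uppercased, headers `"uce-N_pK |chrom:start-end"`).
#' @return list: `baits` (final data.frame), `loci`, `dropped_loci`,
#'   `report` (named integer vector of per-stage counts).
#' @export
design_baits <- function(regions, genome, buffer_to = 180, bait_len = 120,
                         stride = 60, max_repeat = 0.25, max_gc = 0.70,
                         min_identity = 0.80, min_coverage = 0.50, out = NULL) {
  if (is.character(regions) && length(regions) == 1) regions <- read_bed(regions)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome[1])) {
    genome <- read_fasta(genome)
  }
  if (nrow(regions) == 0) {
    warning("empty conserved-region set: designing zero baits")
    return(list(baits = empty_bait_df(), loci = NULL, dropped_loci = character(0),
                report = c(regions = 0L, loci = 0L, baits_tiled = 0L,
                           baits_filtered = 0L, baits_final = 0L)))
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  loci <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    buffer_region(regions[i, ], genome, target_len = buffer_to,
                  locus_id = sprintf("uce-%d", i))
  }))
  tiled <- do.call(rbind, c(list(empty_bait_df()),
                            lapply(seq_len(nrow(loci)), function(i) {
                              tile_baits(loci[i, ], bait_len, stride)
                            })))
  filt <- filter_baits(tiled$residues, max_repeat = max_repeat, max_gc = max_gc)
  passed <- tiled[filt$pass, , drop = FALSE]
  dd <- dedupe_baits(passed, min_identity = min_identity,
                     min_coverage = min_coverage)
  final <- dd$kept
  dropped <- setdiff(loci$locus_id, unique(final$locus_id))
  report <- c(regions = nrow(regions), loci = nrow(loci),
              baits_tiled = nrow(tiled), baits_filtered = nrow(passed),
              baits_final = nrow(final), loci_dropped = length(dropped))
  message("stage=design in=", nrow(regions), " out=", nrow(final))
  if (!is.null(out) && nrow(final) > 0) {
    headers <- sprintf("%s |%s:%d-%d", final$bait_id, final$chrom,
                       final$start, final$end)
    write_fasta(setNames(toupper(final$residues), headers), out)
  }
  list(baits = final, loci = loci, dropped_loci = dropped, report = report)
}
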