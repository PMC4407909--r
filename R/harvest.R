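# Matching assembled contigs (or genome slices) back to the bait set, with
# the two orthology-protection rules applied per taxon:
#   1. a contig hit by baits of >= 2 distinct loci is removed ("multi-locus")
#   2. a locus hit by >= 2 surviving contigs is marked absent for that taxon
#      ("duplicate-contig")
# Survivors populate a two-table relational store: a locus x taxon presence
# table and a (locus, taxon) -> contig name map.

locus_of_bait <- function(bait_id) {
  locus <- sub("_p\\d+$", "", bait_id)
  bad <- !grepl("^.+_p\\d+$", bait_id)
  if (any(bad)) {
    stop("bait id(s) not parseable to a locus: ",
         paste(bait_id[bad], collapse = ", "))
  }
  locus
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# all bait hits against one taxon's contigs; coverage on the bait.
# A shared-k-mer prefilter (k = 14) skips contig/bait pairs with no exact
# 14-mer in common on either strand; pairs passing the identity threshold
# share many, so this only prunes hopeless comparisons.
bait_hits <- function(contigs, baits, min_identity, min_coverage) {
  hits <- list()
  contig_ids <- names(contigs)
  contigs_up <- toupper(unname(contigs))
  rc <- revcomp(contigs_up)
  k <- min(14L, min(nchar(baits)))
  pairs <- lapply(seq_along(contigs_up), function(ci) {
    kms <- unique(c(kmer_set(contigs_up[ci], k), kmer_set(rc[ci], k)))
    list(km = kms, ci = rep.int(ci, length(kms)))
  })
  kmap <- split(unlist(lapply(pairs, `[[`, "ci"), use.names = FALSE),
                unlist(lapply(pairs, `[[`, "km"), use.names = FALSE))
  for (b in seq_along(baits)) {
    bseq <- toupper(baits[[b]])
    blen <- nchar(bseq)
    cand <- sort(unique(unlist(kmap[kmer_set(bseq, k)], use.names = FALSE)))
    if (!length(cand)) next
    fwd <- .sw_align_many(bseq, contigs_up[cand])
    rev <- .sw_align_many(bseq, rc[cand])
    for (strand in c("+", "-")) {
      m <- if (strand == "+") fwd else rev
      identity <- ifelse(m[, "n_col"] > 0, m[, "n_match"] / m[, "n_col"], 0)
      coverage <- (m[, "q_end"] - m[, "q_start"]) / blen
      ok <- identity >= min_identity & coverage >= min_coverage
      if (any(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          bait_id = names(baits)[b], contig_id = contig_ids[cand][ok],
          identity = identity[ok], coverage = coverage[ok], strand = strand,
          t_start = m[ok, "t_start"], t_end = m[ok, "t_end"],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(bait_id = character(), contig_id = character(),
                      identity = numeric(), coverage = numeric(),
                      strand = character(), t_start = integer(),
                      t_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Match per-taxon contig assemblies to UCE loci
#'
#' Aligns every bait to every contig of every taxon (both strands), keeps
#' hits at `min_identity` identity over `min_coverage` of the bait, collapses
#' multiple bait hits per (contig, locus) to the best one, then applies the
#' chimera and duplicate screens described above.
#'
#' @param contigs named list: taxon -> named character vector of contig
#'   sequences. Entries may also be FASTA paths.
#' @param baits bait set: data.frame from [design_baits()] (`bait_id`,
#'   `residues`), named character vector, or FASTA path. Bait ids must have
#'   the form `"<locus>_pK"`.
#' @param min_identity,min_coverage match thresholds, default 0.80 / 0.80
#'   (coverage on the bait).
#' @return a `match_db` object: list with `presence` (locus x taxon logical
#'   matrix), `name_map` (locus, taxon, contig, identity, strand),
#'   `removal_log` (taxon, item, reason).
#' @export
match_contigs_to_loci <- function(contigs, baits, min_identity = 0.80,
                                  min_coverage = 0.80) {
  baits <- as_bait_vector(baits)
  loci <- sort(unique(locus_of_bait(names(baits))))
  taxa <- names(contigs)
  stopifnot(!is.null(taxa), all(nzchar(taxa)))
  presence <- matrix(FALSE, nrow = length(loci), ncol = length(taxa),
                     dimnames = list(loci, taxa))
  name_map <- data.frame(locus_id = character(), taxon = character(),
                         contig_id = character(), identity = numeric(),
                         strand = character(), stringsAsFactors = FALSE)
  removal_log <- data.frame(taxon = character(), item = character(),
                            reason = character(), stringsAsFactors = FALSE)
  for (taxon in taxa) {
    ctg <- contigs[[taxon]]
    if (is.character(ctg) && length(ctg) == 1 && file.exists(ctg[1])) {
      ctg <- read_fasta(ctg)
    }
    hits <- bait_hits(ctg, baits, min_identity, min_coverage)
    if (nrow(hits) == 0) next
    hits$locus_id <- locus_of_bait(hits$bait_id)
    # best hit per (contig, locus); multiple baits of one locus hitting one
    # contig are the norm under 2X tiling and count as one locus-level match
    hits <- hits[order(-hits$identity, -hits$coverage), , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("contig_id", "locus_id")]), , drop = FALSE]

    multi <- tapply(hits$locus_id, hits$contig_id,
                    function(l) length(unique(l)))
    chimeric <- names(multi)[multi >= 2]
    if (length(chimeric)) {
      removal_log <- rbind(removal_log, data.frame(
        taxon = taxon, item = chimeric, reason = "multi-locus",
        stringsAsFactors = FALSE))
      hits <- hits[!hits$contig_id %in% chimeric, , drop = FALSE]
    }
    ncontigs <- tapply(hits$contig_id, hits$locus_id,
                       function(ct) length(unique(ct)))
    dup_loci <- names(ncontigs)[ncontigs >= 2]
    if (length(dup_loci)) {
      removal_log <- rbind(removal_log, data.frame(
        taxon = taxon, item = dup_loci, reason = "duplicate-contig",
        stringsAsFactors = FALSE))
      hits <- hits[!hits$locus_id %in% dup_loci, , drop = FALSE]
    }
    if (nrow(hits)) {
      presence[cbind(hits$locus_id, taxon)] <- TRUE
      name_map <- rbind(name_map, data.frame(
        locus_id = hits$locus_id, taxon = taxon, contig_id = hits$contig_id,
        identity = hits$identity, strand = hits$strand,
        stringsAsFactors = FALSE))
    }
  }
  db <- structure(list(presence = presence, name_map = name_map,
                       removal_log = removal_log,
                       params = list(min_identity = min_identity,
                                     min_coverage = min_coverage)),
                  class = "match_db")
  message("stage=harvest in=", sum(lengths(contigs)),
          " out=", sum(presence))
  db
}

as_bait_vector <- function(baits) {
  if (is.data.frame(baits)) {
    return(setNames(toupper(baits$residues), baits$bait_id))
  }
  if (is.character(baits) && length(baits) == 1 && file.exists(baits[1])) {
    b <- read_fasta(baits)
    return(toupper(b))
  }
  stopifnot(is.character(baits), !is.null(names(baits)))
  toupper(baits)
}

#' @export
print.match_db <- function(x, ...) {
  cat("UCE match database:", nrow(x$presence), "loci x",
      ncol(x$presence), "taxa;", sum(x$presence), "matches,",
      nrow(x$removal_log), "removals\n")
  invisible(x)
}

#' Write / read a match database as a two-table relational store
#'
#' `presence.csv` holds the detection status of each locus in each taxon;
#' `name_map.csv` maps contig names to loci; `removal_log.csv` records
#' screened-out items.
#'
#' @param db a `match_db`.
#' @param dir directory to hold the tables.
#' @return `dir` (or the `match_db` for the reader), invisibly.
#' @export
write_match_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pres <- data.frame(locus_id = rownames(db$presence),
                     db$presence + 0L, check.names = FALSE)
  write.csv(pres, file.path(dir, "presence.csv"), row.names = FALSE)
  write.csv(db$name_map, file.path(dir, "name_map.csv"), row.names = FALSE)
  write.csv(db$removal_log, file.path(dir, "removal_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_match_db
#' @export
read_match_db <- function(dir) {
  pres <- read.csv(file.path(dir, "presence.csv"), check.names = FALSE)
  m <- as.matrix(pres[, -1, drop = FALSE]) > 0
  rownames(m) <- pres$locus_id
  structure(list(presence = m,
                 name_map = read.csv(file.path(dir, "name_map.csv"),
                                     stringsAsFactors = FALSE),
                 removal_log = read.csv(file.path(dir, "removal_log.csv"),
                                        stringsAsFactors = FALSE),
                 params = list()),
            class = "match_db")
}

#' Loci shared by a minimum fraction of taxa
#'
#' @param db a `match_db`.
#' @param taxa taxa to consider (must all be in the database).
#' @param min_fraction completeness fraction; a locus is kept when present
#'   in at least `ceiling(min_fraction * length(taxa))` of them (so 0.70 of
#'   14 taxa means at least 10, and 0.75 of 44 means at least 33).
#' @return sorted character vector of locus ids.
#' @export
get_match_counts <- function(db, taxa, min_fraction) {
  unknown <- setdiff(taxa, colnames(db$presence))
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  stopifnot(min_fraction > 0, min_fraction <= 1)
  threshold <- ceiling(min_fraction * length(taxa))
  counts <- rowSums(db$presence[, taxa, drop = FALSE])
  sort(rownames(db$presence)[counts >= threshold])
}

#' Export a monolithic FASTA of all UCE sequence data for all taxa
#'
#' One record per credited (locus, taxon) pair, header `"uce-N_taxon"`,
#' locus-major order then taxon order as in the database.
#'
#' @param db a `match_db`.
#' @param sequences named list: taxon -> named character vector of contig or
#'   slice sequences (keyed by contig id as in the name map).
#' @param loci locus ids to export (e.g. from [get_match_counts()]).
#' @param out optional FASTA path.
#' @return named character vector of records.
#' @export
get_fastas <- function(db, sequences, loci, out = NULL) {
  recs <- character(0)
  for (locus in loci) {
    for (taxon in colnames(db$presence)) {
      if (!db$presence[locus, taxon]) next
      row <- db$name_map[db$name_map$locus_id == locus &
                           db$name_map$taxon == taxon, , drop = FALSE]
      idx <- match(row$contig_id[1], names(sequences[[taxon]]))
      if (is.na(idx)) {
        stop("missing sequence for credited pair (", locus, ", ", taxon, ")")
      }
      seq <- sequences[[taxon]][[idx]]
      recs[[paste0(locus, "_", taxon)]] <- seq
    }
  }
  if (!is.null(out)) write_fasta(recs, out)
  recs
}

#' Slice UCE loci (plus flank) out of a genome using the bait set
#'
#' Locates each bait on the genome (exact-seed search followed by local
#' alignment in a window), merges overlapping bait hits of one locus into
#' candidate sites, and makes a first pass at duplicate removal: a locus
#' matching two or more distinct genomic sites is dropped and logged. Each
#' surviving site is emitted with `flank` bases of 5' and 3' flanking
#' sequence, clamped at sequence ends; minus-strand sites are
#' reverse-complemented into bait orientation.
#'
#' @param genome named character vector of sequences (or FASTA path).
#' @param baits bait set as in [match_contigs_to_loci()].
#' @param flank flanking bases retained on each side, default 1000.
#' @param min_identity,min_coverage bait-hit thresholds (coverage on bait).
#' @param seed_len exact seed length for the window search, default 20.
#' @return list: `slices` (named character vector, one per locus) and `log`
#'   (data.frame of dropped loci).
#' @export
slice_from_genome <- function(genome, baits, flank = 1000,
                              min_identity = 0.80, min_coverage = 0.80,
                              seed_len = 20) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome[1])) {
    genome <- read_fasta(genome)
  }
  baits <- as_bait_vector(baits)
  loci <- sort(unique(locus_of_bait(names(baits))))
  hits <- list()
  for (chrom in names(genome)) {
    gseq <- toupper(genome[[chrom]])
    glen <- nchar(gseq)
    for (b in names(baits)) {
      bseq <- baits[[b]]
      blen <- nchar(bseq)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") bseq else revcomp(bseq)
        starts <- seed_positions(q, gseq, seed_len)
        for (w0 in starts) {
          ws <- max(0L, w0 - blen - 80L)
          we <- min(glen, w0 + 2L * blen + 80L)
          r <- sw_stats(q, slice0(gseq, ws, we))
          cov <- (r$q_end - r$q_start) / blen
          if (r$identity >= min_identity && cov >= min_coverage) {
            hits[[length(hits) + 1L]] <- data.frame(
              locus_id = locus_of_bait(b), chrom = chrom,
              start = ws + r$t_start, end = ws + r$t_end, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  log <- data.frame(locus_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  slices <- character(0)
  if (length(hits)) {
    hits <- unique(do.call(rbind, hits))
    for (locus in unique(hits$locus_id)) {
      h <- hits[hits$locus_id == locus, , drop = FALSE]
      sites <- merge_intervals(h)
      if (nrow(sites) > 1) {
        log <- rbind(log, data.frame(locus_id = locus,
                                     reason = "multiple-genomic-sites",
                                     stringsAsFactors = FALSE))
        next
      }
      s <- max(0L, sites$start[1] - flank)
      e <- min(nchar(genome[[sites$chrom[1]]]), sites$end[1] + flank)
      seq <- slice0(genome[[sites$chrom[1]]], s, e)
      if (sites$strand[1] == "-") seq <- revcomp(seq)
      slices[[locus]] <- seq
    }
  }
  message("stage=slice in=", length(baits), " out=", length(slices))
  list(slices = slices, log = log)
}

seed_positions <- function(query, target, seed_len) {
  n <- nchar(query)
  offs <- seq(0L, max(0L, n - seed_len), by = seed_len)
  pos <- integer(0)
  for (o in offs) {
    seed <- substr(query, o + 1L, min(n, o + seed_len))
    m <- gregexpr(seed, target, fixed = TRUE)[[1]]
    if (m[1] != -1L) pos <- c(pos, m - 1L - o)
  }
  # collapse seed hits pointing at (nearly) the same placement
  sort(unique(pmax(0L, pos - pos %% 50L)))
}

merge_intervals <- function(h) {
  h <- h[order(h$chrom, h$start), , drop = FALSE]
  out <- h[0, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    n <- nrow(out)
    if (n > 0 && out$chrom[n] == h$chrom[i] && h$start[i] <= out$end[n]) {
      out$end[n] <- max(out$end[n], h$end[i])
    } else {
      out <- rbind(out, h[i, , drop = FALSE])
    }
  }
  out
}
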