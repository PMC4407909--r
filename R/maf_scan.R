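#' Find perfectly conserved regions within one MAF block
#'
#' Scans alignment columns for maximal runs where every row carries the
#' identical, unambiguous nucleotide (case-insensitive; gaps and 'N' break a
#' run) and keeps runs strictly longer than `min_len`, matching the
#' "longer than `min_len` base pairs" criterion. Coordinates are reported on
#' the first row's source in + strand space, 0-based half-open.
#'
#' @param block a [maf_block] with at least 2 rows.
#' @param min_len minimum length; runs must be strictly longer. Default 40.
#' @param origin_block index recorded in the output (bookkeeping).
#' @return data.frame with columns `chrom`, `start`, `end`, `length`,
#'   `residues` (uppercase, + strand), `lowercase_frac` (soft-masked fraction
#'   seen in the first row; regions above 0.25 are candidates for the bait
#'   repeat filter, not discarded here), `origin_block`.
#' @export
find_conserved <- function(block, min_len = 40, origin_block = NA_integer_) {
  stopifnot(inherits(block, "maf_block") || is.data.frame(block))
  if (nrow(block) < 2) stop("nothing to compare: MAF block has a single row")
  chars <- do.call(rbind, strsplit(block$text, "", fixed = TRUE))
  up <- toupper(chars)
  conserved <- apply(up, 2, function(col) {
    col[1] %in% c("A", "C", "G", "T") && all(col == col[1])
  })
  runs <- rle(conserved)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths > min_len)
  out <- empty_region_df()
  if (!length(keep)) return(out)

  # map alignment columns to row-1 source positions (non-gap columns only)
  row1 <- chars[1, ]
  nongap <- row1 != "-"
  srcpos <- integer(ncol(chars))
  srcpos[nongap] <- block$start[1] + seq_len(sum(nongap)) - 1L
  strand <- block$strand[1]
  src_size <- block$src_size[1]

  for (k in keep) {
    c1 <- starts[k]; c2 <- ends[k]
    s <- srcpos[c1]; e <- srcpos[c2] + 1L
    res <- paste(up[1, c1:c2], collapse = "")
    lc <- mean(row1[c1:c2] %in% c("a", "c", "g", "t", "n"))
    if (strand == "-") {
      tmp <- src_size - e
      e <- src_size - s
      s <- tmp
      res <- revcomp(res)
    }
    out <- rbind(out, data.frame(
      chrom = block$src[1], start = s, end = e, length = e - s,
      residues = res, lowercase_frac = lc, origin_block = origin_block,
      stringsAsFactors = FALSE))
  }
  out
}

empty_region_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             length = integer(), residues = character(),
             lowercase_frac = numeric(), origin_block = integer(),
             stringsAsFactors = FALSE)
}

#' Scan a whole MAF alignment for conserved regions
#'
#' Applies [find_conserved()] to every block, concatenates the results, and
#' collapses regions with identical (chrom, start, end). Regions are never
#' merged across blocks. Each region receives a coordinate-derived `name`.
#'
#' @param blocks list of [maf_block] objects (e.g. from [read_maf()]).
#' @param min_len passed to [find_conserved()].
#' @param bed,fasta optional output paths (BED4 of regions; FASTA of region
#'   residues).
#' @return data.frame of conserved regions with a `name` column.
#' @export
scan_alignment <- function(blocks, min_len = 40, bed = NULL, fasta = NULL) {
  per_block <- lapply(seq_along(blocks), function(i) {
    find_conserved(blocks[[i]], min_len = min_len, origin_block = i)
  })
  regions <- do.call(rbind, c(list(empty_region_df()), per_block))
  key <- paste(regions$chrom, regions$start, regions$end)
  regions <- regions[!duplicated(key), , drop = FALSE]
  rownames(regions) <- NULL
  regions$name <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  message("stage=scan in=", length(blocks), " out=", nrow(regions))
  if (!is.null(bed)) write_bed(regions, bed)
  if (!is.null(fasta) && nrow(regions) > 0) {
    write_fasta(setNames(regions$residues, regions$name), fasta)
  }
  regions
}
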