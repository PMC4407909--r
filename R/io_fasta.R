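#' Read a FASTA file into a named character vector
#'
#' Sequences are returned as plain character strings named by their FASTA
#' identifiers (the header up to the first whitespace). Case is preserved:
#' lowercase residues denote soft-masked repeats throughout the toolkit.
#'
#' @param path path to a FASTA file.
#' @param check validate that residues are in `{A,C,G,T,N,a,c,g,t,n}` and
#'   error otherwise. Default `TRUE`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, check = TRUE) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  if (any(Biostrings::width(x) == 0)) {
    stop("empty record body in ", path, ": ",
         paste(names(x)[Biostrings::width(x) == 0], collapse = ", "))
  }
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  if (check) {
    bad <- grepl("[^ACGTNacgtn]", out)
    if (any(bad)) {
      stop("non-nucleotide characters in record(s): ",
           paste(names(out)[bad], collapse = ", "))
    }
  }
  out
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width for the sequence body (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  stopifnot(is.character(records), !is.null(names(records)),
            all(nzchar(names(records))), wrap >= 1)
  if (any(nchar(records) == 0)) stop("refusing to write empty record body")
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = as.integer(wrap))
  invisible(path)
}

#' Read / write BED4 intervals
#'
#' BED intervals are 0-based half-open. Columns: chrom, start, end, name.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name"),
                   colClasses = c("character", "integer", "integer", "character"))
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("invalid BED interval (need 0 <= start < end)")
  }
  df
}

#' @rdname read_bed
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
    stop("invalid BED interval (need 0 <= start < end)")
  }
  write.table(intervals[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Slice genome regions named by a BED data.frame
#'
#' @param genome named character vector of sequences.
#' @param bed data.frame as returned by [read_bed()].
#' @return character vector of region residues, named by the BED `name`.
#' @export
slice_bed <- function(genome, bed) {
  missing <- setdiff(unique(bed$chrom), names(genome))
  if (length(missing)) stop("chrom(s) not in genome: ", paste(missing, collapse = ", "))
  out <- mapply(function(chrom, s, e) slice0(genome[[chrom]], s, e),
                bed$chrom, bed$start, bed$end)
  names(out) <- bed$name
  out
}
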