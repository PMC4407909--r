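#' Write a supermatrix as relaxed PHYLIP
#'
#' One taxon per line: name, whitespace, full sequence. Header is
#' `"ntaxa nchar"`.
#'
#' @param sm a supermatrix (see [concat_alignments()]), or any named character vector of
#'   equal-length aligned rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  rows <- if (inherits(sm, "supermatrix")) sm$rows else sm
  stopifnot(is.character(rows), !is.null(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("ragged rows: all taxa must have equal length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(rows), w), con)
  writeLines(sprintf("%s %s", names(rows), unname(rows)), con)
  invisible(path)
}

#' Read relaxed PHYLIP
#'
#' @param path path to a relaxed PHYLIP file (one taxon per line).
#' @return named character vector of aligned rows.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  rows <- vapply(parts, `[`, character(1), 2)
  names(rows) <- vapply(parts, `[`, character(1), 1)
  if (length(rows) != hdr[1] || any(nchar(rows) != hdr[2])) {
    stop("PHYLIP body disagrees with header")
  }
  rows
}

#' Write RAxML-style charset/partition lines for a supermatrix
#'
#' One line per locus, `"DNA, uce-N = a-b"`, 1-based inclusive ranges in
#' concatenation order.
#'
#' @param sm a supermatrix from [concat_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charsets <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  cs <- sm$charsets
  writeLines(sprintf("DNA, %s = %d-%d", cs$locus_id, cs$start, cs$end), path)
  invisible(path)
}

#' Minimal NEXUS writer / reader
#'
#' Writes a DATA block (and, for supermatrices, simple `charset` lines in a
#' SETS block). This is deliberately minimal: enough for the toolkit's own
#' round-trips, not a general NEXUS implementation.
#'
#' @param sm a supermatrix or named character vector of aligned rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path) {
  rows <- if (inherits(sm, "supermatrix")) sm$rows else sm
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("ragged rows")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(rows), w),
               "  FORMAT DATATYPE=DNA GAP=- MISSING=?;", "  MATRIX"), con)
  writeLines(sprintf("    %s %s", names(rows), unname(rows)), con)
  writeLines(c("  ;", "END;"), con)
  if (inherits(sm, "supermatrix")) {
    cs <- sm$charsets
    writeLines(c("BEGIN SETS;",
                 sprintf("  CHARSET %s = %d-%d;", cs$locus_id, cs$start, cs$end),
                 "END;"), con)
  }
  invisible(path)
}

#' @rdname write_nexus
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)[1]
  i1 <- grep("^\\s*;\\s*$", lines)
  i1 <- i1[i1 > i0][1]
  if (is.na(i0) || is.na(i1)) stop("no MATRIX block found")
  body <- trimws(lines[(i0 + 1):(i1 - 1)])
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\\s+")
  rows <- vapply(parts, `[`, character(1), 2)
  names(rows) <- vapply(parts, `[`, character(1), 1)
  cs_lines <- grep("^\\s*CHARSET\\s", lines, ignore.case = TRUE, value = TRUE)
  charsets <- NULL
  if (length(cs_lines)) {
    m <- regmatches(cs_lines,
                    regexec("CHARSET\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+)", cs_lines,
                            ignore.case = TRUE))
    charsets <- data.frame(
      locus_id = vapply(m, `[`, character(1), 2),
      start = as.integer(vapply(m, `[`, character(1), 3)),
      end = as.integer(vapply(m, `[`, character(1), 4)),
      stringsAsFactors = FALSE)
  }
  if (is.null(charsets)) rows else supermatrix_from_rows(rows, charsets)
}
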