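#' Read a MAF (Multiple Alignment Format) file
#'
#' Parses alignment blocks ('a' lines followed by 's' rows). Lines starting
#' with '#' are comments. Each block is a data.frame of rows with columns
#' `src`, `start`, `size`, `strand`, `src_size`, `text`; starts are 0-based
#' and, for '-' strand rows, count from the start of the reverse-complemented
#' source, as the format prescribes.
#'
#' @param path path to a MAF file.
#' @param taxon_map optional named character vector mapping a source-name
#'   prefix to a taxon label; when supplied, matching sources are rewritten
#'   to `"taxon.src"`, mirroring the usual rename step that annotates MAF
#'   rows with taxon names.
#' @return list of blocks (class `maf_block` each).
#' @export
read_maf <- function(path, taxon_map = NULL) {
  lines <- readLines(path)
  blocks <- list()
  rows <- NULL
  flush <- function() {
    if (!is.null(rows) && nrow(rows) > 0) {
      blocks[[length(blocks) + 1L]] <<- maf_block(rows)
    }
    rows <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#", line) || !nzchar(trimws(line))) {
      if (!nzchar(trimws(line))) flush()
      next
    }
    if (grepl("^a( |$)", line)) {
      flush()
      rows <- data.frame(src = character(), start = integer(), size = integer(),
                         strand = character(), src_size = integer(),
                         text = character(), stringsAsFactors = FALSE)
    } else if (grepl("^s ", line)) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) != 7L) stop("malformed 's' line at line ", i)
      start <- suppressWarnings(as.integer(f[3]))
      size <- suppressWarnings(as.integer(f[4]))
      src_size <- suppressWarnings(as.integer(f[6]))
      if (anyNA(c(start, size, src_size)) || !f[5] %in% c("+", "-")) {
        stop("malformed 's' line at line ", i)
      }
      src <- f[2]
      if (!is.null(taxon_map)) {
        hit <- match(sub("\\..*$", "", src), names(taxon_map))
        if (!is.na(hit)) src <- paste0(taxon_map[[hit]], ".", src)
      }
      if (is.null(rows)) {
        rows <- data.frame(src = character(), start = integer(), size = integer(),
                           strand = character(), src_size = integer(),
                           text = character(), stringsAsFactors = FALSE)
      }
      rows <- rbind(rows, data.frame(src = src, start = start, size = size,
                                     strand = f[5], src_size = src_size,
                                     text = f[7], stringsAsFactors = FALSE))
    }
  }
  flush()
  blocks
}

#' Construct and validate a MAF block
#'
#' @param rows data.frame with columns `src`, `start`, `size`, `strand`,
#'   `src_size`, `text`.
#' @return the validated data.frame with class `maf_block`.
#' @export
maf_block <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("src", "start", "size", "strand", "src_size", "text") %in% names(rows)))
  widths <- nchar(rows$text)
  if (length(unique(widths)) > 1L) {
    stop("inconsistent row text lengths within a MAF block")
  }
  nongap <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  bad <- which(nongap != rows$size)
  if (length(bad)) {
    stop("MAF row size field disagrees with non-gap character count (row ",
         bad[1], ": size ", rows$size[bad[1]], ", non-gap ", nongap[bad[1]], ")")
  }
  if (any(rows$start < 0) || any(rows$start + rows$size > rows$src_size)) {
    stop("MAF row coordinates exceed source size")
  }
  structure(rows, class = c("maf_block", "data.frame"))
}

#' Write MAF blocks
#'
#' @param blocks list of `maf_block` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       b$src, b$start, b$size, b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}
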