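#' Read a single-end FASTQ file
#'
#' Parses plain or gzip-compressed four-line FASTQ records. Bases are
#' upper-cased and must be over the alphabet {A,C,G,T,N}; anything else is
#' an error. Quality strings are retained verbatim but are not interpreted
#' (no quality filtering is applied anywhere in the pipeline).
#'
#' @param path path to a FASTQ file (`.fastq` or `.fastq.gz`).
#' @return a data.frame with columns `read_id`, `bases`, `quality`, one row
#'   per record, in file order.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' write_fastq(fq, c("r1", "r2"), c("ACGT", "GGNT"))
#' parse_fastq(fq)
#' @export
parse_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(0), bases = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ %s: %d lines is not a multiple of 4 (truncated record near line %d)",
                 path, n, n))
  }
  head_i <- seq(1L, n, by = 4L)
  bad_head <- which(!startsWith(lines[head_i], "@"))
  if (length(bad_head)) {
    stop(sprintf("malformed FASTQ %s: header at line %d does not start with '@'",
                 path, head_i[bad_head[1]]))
  }
  sep_i <- head_i + 2L
  bad_sep <- which(!startsWith(lines[sep_i], "+"))
  if (length(bad_sep)) {
    stop(sprintf("malformed FASTQ %s: separator at line %d does not start with '+'",
                 path, sep_i[bad_sep[1]]))
  }
  bases <- toupper(lines[head_i + 1L])
  bad_alpha <- which(!grepl("^[ACGTN]*$", bases))
  if (length(bad_alpha)) {
    stop(sprintf("FASTQ %s: bases at line %d contain characters outside {A,C,G,T,N}",
                 path, head_i[bad_alpha[1]] + 1L))
  }
  empty <- which(!nzchar(bases))
  if (length(empty)) {
    stop(sprintf("FASTQ %s: empty sequence at line %d", path, head_i[empty[1]] + 1L))
  }
  qual <- lines[head_i + 3L]
  if (any(nchar(qual) != nchar(bases))) {
    k <- which(nchar(qual) != nchar(bases))[1]
    stop(sprintf("FASTQ %s: quality length differs from sequence length at line %d",
                 path, head_i[k] + 3L))
  }
  data.frame(read_id = sub("^@", "", lines[head_i]),
             bases = bases, quality = qual, stringsAsFactors = FALSE)
}

#' Write a single-end FASTQ file
#'
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param read_id character vector of read identifiers (without `@`).
#' @param bases character vector of base strings.
#' @param quality optional quality strings; defaults to `"I"` (Q40) at every
#'   base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(path, read_id, bases, quality = NULL) {
  stopifnot(length(read_id) == length(bases))
  if (is.null(quality)) {
    quality <- vapply(nchar(bases), function(k) strrep("I", k), character(1))
  }
  stopifnot(length(quality) == length(bases))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(bases)) {
    rec <- rbind(paste0("@", read_id), bases, "+", quality)
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}
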