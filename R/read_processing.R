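#' Describe the constant regions of a SELEX sequencing library
#'
#' A library layout records everything needed to recover the fixed-length
#' random-region core from a raw read: the core length, the 3'-fixed oligo
#' expected immediately downstream of the core, and the matching tolerance
#' used to locate it. Sequencing runs read the cDNA strand, so layouts are
#' expressed in the DNA alphabet (T, not U).
#'
#' @param fixed3_sequence the 3'-fixed oligo (DNA alphabet) expected to
#'   follow the random core in each read.
#' @param core_length length of the random region in nt (default 30).
#' @param adapter_sequence optional sequencing adapter downstream of the
#'   fixed oligo. It is recorded for read synthesis only: trimming at the
#'   fixed-oligo start already removes everything 3' of the core, so the
#'   adapter is never searched separately.
#' @param fixed3_max_mismatch maximum Hamming mismatches tolerated in a
#'   full-length anchor match (default 1).
#' @param fixed3_min_anchor number of fixed-oligo bases that form the
#'   anchor probe (default 10).
#' @return an object of class `library_layout`.
#' @examples
#' library_layout("TGGAATCCGCTACGGTCAGAA")
#' @export
library_layout <- function(fixed3_sequence, core_length = 30L,
                           adapter_sequence = NULL,
                           fixed3_max_mismatch = 1L, fixed3_min_anchor = 10L) {
  if (!is.character(fixed3_sequence) || length(fixed3_sequence) != 1L ||
      !nzchar(fixed3_sequence)) {
    stop("fixed3_sequence must be a non-empty base string")
  }
  fixed3_sequence <- toupper(fixed3_sequence)
  assert_dna(fixed3_sequence, what = "fixed3_sequence")
  core_length <- as.integer(core_length)
  fixed3_max_mismatch <- as.integer(fixed3_max_mismatch)
  fixed3_min_anchor <- as.integer(fixed3_min_anchor)
  stopifnot(core_length > 0, fixed3_max_mismatch >= 0,
            fixed3_min_anchor >= 1,
            fixed3_min_anchor <= nchar(fixed3_sequence))
  structure(list(core_length = core_length,
                 fixed3_sequence = fixed3_sequence,
                 adapter_sequence = adapter_sequence,
                 fixed3_max_mismatch = fixed3_max_mismatch,
                 fixed3_min_anchor = fixed3_min_anchor),
            class = "library_layout")
}

#' Remove low-quality tails at the first N
#'
#' Everything from the first ambiguous base (N) onwards is treated as low
#' quality and discarded, the N itself included; an N can never be part of
#' a usable fixed-length core, so dropping it keeps the downstream length
#' filter simple. Vectorised.
#'
#' @param bases character vector over {A,C,G,T,N}.
#' @return character vector of N-free prefixes.
#' @examples
#' truncate_at_n(c("ACGTNACGT", "ACGT", "NACGT"))
#' @export
truncate_at_n <- function(bases) {
  sub("N.*$", "", bases)
}

#' Trim the 3'-fixed oligo and everything downstream from reads
#'
#' Scans each read left to right for the first occurrence of the start of
#' the layout's fixed oligo and returns the bases before it. The probe at
#' each position is the first `min(fixed3_min_anchor, remaining)` bases of
#' the fixed oligo; a full-length anchor tolerates up to
#' `fixed3_max_mismatch` Hamming mismatches, and shorter terminal overlaps
#' scale the allowance down proportionally (so very short overlaps must
#' match exactly). The earliest accepted position wins, which prevents
#' chimeric over-long cores. Reads without any accepted occurrence are
#' returned unchanged (the length filter decides their fate); empty reads
#' give `NA`.
#'
#' @param bases character vector of (already N-truncated) reads.
#' @param layout a [library_layout()].
#' @return character vector of trimmed cores (`NA` for empty input reads).
#' @examples
#' lay <- library_layout("TGGAATCCGCTACGGTCAGAA")
#' extract_core(paste0(strrep("A", 30), lay$fixed3_sequence), lay)
#' @export
extract_core <- function(bases, layout) {
  stopifnot(inherits(layout, "library_layout"))
  cut <- scan_fixed3_cpp(bases, layout$fixed3_sequence,
                         layout$fixed3_max_mismatch, layout$fixed3_min_anchor)
  out <- ifelse(cut > 0L, substr(bases, 1L, cut - 1L), bases)
  out[!is.na(bases) & !nzchar(bases)] <- NA_character_
  out
}

#' Keep only reads whose trimmed core is exactly core length
#'
#' A core is usable when its length equals the layout's core length exactly
#' and it contains no ambiguous base.
#'
#' @param core character vector of trimmed cores.
#' @param layout a [library_layout()].
#' @return logical vector.
#' @export
filter_usable <- function(core, layout) {
  stopifnot(inherits(layout, "library_layout"))
  !is.na(core) & nchar(core) == layout$core_length & !grepl("N", core, fixed = TRUE)
}

#' Per-round counted core sequences
#'
#' Container for one selection round's processed sequencing output: the
#' multiset of usable fixed-length cores with their read counts, plus the
#' total and usable read tallies. `usable_reads` always equals the sum of
#' the counts; rows are stored in ranking order (count descending, sequence
#' lexicographic ascending).
#'
#' @param sequence character vector of distinct core sequences (A/C/G/T).
#' @param count integer read counts, one per sequence.
#' @param total_reads total raw reads in the round (defaults to
#'   `sum(count)`).
#' @param round_label label such as `"initial"` or `"R7"`.
#' @param core_length expected core length; defaults to the common sequence
#'   length.
#' @return an object of class `round_counts`.
#' @examples
#' round_counts(c("ACGTACGTAC", "TTTTTTTTTT"), c(5, 2),
#'              total_reads = 10, round_label = "R1", core_length = 10)
#' @export
round_counts <- function(sequence, count, total_reads = sum(count),
                         round_label = "round", core_length = NULL) {
  stopifnot(length(sequence) == length(count))
  sequence <- toupper(as.character(sequence))
  count <- as.numeric(count)
  if (anyDuplicated(sequence)) stop("core sequences must be distinct")
  if (any(count < 0)) stop("counts must be non-negative")
  assert_dna(sequence, what = "core sequence")
  if (length(sequence)) {
    lens <- unique(nchar(sequence))
    if (length(lens) > 1L) stop("all core sequences must share one length")
    if (is.null(core_length)) core_length <- lens
    if (lens != core_length) stop("core sequences do not match core_length")
  } else if (is.null(core_length)) {
    core_length <- 30L
  }
  usable <- sum(count)
  if (total_reads < usable) stop("total_reads cannot be below usable_reads")
  ord <- order(-count, sequence)
  structure(list(round_label = round_label,
                 total_reads = as.numeric(total_reads),
                 usable_reads = usable,
                 core_length = as.integer(core_length),
                 core_counts = data.frame(sequence = sequence[ord],
                                          count = count[ord],
                                          stringsAsFactors = FALSE)),
            class = "round_counts")
}

#' @export
print.round_counts <- function(x, ...) {
  cat(sprintf("<round_counts> %s: %s total, %s usable (%.2f%%), %d unique %d-nt cores\n",
              x$round_label, format(x$total_reads, big.mark = ","),
              format(x$usable_reads, big.mark = ","),
              ifelse(x$total_reads > 0, 100 * x$usable_reads / x$total_reads, NA),
              nrow(x$core_counts), x$core_length))
  invisible(x)
}

#' Process one round of FASTQ into counted cores
#'
#' Applies the full read-processing chain: parse, truncate at the first N,
#' trim the 3'-fixed oligo (and with it everything downstream, adapter
#' included), keep reads whose core is exactly core length, and count
#' identical cores.
#'
#' @param path FASTQ file (plain or gzip).
#' @param layout a [library_layout()].
#' @param round_label label stored in the result.
#' @return a [round_counts()] object.
#' @export
process_round <- function(path, layout, round_label = basename(path)) {
  stopifnot(inherits(layout, "library_layout"))
  fq <- parse_fastq(path)
  core <- extract_core(truncate_at_n(fq$bases), layout)
  keep <- filter_usable(core, layout)
  tab <- table(core[keep])
  round_counts(sequence = names(tab), count = as.integer(tab),
               total_reads = nrow(fq), round_label = round_label,
               core_length = layout$core_length)
}

#' Round summary statistics
#'
#' @param counts a [round_counts()] object.
#' @return list with `round_label`, `total_reads`, `usable_reads`,
#'   `pct_usable` (percent, full precision), `n_unique`.
#' @export
round_summary <- function(counts) {
  stopifnot(inherits(counts, "round_counts"))
  list(round_label = counts$round_label,
       total_reads = counts$total_reads,
       usable_reads = counts$usable_reads,
       pct_usable = if (counts$total_reads > 0)
         100 * counts$usable_reads / counts$total_reads else NA_real_,
       n_unique = nrow(counts$core_counts))
}

#' Write a per-round core-count table
#'
#' Two-column TSV (`sequence`, `count`) in ranking order.
#'
#' @param counts a [round_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_core_counts <- function(counts, path) {
  stopifnot(inherits(counts, "round_counts"))
  utils::write.table(counts$core_counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
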