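# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sample random DNA core sequences
#'
#' Draws `n` sequences of fixed length with bases sampled independently at
#' each position from `base_weights`. Used by the synthetic SELEX generator
#' and by test fixtures.
#'
#' @param n number of sequences.
#' @param length sequence length in nt.
#' @param base_weights named numeric weights for A, C, G, T (any positive
#'   scale; normalised internally).
#' @return character vector of length `n`.
#' @export
random_cores <- function(n, length = 30L, base_weights = c(A = 1, C = 1, G = 1, T = 1)) {
  stopifnot(n >= 0, length > 0)
  w <- base_weights[DNA_BASES]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("base_weights must be non-negative and named A, C, G, T")
  }
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * length, replace = TRUE, prob = w / sum(w)),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# fraction of a given base in each sequence of a character vector
base_fraction <- function(seqs, base) {
  n <- nchar(seqs)
  cnt <- nchar(seqs) - nchar(gsub(base, "", seqs, fixed = TRUE))
  ifelse(n > 0, cnt / n, 0)
}

assert_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad)) {
    stop(sprintf("%s %d contains characters outside {%s}", what, bad[1],
                 if (allow_n) "A,C,G,T,N" else "A,C,G,T"), call. = FALSE)
  }
  invisible(x)
}
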