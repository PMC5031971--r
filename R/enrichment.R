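#' Rank the unique core sequences of a round
#'
#' Full deterministic ranking: count descending, ties broken by
#' lexicographically smaller sequence first.
#'
#' @param counts a [round_counts()] object.
#' @return data.frame with columns `sequence`, `count`, in ranking order
#'   (empty for an empty round).
#' @export
rank_unique <- function(counts) {
  stopifnot(inherits(counts, "round_counts"))
  cc <- counts$core_counts
  cc[order(-cc$count, cc$sequence), , drop = FALSE]
}

#' Extract the top-N unique sequences of a round
#'
#' The first `min(n, #unique)` entries of [rank_unique()], each annotated
#' with its frequency among the round's usable reads.
#'
#' @param counts a [round_counts()] object.
#' @param n set size (default 1000, the conventional reporting depth).
#' @return an object of class `top_set`: list with `round_label`, `n`,
#'   `usable_reads` and `entries` (data.frame `sequence`, `count`,
#'   `frequency` in usable reads).
#' @export
top_n_set <- function(counts, n = 1000L) {
  stopifnot(inherits(counts, "round_counts"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  ranked <- rank_unique(counts)
  ranked <- utils::head(ranked, n)
  ranked$frequency <- if (counts$usable_reads > 0)
    ranked$count / counts$usable_reads else rep(NA_real_, nrow(ranked))
  rownames(ranked) <- NULL
  structure(list(round_label = counts$round_label, n = n,
                 usable_reads = counts$usable_reads, entries = ranked),
            class = "top_set")
}

#' @export
print.top_set <- function(x, ...) {
  cat(sprintf("<top_set> %s: top %d of %d unique (T = %s reads)\n",
              x$round_label, nrow(x$entries), x$n,
              format(sum(x$entries$count), big.mark = ",")))
  invisible(x)
}

#' Total reads and frequency of a top-N set
#'
#' `T_X` is the summed read count of the set; `f_X = T_X / U_X` is its
#' frequency among the round's usable reads.
#'
#' @param top a [top_n_set()] result.
#' @param usable usable read count of the round (defaults to the value
#'   recorded in `top`).
#' @return list with elements `T` (count) and `f` (fraction).
#' @export
top_total_and_frequency <- function(top, usable = top$usable_reads) {
  stopifnot(inherits(top, "top_set"))
  T_X <- sum(top$entries$count)
  if (usable == 0) stop("usable read count is zero: frequency undefined")
  if (usable < T_X) stop("usable reads cannot be below the top-N total")
  list(T = T_X, f = T_X / usable)
}

#' Molecular enrichment fold
#'
#' The round-X enrichment fold is the top-N read total at round X divided
#' by the same statistic in the unselected (initial) library:
#' `E_X = T_X / T_0`. By construction `E = 1` at the initial round.
#'
#' @param t_x top-N read total at round X.
#' @param t_0 top-N read total of the initial library.
#' @return the fold as a positive real (full precision; tables
#'   conventionally print 2 decimals).
#' @examples
#' enrichment_fold(771042, 3169) # 243.31-fold
#' @export
enrichment_fold <- function(t_x, t_0) {
  if (t_0 <= 0) stop("initial-library top-N total must be positive: enrichment undefined")
  t_x / t_0
}

#' Per-round enrichment series
#'
#' Computes `T_X`, `U_X`, `f_X = T_X/U_X` and `E_X = T_X/T_0` for an ordered
#' list of rounds; the first element is taken as the unselected library
#' (so its enrichment is exactly 1).
#'
#' @param rounds list of [round_counts()] in round order (initial first).
#' @param n top-set size (default 1000).
#' @return data.frame with one row per round: `round`, `total_reads`,
#'   `usable_reads`, `pct_usable`, `top_reads`, `pct_top_in_usable`,
#'   `enrichment_fold`.
#' @export
enrichment_series <- function(rounds, n = 1000L) {
  stopifnot(is.list(rounds), length(rounds) >= 1L)
  stats <- lapply(rounds, function(rc) {
    tf <- top_total_and_frequency(top_n_set(rc, n))
    data.frame(round = rc$round_label, total_reads = rc$total_reads,
               usable_reads = rc$usable_reads,
               pct_usable = 100 * rc$usable_reads / rc$total_reads,
               top_reads = tf$T, pct_top_in_usable = 100 * tf$f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  out$enrichment_fold <- vapply(out$top_reads, enrichment_fold,
                                numeric(1), t_0 = out$top_reads[1])
  out
}

#' Match a reference top set against another round
#'
#' For every sequence in the reference set (conventionally the final
#' round's top 1000), reports its exact-match read count in the other
#' round, and that count as a frequency of (a) the other round's own top-N
#' read total and (b) the other round's usable reads. Sequences absent
#' from the other round count 0. Matching is exact 30-mer identity; no
#' mismatch tolerance is applied.
#'
#' @param reference a [top_n_set()] result.
#' @param other a [round_counts()] object.
#' @return data.frame `sequence`, `count`, `frequency_in_top` (vs the other
#'   round's top-N total), `frequency_in_usable`.
#' @export
match_reference_set <- function(reference, other) {
  stopifnot(inherits(reference, "top_set"), inherits(other, "round_counts"))
  if (nrow(reference$entries) == 0L) stop("reference top set is empty")
  idx <- match(reference$entries$sequence, other$core_counts$sequence)
  cnt <- ifelse(is.na(idx), 0, other$core_counts$count[idx])
  t_other <- sum(top_n_set(other, reference$n)$entries$count)
  data.frame(sequence = reference$entries$sequence,
             count = cnt,
             frequency_in_top = if (t_other > 0) cnt / t_other else NA_real_,
             frequency_in_usable = if (other$usable_reads > 0)
               cnt / other$usable_reads else NA_real_,
             stringsAsFactors = FALSE)
}
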