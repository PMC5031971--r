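#' Levenshtein distance between two sequences
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' the primary-sequence similarity kernel used for aptamer-family
#' grouping.
#'
#' @param a,b character scalars.
#' @return non-negative integer; 0 iff `a == b`.
#' @export
edit_distance <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b))
}

# T and U pair identically; allowed pairs are Watson-Crick plus G.U wobble
.pair_ok <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

#' Predict a secondary structure by base-pair maximisation
#'
#' Nussinov-style dynamic programme: finds a pseudoknot-free structure with
#' the maximum number of base pairs under the pairing rules A-U(T), G-C and
#' the G-U(T) wobble, with a minimum hairpin loop of `min_loop` unpaired
#' bases (a pair (i, j) requires `j - i > min_loop`). T in the input is
#' treated as U. Among co-optimal structures the traceback is
#' deterministic: position i is left unpaired whenever that is optimal,
#' otherwise i is paired with the smallest admissible j, so every sequence
#' maps to a unique dot-bracket string.
#'
#' This folder deliberately trades thermodynamic realism for exact
#' testability (the optimum is checkable by brute-force enumeration);
#' downstream clustering consumes only the pair set, so a thermodynamic
#' folder returning pair sets can be substituted via the `fold_fun`
#' argument of [cluster_top_sequences()].
#'
#' @param sequence base string over {A,C,G,T,U}.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return an object of class `structure_fold`: list with `sequence` (as
#'   given), `dot_bracket`, `pairs` (two-column matrix of 1-based i < j),
#'   `n_pairs`.
#' @examples
#' fold_structure("GGGAAACCC")
#' @export
fold_structure <- function(sequence, min_loop = 3L) {
  stopifnot(length(sequence) == 1L, min_loop >= 0L)
  s <- chartr("T", "U", toupper(sequence))
  n <- nchar(s)
  empty <- structure(list(sequence = sequence,
                          dot_bracket = strrep(".", n),
                          pairs = matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL, c("i", "j"))),
                          n_pairs = 0L),
                     class = "structure_fold")
  if (n == 0L) return(empty)
  b <- strsplit(s, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "U"))) {
    stop("sequence must be over {A,C,G,T,U}")
  }
  if (n <= min_loop + 1L) return(empty)
  N <- matrix(0L, n, n)
  for (span in seq.int(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i + 1L, j]
      for (k in seq.int(i + min_loop + 1L, j)) {
        if (.pair_ok[b[i], b[k]]) {
          v <- 1L +
            (if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L) +
            (if (k + 1L <= j) N[k + 1L, j] else 0L)
          if (v > best) best <- v
        }
      }
      N[i, j] <- best
    }
  }
  # deterministic traceback: prefer leaving i unpaired, else smallest j
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    if (N[i, j] == N[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (.pair_ok[b[i], b[k]]) {
        v <- 1L +
          (if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L) +
          (if (k + 1L <= j) N[k + 1L, j] else 0L)
        if (v == N[i, j]) {
          pairs <- rbind(pairs, c(i, k))
          stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  db <- rep(".", n)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  colnames(pairs) <- c("i", "j")
  structure(list(sequence = sequence, dot_bracket = paste(db, collapse = ""),
                 pairs = pairs, n_pairs = nrow(pairs)),
            class = "structure_fold")
}

#' @export
print.structure_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "  (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

pair_keys <- function(fold) {
  if (fold$n_pairs == 0L) return(character(0))
  paste(fold$pairs[, 1], fold$pairs[, 2], sep = "-")
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two structures' pair sets.
#' Both folds must be over sequences of equal length.
#'
#' @param f1,f2 [fold_structure()] results.
#' @return non-negative integer.
#' @export
structure_distance <- function(f1, f2) {
  stopifnot(inherits(f1, "structure_fold"), inherits(f2, "structure_fold"))
  if (nchar(f1$sequence) != nchar(f2$sequence)) {
    stop("structures must be over sequences of equal length")
  }
  k1 <- pair_keys(f1)
  k2 <- pair_keys(f2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# combined sequence + structure dissimilarity in [0, ~1]
# structure term: symmetric difference over the summed pair counts
# (0 when both structures are unpaired)
combined_distance <- function(seq_a, seq_b, fold_a, fold_b, alpha, core_length) {
  d_seq <- edit_distance(seq_a, seq_b) / core_length
  denom <- fold_a$n_pairs + fold_b$n_pairs
  d_str <- if (denom > 0) structure_distance(fold_a, fold_b) / denom else 0
  alpha * d_seq + (1 - alpha) * d_str
}

#' Group top sequences into aptamer families
#'
#' Greedy single-linkage-style grouping of a ranked top set (conventionally
#' the top 50) by a combined dissimilarity
#' `D = alpha * edit/core_length + (1 - alpha) * bp_distance / (pairs_a + pairs_b)`.
#' Sequences are visited in ranking order (count descending, then
#' lexicographic); each is assigned to the first existing group whose
#' representative is within `threshold`, otherwise it founds a new group.
#' Because visiting order follows abundance, a group's representative is
#' always its most abundant member. Singleton groups whose count falls
#' below `orphan_min_count` are flagged as orphan sequences.
#'
#' @param sequences character vector of core sequences (equal length).
#' @param counts matching read counts (used for ordering and orphan
#'   calling).
#' @param alpha weight of the primary-sequence term, in `[0, 1]`. The
#'   default 0.85 keeps the sequence term dominant: under base-pair
#'   maximisation many structures are co-optimal, so the canonical pair
#'   set can change wholesale under one or two substitutions, and its
#'   worst-case normalised distance of 1 must stay below the joining
#'   threshold for true substitution families (at 0.85 it contributes at
#'   most 0.15).
#' @param threshold dissimilarity below/at which a sequence joins a group
#'   (default 0.25).
#' @param min_loop hairpin-loop minimum passed to the folder.
#' @param fold_fun folding function taking `(sequence, min_loop)` and
#'   returning a [fold_structure()]-compatible object; pluggable so a
#'   thermodynamic folder can be substituted.
#' @param orphan_min_count count floor for singleton groups; defaults to
#'   1% of the clustered set's total reads.
#' @return an object of class `selex_groups`: list of groups, each with
#'   `group_id`, `representative`, `members` (data.frame `sequence`,
#'   `count`), `reads` (summed count) and `orphan` flag.
#' @export
cluster_top_sequences <- function(sequences, counts, alpha = 0.85,
                                  threshold = 0.25, min_loop = 3L,
                                  fold_fun = fold_structure,
                                  orphan_min_count = NULL) {
  stopifnot(length(sequences) == length(counts),
            alpha >= 0, alpha <= 1, threshold >= 0)
  if (length(sequences) == 0L) {
    return(structure(list(), class = "selex_groups"))
  }
  if (length(unique(nchar(sequences))) != 1L) {
    stop("all sequences must share one length")
  }
  core_length <- nchar(sequences[1])
  if (is.null(orphan_min_count)) orphan_min_count <- 0.01 * sum(counts)
  ord <- order(-counts, sequences)
  sequences <- sequences[ord]
  counts <- counts[ord]
  folds <- lapply(sequences, fold_fun, min_loop = min_loop)
  rep_idx <- integer(0)          # index of each group's representative
  assign <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (g in seq_along(rep_idx)) {
      r <- rep_idx[g]
      d <- combined_distance(sequences[i], sequences[r],
                             folds[[i]], folds[[r]], alpha, core_length)
      if (d <= threshold) {
        assign[i] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
    }
  }
  groups <- lapply(seq_along(rep_idx), function(g) {
    m <- which(assign == g)
    list(group_id = g,
         representative = sequences[rep_idx[g]],
         representative_fold = folds[[rep_idx[g]]],
         members = data.frame(sequence = sequences[m], count = counts[m],
                              stringsAsFactors = FALSE),
         reads = sum(counts[m]),
         orphan = length(m) == 1L && counts[m] < orphan_min_count)
  })
  structure(groups, class = "selex_groups")
}

#' @export
print.selex_groups <- function(x, ...) {
  cat(sprintf("<selex_groups> %d groups (%d orphan singletons)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "orphan"))))
  for (g in x) {
    cat(sprintf("  %s%d: %s  %d member(s), %s reads\n",
                if (g$orphan) "orphan " else "group ", g$group_id,
                g$representative, nrow(g$members),
                format(g$reads, big.mark = ",")))
  }
  invisible(x)
}

#' Frequency of a sequence group
#'
#' A group's frequency at round X is its summed read count divided by the
#' round's top-N read total `T_X` (the conventional denominator for
#' family-evolution plots).
#'
#' @param group_reads summed read count of the group at the round.
#' @param t_x the round's top-N read total.
#' @return fraction.
#' @examples
#' group_frequency(619702, 771042) # 0.8037
#' @export
group_frequency <- function(group_reads, t_x) {
  if (t_x <= 0) stop("top-N total must be positive: group frequency undefined")
  group_reads / t_x
}

#' Classify the round-to-round fate of a frequency trajectory
#'
#' Formalises the qualitative arrows used in family-evolution tables:
#' * `enriched` - the final frequency exceeds the initial one and the
#'   trajectory peak lies (within `tol` relative) in the last two rounds;
#' * `depleted` - the final frequency is below the initial one and has
#'   fallen to at most `depleted_frac` of the trajectory maximum;
#' * `transient` - the maximum occurs strictly inside the trajectory and
#'   the final value is below `transient_frac` of it;
#' * `flat` - everything else.
#'
#' @param trajectory numeric vector of per-round frequencies (>= 2 rounds,
#'   round order).
#' @param tol relative tolerance for "peak at the end" (default 0.05).
#' @param depleted_frac depletion floor relative to the maximum
#'   (default 0.10).
#' @param transient_frac drop-from-peak factor for transients
#'   (default 0.5).
#' @return one of `"enriched"`, `"depleted"`, `"transient"`, `"flat"`.
#' @examples
#' classify_fate(c(3.16, 45.58, 85.97, 84.05, 80.37)) # enriched
#' classify_fate(c(0, 4.80, 11.28, 1.60, 4.76))       # transient
#' @export
classify_fate <- function(trajectory, tol = 0.05, depleted_frac = 0.10,
                          transient_frac = 0.5) {
  if (length(trajectory) < 2L) stop("a fate needs at least two rounds")
  if (any(trajectory < 0)) stop("frequencies must be non-negative")
  first <- trajectory[1]
  final <- trajectory[length(trajectory)]
  peak <- max(trajectory)
  peak_at <- which.max(trajectory)
  tail_peak <- max(utils::tail(trajectory, 2))
  if (final > first && peak <= tail_peak * (1 + tol)) return("enriched")
  if (final < first && final <= depleted_frac * peak) return("depleted")
  if (peak_at > 1L && peak_at < length(trajectory) &&
      final < transient_frac * peak) return("transient")
  "flat"
}
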