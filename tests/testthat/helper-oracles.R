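# Independent oracles: deliberately naive re-implementations used to check
# the package's fast paths. They share no code with the package internals.

# exhaustive per-position Hamming scan for the 3'-fixed-oligo locator:
# probe = min(min_anchor, remaining) leading bases of fixed3; allowance
# scales with overlap; returns 1-based cut position or 0
oracle_fixed3_scan <- function(read, fixed3, max_mismatch, min_anchor) {
  rch <- strsplit(read, "")[[1]]
  fch <- strsplit(fixed3, "")[[1]]
  n <- length(rch)
  for (p in seq_len(n)) {
    L <- min(min_anchor, n - p + 1L, length(fch))
    allow <- if (L >= min_anchor) max_mismatch
             else floor(max_mismatch * L / min_anchor)
    mm <- sum(rch[p:(p + L - 1L)] != fch[seq_len(L)])
    if (mm <= allow) return(p)
  }
  0L
}

# memoised-recursion Levenshtein distance
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + (av[i] != bv[j]))
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# exhaustive enumeration of every valid nested structure of a short
# sequence; returns the maximum pair count (and optionally all structures)
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  s <- chartr("T", "U", toupper(sequence))
  b <- strsplit(s, "")[[1]]
  ok <- function(x, y) paste(x, y) %in%
    c("A U", "U A", "G C", "C G", "G U", "U G")
  enum <- function(i, j) {
    # all structures of b[i..j] as lists of c(i, k) pairs
    if (j - i < min_loop + 1L) return(list(list()))
    out <- enum(i + 1L, j)                 # i unpaired
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (ok(b[i], b[k])) {
        left <- enum(i + 1L, k - 1L)
        right <- if (k + 1L <= j) enum(k + 1L, j) else list(list())
        for (s1 in left) for (s2 in right) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), s1, s2)
        }
      }
    }
    out
  }
  n <- length(b)
  if (n < 2L) return(0L)
  max(vapply(enum(1L, n), length, integer(1)))
}

# structural validity check for a fold result
expect_valid_fold <- function(fold, min_loop = 3L) {
  s <- chartr("T", "U", toupper(fold$sequence))
  b <- strsplit(s, "")[[1]]
  ok <- function(x, y) paste(x, y) %in%
    c("A U", "U A", "G C", "C G", "G U", "U G")
  p <- fold$pairs
  expect_equal(nchar(fold$dot_bracket), nchar(fold$sequence))
  if (nrow(p)) {
    expect_true(all(p[, 2] - p[, 1] > min_loop))
    expect_true(all(mapply(ok, b[p[, 1]], b[p[, 2]])))
    idx <- c(p[, 1], p[, 2])
    expect_equal(anyDuplicated(idx), 0L)
    # nestedness: no crossing pairs
    if (nrow(p) > 1) {
      for (u in seq_len(nrow(p) - 1)) for (v in seq.int(u + 1, nrow(p))) {
        i <- p[u, 1]; j <- p[u, 2]; k <- p[v, 1]; l <- p[v, 2]
        crossing <- (i < k && k < j && j < l) || (k < i && i < l && l < j)
        expect_false(crossing)
      }
    }
  }
}

# naive letter-count composition oracle (read-weighted)
oracle_overall_composition <- function(seqs, counts) {
  ch <- unlist(mapply(function(s, k) rep(strsplit(s, "")[[1]], k),
                      seqs, counts, SIMPLIFY = FALSE))
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  as.vector(tab) / length(ch)
}

# per-sequence T fraction (naive, independent of package internals)
base_fraction_test <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) mean(ch == "T"), numeric(1))
}
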