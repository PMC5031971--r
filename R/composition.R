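#' Nucleotide composition of a round's random region
#'
#' Overall and per-position base fractions of the counted cores.
#' Read-weighted mode (the default, matching how pool compositions are
#' conventionally reported over all usable reads) weights every core by
#' its read count; unique-weighted mode counts each distinct sequence
#' once and is useful as a diagnostic for synthesis bias independent of
#' depth.
#'
#' @param counts a [round_counts()] object with at least one core.
#' @param weighting `"read"` or `"unique"`.
#' @return an object of class `composition_profile`: list with `overall`
#'   (named fractions A, C, G, T), `per_position` (core_length x 4
#'   matrix of fractions), `purine`, `pyrimidine`, `weighting`.
#' @export
composition <- function(counts, weighting = c("read", "unique")) {
  stopifnot(inherits(counts, "round_counts"))
  weighting <- match.arg(weighting)
  seqs <- counts$core_counts$sequence
  if (length(seqs) == 0L) stop("no cores to profile")
  w <- if (weighting == "read") counts$core_counts$count else rep(1, length(seqs))
  L <- counts$core_length
  per_pos <- matrix(0, nrow = L, ncol = 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  tot <- sum(w)
  for (j in seq_len(L)) {
    ch <- substr(seqs, j, j)
    for (b in c("A", "C", "G", "T")) per_pos[j, b] <- sum(w[ch == b])
  }
  per_pos <- per_pos / tot
  overall <- colMeans(per_pos)
  composition_profile(overall, per_position = per_pos, weighting = weighting)
}

#' Build a composition profile from base fractions
#'
#' Constructor used both by [composition()] and for profiles taken from
#' published tables (where only the overall percentages are printed).
#' Accepts fractions or percentages (values summing to ~100 are divided
#' by 100).
#'
#' @param overall named numeric of A, C, G, T fractions (or percents).
#' @param per_position optional positions x 4 matrix, same convention.
#' @param weighting bookkeeping label.
#' @return an object of class `composition_profile`.
#' @examples
#' composition_profile(c(A = 14.0, C = 23.0, T = 41.1, G = 22.0))
#' @export
composition_profile <- function(overall, per_position = NULL,
                                weighting = "read") {
  overall <- overall[c("A", "C", "G", "T")]
  if (anyNA(overall)) stop("overall must be named with A, C, G, T")
  s <- sum(overall)
  if (abs(s - 100) < 1) overall <- overall / 100
  else if (abs(s - 1) > 0.01) stop("overall fractions must sum to ~1 (or ~100%)")
  if (!is.null(per_position)) {
    per_position <- per_position[, c("A", "C", "G", "T"), drop = FALSE]
    rs <- rowSums(per_position)
    if (any(abs(rs - 100) < 1)) per_position <- per_position / 100
    if (any(abs(rowSums(per_position) - 1) > 0.01))
      stop("each per-position row must sum to ~1")
  }
  structure(list(overall = overall, per_position = per_position,
                 purine = unname(overall["A"] + overall["G"]),
                 pyrimidine = unname(overall["C"] + overall["T"]),
                 weighting = weighting),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> (%s-weighted) A %.2f%% C %.2f%% G %.2f%% T %.2f%% | purine %.2f%% pyrimidine %.2f%%\n",
              x$weighting, 100 * x$overall["A"], 100 * x$overall["C"],
              100 * x$overall["G"], 100 * x$overall["T"],
              100 * x$purine, 100 * x$pyrimidine))
  invisible(x)
}

#' Purine and pyrimidine fractions of a composition profile
#'
#' Purine = A + G, pyrimidine = C + T. In 2'-fluoro-modified RNA SELEX the
#' pyrimidine pool carries the 2'-F substitution, so a purine/pyrimidine
#' shift tracks preferential incorporation of the modified nucleotides.
#'
#' @param profile a [composition_profile()].
#' @return named numeric `c(purine = , pyrimidine = )`, fractions.
#' @export
purine_pyrimidine <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  c(purine = profile$purine, pyrimidine = profile$pyrimidine)
}
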