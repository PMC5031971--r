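# fixture builders (everything generated in code; no stored data)

FIX_FIXED3 <- "TGGAATCCGCTACGGTCAGAA"
fix_layout <- function(...) library_layout(FIX_FIXED3, ...)

# write reads (optionally wrapped as core + fixed3) to a temp FASTQ
tmp_fastq <- function(bases, ids = sprintf("r%03d", seq_along(bases)),
                      gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(path, ids, bases)
  path
}

wrap_core <- function(cores, fixed3 = FIX_FIXED3) paste0(cores, fixed3)

# three seed families with members within <= 2 substitutions of each seed
family_fixture <- function(seed, n_seeds = 3, members_per = 5) {
  set.seed(seed)
  seeds <- random_cores(n_seeds, 30)
  seqs <- seeds
  counts <- seq(1000, by = -200, length.out = n_seeds)
  family <- seq_len(n_seeds)
  for (f in seq_len(n_seeds)) {
    for (m in seq_len(members_per)) {
      ch <- strsplit(seeds[f], "")[[1]]
      for (p in sample(30, sample(1:2, 1))) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      v <- paste(ch, collapse = "")
      if (!v %in% seqs) {
        seqs <- c(seqs, v)
        counts <- c(counts, sample(10:100, 1))
        family <- c(family, f)
      }
    }
  }
  list(sequences = seqs, counts = counts, family = family, seeds = seeds)
}
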