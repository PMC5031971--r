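make_rc <- function(seqs, counts, total = sum(counts), label = "r") {
  round_counts(seqs, counts, total_reads = total, round_label = label)
}

test_that("unique ranking is deterministic with the documented tie rule", {
  rc <- make_rc(c(strrep("A", 4), strrep("C", 4)), c(5, 2))
  expect_equal(rank_unique(rc)$sequence, c("AAAA", "CCCC"))

  rc2 <- make_rc(c("TTTT", "AAAA", "GGGG"), c(3, 3, 7))
  expect_equal(rank_unique(rc2)$sequence, c("GGGG", "AAAA", "TTTT"))

  # independent selection-sort oracle on a random fixture
  set.seed(5)
  seqs <- unique(random_cores(50, 8))
  counts <- sample(1:10, length(seqs), replace = TRUE)
  got <- rank_unique(make_rc(seqs, counts))
  remaining <- data.frame(sequence = seqs, count = counts,
                          stringsAsFactors = FALSE)
  want <- remaining[0, ]
  while (nrow(remaining)) {
    cand <- remaining[remaining$count == max(remaining$count), ]
    pick <- cand[which.min(rank(cand$sequence)), ]
    want <- rbind(want, pick)
    remaining <- remaining[rownames(remaining) != rownames(pick), ]
  }
  expect_equal(got$sequence, want$sequence)
  expect_equal(got$count, want$count)
})

test_that("top-N sets truncate, carry frequencies, and sum to T_X", {
  rc <- make_rc(c("AAAA", "CCCC", "GGGG"), c(5, 3, 2))
  ts <- top_n_set(rc, 1000)
  expect_equal(nrow(ts$entries), 3L)        # fewer uniques than n
  expect_equal(ts$entries$frequency, c(0.5, 0.3, 0.2))
  expect_true(all(diff(ts$entries$frequency) <= 0))
  expect_lte(sum(ts$entries$frequency), 1)

  ts1 <- top_n_set(rc, 1)
  tf <- top_total_and_frequency(ts1)
  expect_equal(tf$T, 5)
  expect_error(top_n_set(rc, 0), "positive")

  # against a simulator truth table
  cfg <- sim_config(seed = 3, n_template_species = 500, depth_per_round = 3000,
                    rounds = 2, error_rate = 0)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth[sim$truth$round == "R2" & sim$truth$sampled_count > 0, ]
  rc2 <- make_rc(tr$sequence, tr$sampled_count, label = "R2")
  want <- sum(sort(tr$sampled_count, decreasing = TRUE)[1:50])
  expect_equal(top_total_and_frequency(top_n_set(rc2, 50))$T, want)
})

test_that("top-set frequency and enrichment fold match published worked examples", {
  # initial library: T_0 = 5,984 of 27,411,096 usable -> 0.022%
  ts <- top_n_set(make_rc("AAAA", 5984))
  tf <- top_total_and_frequency(ts, usable = 27411096)
  expect_equal(round(100 * tf$f, 3), 0.022)
  # round 7: T_7 = 771,042 of 44,593,424 usable -> 1.729%
  tf7 <- top_total_and_frequency(top_n_set(make_rc("AAAA", 771042)),
                                 usable = 44593424)
  expect_equal(round(100 * tf7$f, 3), 1.729)
  expect_error(top_total_and_frequency(ts, usable = 0), "undefined")

  expect_equal(round(enrichment_fold(771042, 3169), 2), 243.31)
  expect_equal(enrichment_fold(3169, 3169), 1)
  expect_error(enrichment_fold(10, 0), "undefined")
})

test_that("enrichment series is 1 at the initial round and scale-invariant", {
  set.seed(9)
  seqs <- unique(random_cores(300, 12))
  r0 <- make_rc(seqs, sample(1:5, length(seqs), TRUE), label = "initial")
  r1 <- make_rc(seqs, sample(1:50, length(seqs), TRUE), label = "R1")
  es <- enrichment_series(list(r0, r1), n = 100)
  expect_equal(es$enrichment_fold[1], 1)

  r0s <- make_rc(seqs, r0$core_counts$count * 17,
                 total = r0$total_reads * 17, label = "initial")
  r1s <- make_rc(seqs, r1$core_counts$count * 17,
                 total = r1$total_reads * 17, label = "R1")
  es2 <- enrichment_series(list(r0s, r1s), n = 100)
  expect_equal(es2$enrichment_fold, es$enrichment_fold)
  expect_true(all(es$top_reads <= es$usable_reads))
})

test_that("reference matching reproduces self counts and zeros for absences", {
  set.seed(13)
  seqs <- unique(random_cores(40, 10))
  rc <- make_rc(seqs, sample(1:30, length(seqs), TRUE))
  ref <- top_n_set(rc, 20)
  m <- match_reference_set(ref, rc)
  expect_equal(m$count, ref$entries$count)          # self-match
  expect_equal(m$frequency_in_top, ref$entries$count / sum(ref$entries$count))

  s1 <- ref$entries$sequence[1]
  other <- make_rc(c(s1, strrep("T", 10)), c(4, 6))
  m2 <- match_reference_set(ref, other)
  expect_equal(m2$count[m2$sequence == s1], 4)
  expect_true(all(m2$count[m2$sequence != s1] == 0))
})

test_that("reference matching tracks a simulated spike against the truth table", {
  cfg <- sim_config(seed = 21, n_template_species = 400, depth_per_round = 4000,
                    rounds = 3, error_rate = 0)
  sim <- simulate_experiment(cfg)
  lay <- sim$layout
  rounds <- lapply(sim$rounds, function(lab)
    process_round(sim$fastq[[lab]], lay, lab))
  names(rounds) <- sim$rounds
  ref <- top_n_set(rounds$R3, 1000)
  spike <- cfg$spikes$sequence
  for (lab in sim$rounds) {
    m <- match_reference_set(ref, rounds[[lab]])
    want <- sim$truth$sampled_count[sim$truth$round == lab &
                                      sim$truth$sequence == spike]
    expect_equal(m$count[m$sequence == spike], want)
  }
})

test_that("composition profiles match the letter-count oracle and conserve mass", {
  one <- make_rc(strrep("G", 30), 12)
  expect_equal(composition(one)$overall[["G"]], 1)

  rep4 <- make_rc(strrep("ACGT", 3), 1)
  expect_equal(unname(composition(rep4)$overall), rep(0.25, 4))

  set.seed(17)
  seqs <- unique(random_cores(100, 30))
  counts <- sample(1:40, length(seqs), TRUE)
  prof <- composition(make_rc(seqs, counts))
  expect_equal(unname(prof$overall),
               oracle_overall_composition(seqs, counts), tolerance = 1e-12)
  expect_equal(sum(prof$overall), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(prof$per_position) - 1) < 1e-9))
  expect_equal(prof$purine + prof$pyrimidine, 1, tolerance = 1e-9)
  # read-weighted overall equals the mean of per-position rows
  expect_equal(unname(prof$overall), unname(colMeans(prof$per_position)))

  uprof <- composition(make_rc(seqs, counts), weighting = "unique")
  expect_equal(unname(uprof$overall),
               oracle_overall_composition(seqs, rep(1, length(seqs))),
               tolerance = 1e-12)
})

test_that("purine/pyrimidine aggregation matches published round-7 composition", {
  p <- composition_profile(c(A = 14.00, C = 23.00, T = 41.10, G = 22.00))
  pp <- purine_pyrimidine(p)
  expect_equal(round(100 * pp[["pyrimidine"]], 2), 64.10)
  expect_equal(round(100 * pp[["purine"]], 2), 36.00)

  allg <- composition_profile(c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(purine_pyrimidine(allg)[["purine"]], 1)
  uni <- composition_profile(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(unname(purine_pyrimidine(uni)), c(0.5, 0.5))
})
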