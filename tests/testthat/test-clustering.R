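test_that("edit distance is a metric-like kernel agreeing with recursion oracle", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("", "ACGT"), 4L)
  a <- "AATTCGTCAAAGTCGTTTATTTCGTCTGTG"
  b <- "AATTCGTCCATTTGTCGCTCATCGTCTGTG"
  expect_equal(edit_distance(a, b), oracle_levenshtein(a, b))
  expect_equal(edit_distance(a, b), edit_distance(b, a))
  set.seed(23)
  for (i in 1:10) {
    x <- random_cores(1, sample(4:12, 1))
    y <- random_cores(1, sample(4:12, 1))
    expect_equal(edit_distance(x, y), oracle_levenshtein(x, y))
  }
})

test_that("base-pair maximisation matches exhaustive enumeration for short RNAs", {
  expect_equal(fold_structure("AAAAA")$n_pairs, 0L)
  expect_equal(fold_structure("AAAAA")$dot_bracket, ".....")
  expect_equal(fold_structure("")$n_pairs, 0L)

  f <- fold_structure("GGGAAACCC")
  expect_equal(f$n_pairs, 3L)
  expect_equal(f$n_pairs, oracle_max_pairs("GGGAAACCC"))
  expect_valid_fold(f)

  set.seed(29)
  for (i in 1:25) {
    s <- random_cores(1, sample(5:12, 1))
    f <- fold_structure(s)
    expect_equal(f$n_pairs, oracle_max_pairs(s), info = s)
    expect_valid_fold(f)
  }
})

test_that("folding is deterministic and respects the wobble pair and T=U", {
  expect_identical(fold_structure("GGGAAACCC")$dot_bracket,
                   fold_structure("GGGAAACCC")$dot_bracket)
  # G pairs with U (and T transliterated to U)
  expect_equal(fold_structure("GAAAU")$n_pairs, 1L)
  expect_equal(fold_structure("GAAAT")$n_pairs, 1L)
  expect_equal(fold_structure("GAAAC")$n_pairs, 1L)
  expect_equal(fold_structure("AAAAC")$n_pairs, 0L)
})

test_that("structure distance is the symmetric difference of pair sets", {
  f1 <- fold_structure("GGGAAACCC")
  f2 <- fold_structure("AAAAAAAAA")
  expect_equal(structure_distance(f1, f1), 0L)
  expect_equal(structure_distance(f1, f2), f1$n_pairs)
  expect_equal(structure_distance(f1, f2), structure_distance(f2, f1))
  expect_error(structure_distance(f1, fold_structure("GGGAAACCCA")), "equal length")

  set.seed(31)
  for (i in 1:10) {
    a <- fold_structure(random_cores(1, 30))
    b <- fold_structure(random_cores(1, 30))
    k1 <- paste(a$pairs[, 1], a$pairs[, 2])
    k2 <- paste(b$pairs[, 1], b$pairs[, 2])
    want <- length(union(k1, k2)) - length(intersect(k1, k2))
    expect_equal(structure_distance(a, b), want)
  }
})

test_that("clustering groups identical and well-separated sequences correctly", {
  g1 <- cluster_top_sequences(rep(strrep("AC", 15), 5), c(9, 7, 5, 3, 1))
  expect_equal(length(g1), 1L)
  expect_equal(nrow(g1[[1]]$members), 5L)

  # maximally distant sequence families force two groups
  seqs <- c(strrep("A", 30), paste0(strrep("A", 29), "C"),
            strrep("C", 30), paste0(strrep("C", 29), "A"))
  g2 <- cluster_top_sequences(seqs, c(10, 8, 9, 7), threshold = 0.3)
  expect_equal(length(g2), 2L)
})

test_that("clustering recovers planted substitution families at defaults", {
  for (seed in c(101, 202, 303)) {
    fam <- family_fixture(seed)
    g <- cluster_top_sequences(fam$sequences, fam$counts)
    expect_equal(length(g), 3L, info = paste("seed", seed))
    # representative of each group is its most abundant member (the seed)
    reps <- vapply(g, `[[`, character(1), "representative")
    expect_setequal(reps, fam$seeds)
    # membership matches generation truth
    for (k in seq_along(g)) {
      f <- fam$family[match(g[[k]]$members$sequence, fam$sequences)]
      expect_equal(length(unique(f)), 1L)
    }
  }
})

test_that("clustering conserves reads and is invariant to input order", {
  fam <- family_fixture(404)
  g <- cluster_top_sequences(fam$sequences, fam$counts)
  expect_equal(sum(vapply(g, `[[`, numeric(1), "reads")), sum(fam$counts))

  perm <- sample(length(fam$sequences))
  g2 <- cluster_top_sequences(fam$sequences[perm], fam$counts[perm])
  reps1 <- vapply(g, `[[`, character(1), "representative")
  reps2 <- vapply(g2, `[[`, character(1), "representative")
  expect_equal(reps1, reps2)
  expect_equal(lapply(g, `[[`, "members"), lapply(g2, `[[`, "members"))

  expect_equal(length(cluster_top_sequences(character(0), numeric(0))), 0L)
})

test_that("low-count singletons are flagged as orphan sequences", {
  fam <- family_fixture(505)
  seqs <- c(fam$sequences, paste0(strrep("GATC", 7), "GA"),
            paste0(strrep("T", 29), "G"))
  counts <- c(fam$counts, 1, 1)
  g <- cluster_top_sequences(seqs, counts)
  orphans <- Filter(function(x) x$orphan, g)
  expect_gte(length(orphans), 2L)
  expect_true(all(vapply(orphans, function(x) nrow(x$members), integer(1)) == 1L))
})

test_that("group frequency reproduces published ratios and guards T_X = 0", {
  expect_equal(round(100 * group_frequency(619702, 771042), 2), 80.37)
  expect_equal(round(100 * group_frequency(102527, 16182954), 2), 0.63)
  expect_equal(group_frequency(0, 100), 0)
  expect_error(group_frequency(1, 0), "undefined")
})

test_that("fate classification reproduces annotated trajectories", {
  expect_equal(classify_fate(c(3.16, 45.58, 85.97, 84.05, 80.37)), "enriched")
  expect_equal(classify_fate(c(1, 2, 3, 4, 5)), "enriched")
  expect_equal(classify_fate(c(0, 4.80, 11.28, 1.60, 4.76)), "transient")
  expect_equal(classify_fate(c(10, 5, 1, 0.5, 0.2)), "depleted")
  expect_equal(classify_fate(c(5, 5, 5, 5)), "flat")
  expect_error(classify_fate(3.2), "two rounds")
})
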