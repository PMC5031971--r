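small_cfg <- function(seed, ...) {
  args <- list(seed = seed, n_template_species = 1000,
               depth_per_round = 5000, rounds = 3, ...)
  if (!"error_rate" %in% names(args)) args$error_rate <- 0
  do.call(sim_config, args)
}

test_that("configuration validation reports all problems at once", {
  err <- tryCatch(sim_config(seed = 1, rounds = 0, depth_per_round = 0,
                             error_rate = 2),
                  error = conditionMessage)
  expect_match(err, "rounds")
  expect_match(err, "depth_per_round")
  expect_match(err, "error_rate")
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1,
                          spikes = data.frame(sequence = strrep("A", 30),
                                              frequency = 1.2, s = 1)),
               "spike")
})

test_that("initial library places spikes at configured frequency and is seed-deterministic", {
  cfg <- sim_config(seed = 8, n_template_species = 20000,
                    depth_per_round = 1e5, rounds = 1, error_rate = 0)
  pop <- make_initial_library(cfg)
  expect_equal(sum(pop$weight), 1, tolerance = 1e-12)
  spike_w <- pop$weight[pop$sequence == cfg$spikes$sequence]
  expect_equal(spike_w, 0.0316, tolerance = 1e-9)

  # realised frequency at depth 1e5 within 3 binomial standard errors
  sim <- simulate_experiment(cfg)
  init <- sim$truth[sim$truth$round == "initial", ]
  got <- init$sampled_count[init$sequence == cfg$spikes$sequence] / 1e5
  se <- sqrt(0.0316 * (1 - 0.0316) / 1e5)
  expect_lt(abs(got - 0.0316), 3 * se)

  expect_identical(make_initial_library(cfg), make_initial_library(cfg))
})

test_that("uniform base weights yield a near-uniform composition", {
  cfg <- sim_config(seed = 12, n_template_species = 20000,
                    base_weights = c(A = 1, C = 1, G = 1, T = 1),
                    spikes = data.frame(sequence = character(0),
                                        frequency = numeric(0), s = numeric(0)),
                    rounds = 1, depth_per_round = 1000, error_rate = 0)
  pop <- make_initial_library(cfg)
  ch <- unlist(strsplit(pop$sequence, ""))
  frac <- as.vector(table(factor(ch, c("A", "C", "G", "T")))) / length(ch)
  se <- sqrt(0.25 * 0.75 / length(ch))
  expect_true(all(abs(frac - 0.25) < 3 * se))
})

test_that("selection reweights by multiplicative fitness", {
  pop <- data.frame(sequence = c(strrep("A", 30), strrep("C", 30)),
                    weight = c(0.01, 0.99), s = c(1, 0))
  post <- selection_step(pop)
  expect_equal(post$weight[1], 0.01 * 2 / (0.01 * 2 + 0.99))
  expect_equal(sum(post$weight), 1)

  neutral <- data.frame(sequence = pop$sequence, weight = c(0.3, 0.7), s = 0)
  expect_equal(selection_step(neutral)$weight, neutral$weight)

  # iterating the step matches the closed-form map w_i (1+s_i)^R
  set.seed(2)
  w <- runif(10); w <- w / sum(w)
  s <- c(rep(0, 8), 0.5, 2)
  pop2 <- data.frame(sequence = random_cores(10, 30), weight = w, s = s)
  iter <- pop2
  for (r in 1:5) iter <- selection_step(iter)
  closed <- w * (1 + s)^5
  expect_equal(iter$weight, closed / sum(closed), tolerance = 1e-12)
})

test_that("amplification bias follows the stated closed forms", {
  cfg <- small_cfg(1)
  pop <- data.frame(sequence = c(strrep("T", 30), strrep("A", 30)),
                    weight = c(0.5, 0.5), s = 0)
  post <- amplification_step(pop, cfg)   # solution_beta = 2
  expect_equal(post$weight[1] / post$weight[2], exp(2), tolerance = 1e-12)

  cfg0 <- small_cfg(1, solution_beta = 0)
  expect_equal(amplification_step(pop, cfg0)$weight, pop$weight)

  cfgd <- small_cfg(1, pcr_model = "droplet", droplet_capacity = 1)
  skew <- data.frame(sequence = random_cores(4, 30),
                     weight = c(0.7, 0.2, 0.06, 0.04), s = 0)
  expect_equal(amplification_step(skew, cfgd)$weight, rep(0.25, 4))
})

test_that("simulated experiments are byte-identical under one seed and differ across seeds", {
  cfg <- small_cfg(33, error_rate = 0.001)
  d1 <- simulate_experiment(cfg, tempfile())
  d2 <- simulate_experiment(cfg, tempfile())
  for (lab in d1$rounds) {
    expect_identical(readLines(d1$fastq[[lab]]), readLines(d2$fastq[[lab]]))
  }
  d3 <- simulate_experiment(small_cfg(34, error_rate = 0.001), tempfile())
  expect_false(identical(readLines(d1$fastq[["R1"]]),
                         readLines(d3$fastq[["R1"]])))
})

test_that("per-round depth is conserved and weights stay normalised", {
  cfg <- small_cfg(44)
  sim <- simulate_experiment(cfg)
  for (lab in sim$rounds) {
    fq <- parse_fastq(sim$fastq[[lab]])
    expect_equal(nrow(fq), cfg$depth_per_round)
    tr <- sim$truth[sim$truth$round == lab, ]
    expect_equal(sum(tr$sampled_count),
                 cfg$depth_per_round)  # spikes always recorded; others sampled>0
  }
  pop <- make_initial_library(cfg)
  for (r in 1:4) {
    pop <- amplification_step(selection_step(pop), cfg)
    expect_equal(sum(pop$weight), 1, tolerance = 1e-12)
  }
})

test_that("the spiked high-affinity sequence enriches monotonically in expectation", {
  cfg <- sim_config(seed = 55, n_template_species = 2000, depth_per_round = 2e4,
                    rounds = 5, error_rate = 0)
  pop <- make_initial_library(cfg)
  freqs <- pop$weight[pop$sequence == cfg$spikes$sequence]
  for (r in 1:5) {
    pop <- amplification_step(selection_step(pop), cfg)
    freqs <- c(freqs, pop$weight[pop$sequence == cfg$spikes$sequence])
  }
  expect_true(all(diff(freqs) > 0))

  sim <- simulate_experiment(cfg)
  spike_traj <- sapply(sim$rounds, function(lab) {
    tr <- sim$truth[sim$truth$round == lab, ]
    tr$sampled_count[tr$sequence == cfg$spikes$sequence] / cfg$depth_per_round
  })
  # realised counts within 3 multinomial sigma of the expected trajectory
  for (k in seq_along(freqs)) {
    se <- sqrt(freqs[k] * (1 - freqs[k]) / cfg$depth_per_round)
    expect_lt(abs(spike_traj[k] - freqs[k]), 3 * se + 1e-12)
  }
})

test_that("solution-PCR drift raises T composition across seeded replicates", {
  deltas <- vapply(1:20, function(sd) {
    cfg <- sim_config(seed = 1000 + sd, n_template_species = 1000,
                      depth_per_round = 2000, rounds = 4, error_rate = 0,
                      spikes = data.frame(sequence = character(0),
                                          frequency = numeric(0),
                                          s = numeric(0)),
                      background_s = list(prob = 0, mean = 1))
    sim <- simulate_experiment(cfg)
    tfrac <- function(lab) {
      tr <- sim$truth[sim$truth$round == lab & sim$truth$sampled_count > 0, ]
      sum(tr$sampled_count * base_fraction_test(tr$sequence)) / sum(tr$sampled_count)
    }
    tfrac("R4") - tfrac("initial")
  }, numeric(1))
  # sign test: neutral-selection solution PCR should raise T essentially always
  expect_gte(sum(deltas > 0), 17)
  binom <- stats::binom.test(sum(deltas > 0), 20, p = 0.5, alternative = "greater")
  expect_lt(binom$p.value, 0.01)
})

test_that("droplet amplification preserves diversity relative to solution PCR", {
  f_top <- function(model, seed) {
    cfg <- sim_config(seed = seed, n_template_species = 2000,
                      depth_per_round = 10000, rounds = 5, error_rate = 0,
                      pcr_model = model, droplet_capacity = 50)
    sim <- simulate_experiment(cfg)
    tr <- sim$truth[sim$truth$round == "R5" & sim$truth$sampled_count > 0, ]
    rc <- round_counts(tr$sequence, tr$sampled_count, round_label = "R5")
    top_total_and_frequency(top_n_set(rc, 1000))$f
  }
  for (seed in c(71, 72, 73)) {
    expect_lt(f_top("droplet", seed), f_top("solution", seed))
  }
})

test_that("JSON configuration round-trips through read_sim_config", {
  cfg <- small_cfg(99)
  dir <- tempfile()
  simulate_experiment(cfg, dir)
  cfg2 <- read_sim_config(file.path(dir, "sim_config.json"))
  expect_equal(cfg2$base_weights, cfg$base_weights)
  expect_equal(cfg2$spikes$sequence, cfg$spikes$sequence)
  expect_equal(cfg2$pcr_model, cfg$pcr_model)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 1, bogus_key = 2), bad, auto_unbox = TRUE)
  expect_error(read_sim_config(bad), "bogus_key")
})
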