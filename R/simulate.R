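# Simulator-defined constant region: the 21-nt 3'-fixed oligo that, with a
# 30-nt core, exactly fills a 51-cycle single-end read.
SIM_FIXED3 <- "TGGAATCCGCTACGGTCAGAA"

#' Configure a synthetic SELEX experiment
#'
#' Bundles every parameter of the generator: the initial library (size,
#' per-base composition weights, spiked biased sequences), the selection
#' model (multiplicative fitness `1 + s`), the amplification-bias model
#' (solution PCR versus droplet digital PCR), sequencing depth, read
#' synthesis error rate and the master seed. Defaults emulate a scaled-down
#' seven-round cell-SELEX on a moderately biased synthetic library: one
#' spiked biased sequence starting at 3.16% of the pool, initial base
#' composition matching published solution-PCR / ddPCR converted libraries,
#' 51-nt reads and 1e5 reads per sequenced round.
#'
#' @param seed master seed; every random draw of the experiment flows from
#'   this single value.
#' @param core_length random-region length, nt.
#' @param fixed3_sequence simulator 3'-fixed oligo (DNA alphabet).
#' @param read_length sequencing read length (cycles).
#' @param n_template_species number of distinct background sequences in
#'   the initial library.
#' @param base_weights named per-base sampling weights for background
#'   synthesis; `NULL` selects a published initial-pool composition by
#'   `pcr_model` (solution: A 22.5, C 22.6, T 28.1, G 26.8; droplet:
#'   A 19.9, C 24.4, T 24.5, G 31.2 - the droplet default carries the
#'   G-rich synthesis bias switch).
#' @param spikes data.frame with columns `sequence`, `frequency`, `s`:
#'   biased sequences placed at fixed initial frequencies with selection
#'   coefficient `s >= 0`.
#' @param background_s list `(prob, mean)`: each background species gets
#'   `s = 0` except with probability `prob`, where `s` is drawn
#'   exponentially with the given mean (a small high-affinity tail).
#' @param rounds number of selection rounds (the initial library is
#'   sequenced additionally, giving `rounds + 1` FASTQ files).
#' @param depth_per_round sequencing reads per round.
#' @param pcr_model `"solution"` or `"droplet"`.
#' @param solution_beta solution-PCR thymidine advantage: each round a
#'   sequence's weight is multiplied by `exp(solution_beta * T-fraction)`,
#'   so with `beta > 0` the pool's expected T composition never decreases.
#' @param droplet_capacity droplet-PCR cap on amplified copies per
#'   distinct template per round, expressed at sequencing-depth scale
#'   (expected copies in `depth_per_round`); capping flattens abundances
#'   and preserves diversity.
#' @param droplet_g_beta optional per-round G-fraction advantage under the
#'   droplet model (default 0: the G bias is applied at library synthesis
#'   via `base_weights`, not per amplification round; both switches are
#'   exposed because sequencing alone cannot separate them).
#' @param error_rate per-base substitution probability during read
#'   synthesis.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       core_length = 30L,
                       fixed3_sequence = SIM_FIXED3,
                       read_length = 51L,
                       n_template_species = 5e4,
                       base_weights = NULL,
                       spikes = data.frame(
                         sequence = "TTTCGTCCTGAGTTCGTGTCCTCGTCTGTG",
                         frequency = 0.0316, s = 2.5,
                         stringsAsFactors = FALSE),
                       background_s = list(prob = 0.01, mean = 0.5),
                       rounds = 7L,
                       depth_per_round = 1e5,
                       pcr_model = c("solution", "droplet"),
                       solution_beta = 2,
                       droplet_capacity = 1000,
                       droplet_g_beta = 0,
                       error_rate = 0.001) {
  pcr_model <- match.arg(pcr_model)
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (is.null(base_weights)) {
    base_weights <- if (pcr_model == "solution") {
      c(A = 0.225, C = 0.226, G = 0.268, T = 0.281)
    } else {
      c(A = 0.199, C = 0.244, G = 0.312, T = 0.245)
    }
  }
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(seed) && length(seed) == 1 && seed == round(seed),
      "seed must be a single integer")
  chk(core_length > 0, "core_length must be positive")
  chk(nchar(fixed3_sequence) > 0 && grepl("^[ACGT]+$", fixed3_sequence),
      "fixed3_sequence must be a non-empty A/C/G/T string")
  chk(read_length > core_length, "read_length must exceed core_length")
  chk(n_template_species >= 1, "n_template_species must be >= 1")
  chk(all(c("A", "C", "G", "T") %in% names(base_weights)) &&
        all(base_weights >= 0) && sum(base_weights) > 0,
      "base_weights must be non-negative and named A, C, G, T")
  chk(is.data.frame(spikes) &&
        all(c("sequence", "frequency", "s") %in% names(spikes)),
      "spikes must be a data.frame with sequence, frequency, s")
  if (is.data.frame(spikes) && nrow(spikes)) {
    chk(all(nchar(spikes$sequence) == core_length),
        "spike sequences must be core_length nt")
    chk(all(spikes$frequency >= 0) && sum(spikes$frequency) < 1,
        "spike frequencies must be in [0,1) and sum below 1")
    chk(all(spikes$s >= 0), "spike selection coefficients must be >= 0")
  }
  chk(rounds >= 1, "rounds must be >= 1")
  chk(depth_per_round >= 1, "depth_per_round must be positive")
  chk(solution_beta >= 0, "solution_beta must be >= 0")
  chk(droplet_capacity > 0, "droplet_capacity must be positive")
  chk(error_rate >= 0 && error_rate < 1, "error_rate must be in [0,1)")
  if (length(problems)) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(list(seed = as.integer(seed), core_length = as.integer(core_length),
                 fixed3_sequence = fixed3_sequence,
                 read_length = as.integer(read_length),
                 n_template_species = as.integer(n_template_species),
                 base_weights = base_weights, spikes = spikes,
                 background_s = background_s, rounds = as.integer(rounds),
                 depth_per_round = as.integer(depth_per_round),
                 pcr_model = pcr_model, solution_beta = solution_beta,
                 droplet_capacity = droplet_capacity,
                 droplet_g_beta = droplet_g_beta,
                 error_rate = error_rate),
            class = "sim_config")
}

#' Library layout implied by a simulator configuration
#'
#' @param config a [sim_config()].
#' @return the [library_layout()] matching the simulated reads.
#' @export
sim_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  library_layout(config$fixed3_sequence, core_length = config$core_length)
}

#' Draw the initial, unselected library
#'
#' Spiked biased sequences are placed at their configured frequencies;
#' background species are synthesised i.i.d. per base from the
#' configuration's base weights and share the remaining probability mass
#' equally. Selection coefficients are attached per species (spikes as
#' configured; background mostly 0 with a small exponential high-affinity
#' tail). Resets the RNG to the configuration seed, so the same
#' configuration always yields the same population.
#'
#' @param config a [sim_config()].
#' @return object of class `selex_population`: data.frame `sequence`,
#'   `weight` (frequencies summing to 1), `s`.
#' @export
make_initial_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spikes <- config$spikes
  bg <- unique(random_cores(config$n_template_species, config$core_length,
                            config$base_weights))
  bg <- setdiff(bg, spikes$sequence)
  # reject cores carrying an internal near-match of the fixed oligo: their
  # reads would be trimmed inside the random region and could never be
  # observed as usable, so they cannot be part of the tracked library
  lay <- sim_layout(config)
  if (nrow(spikes)) {
    sp_ok <- extract_core(paste0(spikes$sequence, config$fixed3_sequence),
                          lay) == spikes$sequence
    if (!all(sp_ok)) {
      stop("spike sequence(s) would be trimmed inside the random region: ",
           paste(spikes$sequence[!sp_ok], collapse = ", "))
    }
  }
  survives <- extract_core(paste0(bg, config$fixed3_sequence), lay) == bg
  bg <- bg[survives]
  if (length(bg) == 0 && sum(spikes$frequency) < 1) {
    stop("infeasible configuration: no background species to carry the remaining mass")
  }
  bg_mass <- 1 - sum(spikes$frequency)
  s_bg <- ifelse(stats::runif(length(bg)) < config$background_s$prob,
                 stats::rexp(length(bg), rate = 1 / config$background_s$mean),
                 0)
  pop <- data.frame(
    sequence = c(spikes$sequence, bg),
    weight = c(spikes$frequency, rep(bg_mass / length(bg), length(bg))),
    s = c(spikes$s, s_bg),
    stringsAsFactors = FALSE)
  pop$weight <- pop$weight / sum(pop$weight)
  class(pop) <- c("selex_population", "data.frame")
  pop
}

#' Apply one round of affinity selection
#'
#' Post-selection weights are proportional to `weight * (1 + s)`; species
#' with `s = 0` therefore decline in relative frequency whenever any
#' positive `s` is present, and a fully neutral population is unchanged.
#'
#' @param pop a `selex_population`.
#' @param config a [sim_config()] (unused beyond validation; kept for a
#'   uniform step signature).
#' @return the reweighted population.
#' @export
selection_step <- function(pop, config = NULL) {
  stopifnot(nrow(pop) > 0)
  w <- pop$weight * (1 + pop$s)
  pop$weight <- w / sum(w)
  pop
}

#' Apply one round of PCR amplification bias
#'
#' Solution model: each sequence's weight is multiplied by
#' `exp(solution_beta * tfrac)` where `tfrac` is the T fraction of its
#' core - a whole-sequence amplification advantage for thymidine-rich
#' templates. Droplet model: expected copy numbers at sequencing-depth
#' scale are capped at `droplet_capacity` per distinct template before
#' renormalisation, the idealisation of equal template partitioning into
#' uniform droplets; an optional `droplet_g_beta` adds a per-round
#' G-fraction advantage.
#'
#' @param pop a `selex_population`.
#' @param config a [sim_config()].
#' @return the reweighted population.
#' @export
amplification_step <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"), nrow(pop) > 0)
  if (config$pcr_model == "solution") {
    w <- pop$weight * exp(config$solution_beta * base_fraction(pop$sequence, "T"))
  } else {
    copies <- pop$weight * config$depth_per_round
    w <- pmin(copies, config$droplet_capacity)
    if (config$droplet_g_beta != 0) {
      w <- w * exp(config$droplet_g_beta * base_fraction(pop$sequence, "G"))
    }
  }
  pop$weight <- w / sum(w)
  pop
}

# multinomial read sampling + read synthesis with substitution errors
sample_round <- function(pop, config, round_label) {
  counts <- as.vector(stats::rmultinom(1, config$depth_per_round, pop$weight))
  keep <- counts > 0
  cores <- rep(pop$sequence[keep], counts[keep])
  full <- paste0(cores, config$fixed3_sequence)
  short <- nchar(full) < config$read_length
  if (any(short)) full[short] <- paste0(full[short], strrep("A", config$read_length))
  reads <- substr(full, 1, config$read_length)
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(length(reads), config$read_length, config$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(config$read_length, n_err[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }
  list(counts = counts, reads = reads,
       ids = sprintf("sim_%s_%06d", round_label, seq_along(reads)))
}

#' Simulate a full SELEX experiment
#'
#' Generates the initial library, then iterates selection, amplification
#' and multinomial sequencing at the configured depth for each round,
#' writing one gzip FASTQ per sequenced pool (`initial`, `R1`, ...,
#' `R<rounds>`) plus a ground-truth table and a JSON echo of the
#' configuration. All randomness flows from the configuration seed, so a
#' given configuration reproduces byte-identical output.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `config`, `dir`, `layout`, `fastq` (named paths),
#'   `truth` (data.frame `round`, `sequence`, `true_count` - the expected
#'   copy number `weight * depth` before read sampling - and
#'   `sampled_count`; species never sampled in a round are omitted) and
#'   `rounds` (the round labels in order).
#' @export
simulate_experiment <- function(config,
                                out_dir = tempfile("selex_sim_")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- make_initial_library(config)
  labels <- c("initial", paste0("R", seq_len(config$rounds)))
  fastq <- character(0)
  truth <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    if (k > 1) {
      pop <- amplification_step(selection_step(pop, config), config)
    }
    smp <- sample_round(pop, config, labels[k])
    path <- file.path(out_dir, paste0(labels[k], ".fastq.gz"))
    write_fastq(path, smp$ids, smp$reads)
    fastq[labels[k]] <- path
    keep <- smp$counts > 0 | pop$sequence %in% config$spikes$sequence
    truth[[k]] <- data.frame(round = labels[k],
                             sequence = pop$sequence[keep],
                             true_count = pop$weight[keep] * config$depth_per_round,
                             sampled_count = smp$counts[keep],
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  cfg$base_weights <- as.list(cfg$base_weights)
  cfg$spikes <- as.list(cfg$spikes)
  jsonlite::write_json(cfg, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  list(config = config, dir = out_dir, layout = sim_layout(config),
       fastq = fastq, truth = truth, rounds = labels)
}
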