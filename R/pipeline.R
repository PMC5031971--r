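#' Configure an end-to-end SELEX analysis
#'
#' @param fastq named character vector of FASTQ paths, one per sequenced
#'   round, in round order (names are the round labels; the first is
#'   taken as the unselected library).
#' @param layout a [library_layout()].
#' @param top_n top-set size for enrichment statistics (default 1000).
#' @param cluster_top number of top unique sequences to cluster
#'   (default 50).
#' @param alpha,threshold clustering parameters, see
#'   [cluster_top_sequences()].
#' @param reference_round round label whose top set is matched across all
#'   rounds and clustered (default: the last round).
#' @param out_dir optional output directory for report files.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(fastq, layout, top_n = 1000L, cluster_top = 50L,
                              alpha = 0.85, threshold = 0.25,
                              reference_round = NULL, out_dir = NULL) {
  stopifnot(inherits(layout, "library_layout"))
  if (length(fastq) < 1L) stop("need at least one round of FASTQ input")
  if (is.null(names(fastq)) || any(!nzchar(names(fastq)))) {
    stop("fastq paths must be named by round label")
  }
  reference_round <- reference_round %||% names(fastq)[length(fastq)]
  if (!reference_round %in% names(fastq)) {
    stop("reference_round must be one of the round labels")
  }
  structure(list(fastq = fastq, layout = layout, top_n = as.integer(top_n),
                 cluster_top = as.integer(cluster_top), alpha = alpha,
                 threshold = threshold, reference_round = reference_round,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full SELEX analysis pipeline
#'
#' Processes every round's FASTQ into counted cores, computes the
#' enrichment series (usable-read percentages, top-N totals and
#' frequencies, molecular-enrichment folds), per-round nucleotide
#' composition, the reference-round top set matched across all rounds,
#' aptamer-family clustering of the reference round's top sequences, and
#' per-family round trajectories with fate labels. All tabulated numbers
#' are also emitted unrounded in a JSON report when `out_dir` is set.
#'
#' @param config an [experiment_config()].
#' @return a report list with elements `rounds` (list of
#'   [round_counts()]), `series`, `composition` (list of profiles),
#'   `composition_table`, `reference_match`, `groups`, `group_table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  missing <- config$fastq[!file.exists(config$fastq)]
  if (length(missing)) {
    stop("stage read_processing: missing FASTQ file(s): ",
         paste(missing, collapse = ", "))
  }
  rounds <- lapply(names(config$fastq), function(lab) {
    message(sprintf("[read_processing] %s: %s", lab, config$fastq[[lab]]))
    rc <- process_round(config$fastq[[lab]], config$layout, lab)
    message(sprintf("[read_processing] %s: %.0f reads, %.0f usable",
                    lab, rc$total_reads, rc$usable_reads))
    rc
  })
  names(rounds) <- names(config$fastq)

  series <- enrichment_series(rounds, config$top_n)

  profiles <- lapply(rounds, composition)
  composition_table <- do.call(rbind, lapply(names(profiles), function(lab) {
    p <- profiles[[lab]]
    data.frame(round = lab, A = p$overall["A"], C = p$overall["C"],
               G = p$overall["G"], T = p$overall["T"],
               purine = p$purine, pyrimidine = p$pyrimidine,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  reference <- top_n_set(rounds[[config$reference_round]], config$top_n)
  reference_match <- lapply(rounds, function(rc) match_reference_set(reference, rc))

  ranked_ref <- utils::head(rank_unique(rounds[[config$reference_round]]),
                            config$cluster_top)
  groups <- cluster_top_sequences(ranked_ref$sequence, ranked_ref$count,
                                  alpha = config$alpha,
                                  threshold = config$threshold)
  gtab <- group_round_table(groups, rounds, config$top_n)

  report <- list(rounds = rounds, series = series, composition = profiles,
                 composition_table = composition_table,
                 reference_match = reference_match, groups = groups,
                 group_table = gtab)
  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

#' Per-round trajectories of aptamer-family groups
#'
#' Tracks every group of a clustering across rounds by exact matching of
#' its member sequences, sums member read counts per round, divides by the
#' round's top-N read total, and classifies each trajectory's fate.
#' Orphan singleton groups are aggregated into a single `Others` row, as
#' is conventional in family-evolution tables.
#'
#' @param groups a [cluster_top_sequences()] result.
#' @param rounds named list of [round_counts()] in round order.
#' @param n top-set size defining the frequency denominator `T_X`.
#' @return data.frame with columns `group`, `representative`, `members`,
#'   per-round `reads_*` and `pct_*` columns, and `fate`.
#' @export
group_round_table <- function(groups, rounds, n = 1000L) {
  stopifnot(inherits(groups, "selex_groups"), length(rounds) >= 1L)
  labs <- names(rounds) %||% paste0("round", seq_along(rounds))
  t_x <- vapply(rounds, function(rc) sum(top_n_set(rc, n)$entries$count),
                numeric(1))
  member_counts <- function(members, rc) {
    idx <- match(members, rc$core_counts$sequence)
    sum(ifelse(is.na(idx), 0, rc$core_counts$count[idx]))
  }
  is_orphan <- vapply(groups, `[[`, logical(1), "orphan")
  rows <- list()
  for (g in groups[!is_orphan]) {
    reads <- vapply(rounds, member_counts, numeric(1), members = g$members$sequence)
    rows[[length(rows) + 1L]] <- c(list(group = as.character(g$group_id),
                                        representative = g$representative,
                                        members = nrow(g$members)),
                                   as.list(reads))
  }
  if (any(is_orphan)) {
    orphan_members <- unlist(lapply(groups[is_orphan],
                                    function(g) g$members$sequence))
    reads <- vapply(rounds, member_counts, numeric(1), members = orphan_members)
    rows[[length(rows) + 1L]] <- c(list(group = "Others",
                                        representative = "orphan sequences",
                                        members = length(orphan_members)),
                                   as.list(reads))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, col.names = c(
      "group", "representative", "members", paste0("reads_", labs)))
  }))
  pct <- sweep(as.matrix(out[, paste0("reads_", labs), drop = FALSE]),
               2, t_x, "/") * 100
  colnames(pct) <- paste0("pct_", labs)
  out <- cbind(out, as.data.frame(pct))
  out$fate <- if (length(rounds) >= 2L) apply(pct, 1, classify_fate)
              else NA_character_
  rownames(out) <- NULL
  out
}

write_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  tsv <- function(d, path) utils::write.table(d, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  fmt <- report$series
  fmt$pct_usable <- sprintf("%.2f%%", fmt$pct_usable)
  fmt$pct_top_in_usable <- sprintf("%.3f%%", fmt$pct_top_in_usable)
  fmt$enrichment_fold <- sprintf("%.2f", fmt$enrichment_fold)
  tsv(fmt, out("round_summary.tsv"))
  ct <- report$composition_table
  for (cl in c("A", "C", "G", "T", "purine", "pyrimidine")) {
    ct[[cl]] <- sprintf("%.2f%%", 100 * ct[[cl]])
  }
  tsv(ct, out("composition.tsv"))
  per_pos <- do.call(rbind, lapply(names(report$composition), function(lab) {
    m <- report$composition[[lab]]$per_position
    data.frame(round = lab, position = seq_len(nrow(m)), m,
               stringsAsFactors = FALSE)
  }))
  tsv(per_pos, out("composition_per_position.tsv"))
  gt <- report$group_table
  for (cl in grep("^pct_", names(gt), value = TRUE)) {
    gt[[cl]] <- sprintf("%.2f%%", gt[[cl]])
  }
  tsv(gt, out("group_table.tsv"))
  for (lab in names(report$reference_match)) {
    tsv(report$reference_match[[lab]],
        out(sprintf("reference_match_%s.tsv", lab)))
  }
  for (lab in names(report$rounds)) {
    write_core_counts(report$rounds[[lab]],
                      out(sprintf("core_counts_%s.tsv", lab)))
  }
  db <- vapply(report$groups, function(g)
    sprintf("group %s %s %s", g$group_id, g$representative,
            g$representative_fold$dot_bracket), character(1))
  writeLines(db, out("structures.txt"))
  raw <- list(
    rounds = report$series,
    composition = report$composition_table,
    groups = report$group_table)
  jsonlite::write_json(raw, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(config$out_dir)
}

#' Read a simulator configuration from JSON
#'
#' Accepts the dialect written by [simulate_experiment()] (`sim_config.json`)
#' or any JSON object with [sim_config()] argument names; unknown keys are
#' an error, and all validation problems are reported together.
#'
#' @param path JSON file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$spikes)) {
    sp <- raw$spikes
    raw$spikes <- if (length(sp) == 0 || all(lengths(sp) == 0)) {
      data.frame(sequence = character(0), frequency = numeric(0),
                 s = numeric(0), stringsAsFactors = FALSE)
    } else {
      as.data.frame(sp, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(raw$base_weights)) raw$base_weights <- unlist(raw$base_weights)
  do.call(sim_config, raw)
}

#' Simulate an experiment and emit a ready-to-run analysis configuration
#'
#' Delegates to [simulate_experiment()] and writes an
#' `experiment_config.json` next to the generated FASTQ files so the
#' output directory is immediately consumable by [run_pipeline()].
#'
#' @param config a [sim_config()] or the path to a JSON file for
#'   [read_sim_config()].
#' @param out_dir output directory.
#' @return list with `sim` (the [simulate_experiment()] result) and
#'   `experiment_config` (an [experiment_config()] pointing at it).
#' @export
run_simulate <- function(config, out_dir = tempfile("selex_sim_")) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_experiment(config, out_dir)
  ec <- experiment_config(sim$fastq, sim$layout)
  jsonlite::write_json(list(fastq = as.list(sim$fastq),
                            fixed3_sequence = config$fixed3_sequence,
                            core_length = config$core_length,
                            reference_round = ec$reference_round),
                       file.path(out_dir, "experiment_config.json"),
                       auto_unbox = TRUE, digits = NA)
  list(sim = sim, experiment_config = ec)
}
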