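#!/usr/bin/env Rscript
# Recompute the statistics of the published CCR7/CD2 HT-SELEX study from
# its printed inputs (round totals, group reads, compositions) using the
# package's statistic implementations, and tabulate them.

suppressPackageStartupMessages(library(htselex))

ext <- function(f) system.file("extdata", f, package = "htselex")
summ <- read.delim(ext("published_round_summary.tsv"))
grp <- read.delim(ext("published_group_reads.tsv"))
comp <- read.delim(ext("published_composition_by_round.tsv"))

# per-experiment enrichment series from the printed totals
rows <- do.call(rbind, lapply(split(summ, summ$experiment), function(d) {
  d <- d[order(match(d$round, c("initial", paste0("R", 1:9)))), ]
  data.frame(experiment = d$experiment, round = d$round,
             pct_usable = round(100 * d$usable_reads / d$total_reads, 2),
             pct_top1000 = round(100 * d$top1000_reads / d$usable_reads, 3),
             enrichment_fold = round(vapply(d$top1000_reads, enrichment_fold,
                                            numeric(1),
                                            t_0 = d$top1000_reads[1]), 2))
}))
dir.create("results", showWarnings = FALSE)
write.table(rows, "results/published_round_statistics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("round statistics (per experiment):")
print(rows[rows$round == "R7", ], row.names = FALSE)

# group frequencies vs top-1000 totals, with fates
gf <- merge(grp[!is.na(grp$aptamer), ],
            summ[, c("experiment", "round", "top1000_reads")],
            by = c("experiment", "round"))
gf$pct_top1000 <- round(100 * mapply(group_frequency, gf$reads,
                                     gf$top1000_reads), 2)
ord <- c("initial", paste0("R", 1:9))
gf <- gf[order(gf$experiment, gf$aptamer, match(gf$round, ord)), ]
fates <- do.call(rbind, lapply(split(gf, list(gf$experiment, gf$aptamer),
                                     drop = TRUE), function(d) {
  data.frame(experiment = d$experiment[1], aptamer = d$aptamer[1],
             fate = classify_fate(d$pct_top1000))
}))
write.table(gf, "results/published_group_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fates, "results/published_group_fates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "biased sequence C-1A/H-8: %.2f%% initially; %.2f%% (CCR7 R7) vs %.2f%% (CD2 R7)",
  gf$pct_top1000[gf$aptamer == "C-1A" & gf$round == "initial" &
                   gf$experiment == "ccr7_solution"],
  gf$pct_top1000[gf$aptamer == "C-1A" & gf$round == "R7" &
                   gf$experiment == "ccr7_solution"],
  gf$pct_top1000[gf$aptamer == "H-8" & gf$round == "R7"]))

# purine/pyrimidine shift per arm and round
pp <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
  r <- comp[i, ]
  v <- purine_pyrimidine(composition_profile(
    c(A = r$A, C = r$C, T = r$T, G = r$G)))
  data.frame(experiment = r$experiment, round = r$round,
             pct_purine = round(100 * v[["purine"]], 1),
             pct_pyrimidine = round(100 * v[["pyrimidine"]], 1))
}))
write.table(pp, "results/published_purine_pyrimidine.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("round-7 purine/pyrimidine:")
print(pp[pp$round == "R7", ], row.names = FALSE)
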