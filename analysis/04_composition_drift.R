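#!/usr/bin/env Rscript
# Nucleotide-composition drift across selection rounds: the published
# values beside the simulated pipelines' read-weighted compositions, plus
# the purine/pyrimidine shift that tracks 2'-F pyrimidine incorporation.

suppressPackageStartupMessages(library(htselex))

ext <- function(f) system.file("extdata", f, package = "htselex")
pub <- read.delim(ext("published_composition_by_round.tsv"))
pub_long <- data.frame(source = "published", experiment = pub$experiment,
                       round = pub$round, A = pub$A, C = pub$C,
                       T = pub$T, G = pub$G)

sim_long <- do.call(rbind, lapply(c("solution", "droplet"), function(model) {
  path <- file.path("results", paste0("sim_", model), "composition.tsv")
  if (!file.exists(path)) stop("run analysis/03_pipeline_on_simulated.R first")
  d <- read.delim(path)
  pct <- function(x) as.numeric(sub("%", "", x))
  data.frame(source = "simulated", experiment = model, round = d$round,
             A = pct(d$A), C = pct(d$C), T = pct(d$T), G = pct(d$G))
}))

both <- rbind(pub_long, sim_long)
both$pct_purine <- round(both$A + both$G, 1)
both$pct_pyrimidine <- round(both$C + both$T, 1)
write.table(both, "results/composition_drift.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (src in c("published", "simulated")) {
  d <- both[both$source == src & both$experiment %in% c("solution"), ]
  message(sprintf(
    "%s solution-PCR: T %.1f%% -> %.1f%%; pyrimidine %.1f%% -> %.1f%%",
    src, d$T[d$round == "initial"], d$T[d$round == "R7"],
    d$pct_pyrimidine[d$round == "initial"], d$pct_pyrimidine[d$round == "R7"]))
}
message("wrote results/composition_drift.tsv")
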