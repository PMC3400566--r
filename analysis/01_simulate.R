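#!/usr/bin/env Rscript
# Generate the synthetic de-etiolation study dataset: a toy genome with
# planted H2Bub domains per condition (dark, 1 h and 6 h of light), a
# NimbleGen-style tile layout, dye-swap ChIP replicates, and CATMA-style
# expression ratios for the five comparisons. Writes the inputs every
# later stage consumes, plus the ground truth used for evaluation.

suppressPackageStartupMessages({
  library(h2bdyn)
  library(readr)
})

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)

write_genes_gff3(sim$genes, file.path(out_dir, "genes.gff3"))
write_tsv(sim$tiles, file.path(out_dir, "tiles.tsv"))
write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
write_tsv(sim$expr, file.path(out_dir, "expression_ratios.tsv"))
for (cond in cfg$conditions) {
  for (r in seq_len(cfg$n_replicates)) {
    sub <- sim$chip[sim$chip$condition == cond & sim$chip$replicate == r, ]
    write_track_bedgraph(
      sub, file.path(out_dir, sprintf("chip_%s_rep%d.bedgraph", cond, r)))
  }
}

message(sprintf("genome: %d genes on %d chromosomes; %d tiles",
                nrow(sim$genes), cfg$n_chromosomes, nrow(sim$tiles)))
message(sprintf("planted: %d stable-marked, %d gain-1h, %d gain-6h, %d loss-6h",
                sum(sim$truth$category == "stable"),
                sum(sim$truth$category == "gain_1h"),
                sum(sim$truth$category == "gain_6h"),
                sum(sim$truth$category == "loss_6h")))
message(sprintf("planted DE: %d up-1h, %d up-6h, %d up&down, %d down",
                sum(sim$truth$expr_class == "up_1h"),
                sum(sim$truth$expr_class == "up_6h"),
                sum(sim$truth$expr_class == "up_and_down"),
                sum(sim$truth$expr_class %in% c("down_1h", "down_6h"))))
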