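#!/usr/bin/env Rscript
# Normalize the tiling signal and call H2Bub-enriched domains per
# condition (EM-fitted two-state HMM, stringent 0.95 posterior), then call
# differentially enriched domains between the time points with the
# moderated moving-average statistic + HMM decode.

suppressPackageStartupMessages({
  library(h2bdyn)
  library(readr)
  library(dplyr)
})

data_dir <- "results/data"
out_dir <- "results/domains"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tiles <- read_tsv(file.path(data_dir, "tiles.tsv"), show_col_types = FALSE)
conds <- c("D", "1h", "6h")
paths <- lapply(setNames(conds, conds), function(cc) {
  file.path(data_dir, sprintf("chip_%s_rep%d.bedgraph", cc, 1:2))
})
chip <- read_tracks(paths, tiles)

tracks <- combine_all_conditions(chip, conds)
domains <- list()
for (cond in conds) {
  fit <- fit_hmm(tracks[[cond]])
  domains[[cond]] <- call_domains(tracks[[cond]], fit, label = cond)
  write_track_bedgraph(tracks[[cond]],
                       file.path(out_dir, paste0("track_", cond, ".bedgraph")))
  message(sprintf(
    "%s: mu_bg=%.2f mu_enr=%.2f, %d domains (median %d tiles)",
    cond, fit$mu_bg, fit$mu_enr, nrow(domains[[cond]]),
    median(domains[[cond]]$n_tiles)))
}
all_domains <- bind_rows(domains)
write_tsv(all_domains, file.path(out_dir, "domains.tsv"))
write_domains_bed(all_domains, file.path(out_dir, "domains.bed"))

comparisons <- c("1h_vs_D", "6h_vs_D", "6h_vs_1h")
diff_domains <- list()
for (comp in comparisons) {
  parts <- strsplit(comp, "_vs_")[[1]]
  st <- differential_score(chip, parts[2], parts[1])
  for (dir in c("gain", "loss")) {
    dd <- suppressWarnings(call_differential_domains(st, dir, comp))
    diff_domains[[paste(comp, dir)]] <- dd
    message(sprintf("%s %s: %d domains", comp, dir, nrow(dd)))
  }
}
diff_domains <- bind_rows(diff_domains)
write_tsv(diff_domains, file.path(out_dir, "differential_domains.tsv"))
write_domains_bed(diff_domains,
                  file.path(out_dir, "differential_domains.bed"))
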