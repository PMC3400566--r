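#!/usr/bin/env Rscript
# Integrate chromatin and expression: mark-by-response cross-tabs, rank
# tests on per-gene H2Bub levels, metagene profiles, the expression-vs-
# H2Bub change scatter with quadrant correlations and LOWESS trend,
# marked-fraction by expression bin, set over-representation, and the
# three-criterion candidate screen evaluated against the planted truth.

suppressPackageStartupMessages({
  library(h2bdyn)
  library(readr)
  library(dplyr)
})

data_dir <- "results/data"
dom_dir <- "results/domains"
mark_dir <- "results/marking"
expr_dir <- "results/expression"
out_dir <- "results/integration"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genes <- read_genes_gff3(file.path(data_dir, "genes.gff3"))
tiles <- read_tsv(file.path(data_dir, "tiles.tsv"), show_col_types = FALSE)
truth <- read_tsv(file.path(data_dir, "truth.tsv"), show_col_types = FALSE)
mm <- read_tsv(file.path(mark_dir, "mark_matrix.tsv"),
               show_col_types = FALSE)
categories <- read_tsv(file.path(mark_dir, "gain_loss_categories.tsv"),
                       show_col_types = FALSE)
de <- read_tsv(file.path(expr_dir, "de_table.tsv"), show_col_types = FALSE)
classes <- read_tsv(file.path(expr_dir, "light_response_classes.tsv"),
                    show_col_types = FALSE)
defective <- readLines(file.path(expr_dir, "defective_up_genes.txt"))

conds <- c("D", "1h", "6h")
tracks <- lapply(setNames(conds, conds), function(cc) {
  tr <- read_bedgraph(file.path(dom_dir,
                                paste0("track_", cc, ".bedgraph")))
  tr$tile_id <- tiles$tile_id[match(paste(tr$chrom, tr$start),
                                    paste(tiles$chrom, tiles$start))]
  tr
})

## per-gene mean levels and rank tests (up vs down at 6 h)
levels <- gene_mean_levels(tracks, genes, tiles)
write_tsv(levels, file.path(out_dir, "gene_mean_levels.tsv"))
up6 <- classes$gene_id[classes$up_6h]
down6 <- classes$gene_id[classes$down_6h]
sets <- list(
  up_D = levels$level_D[levels$gene_id %in% up6],
  up_6h = levels$`level_6h`[levels$gene_id %in% up6],
  down_D = levels$level_D[levels$gene_id %in% down6],
  down_6h = levels$`level_6h`[levels$gene_id %in% down6])
rc <- rank_compare(sets)
write_tsv(rc, file.path(out_dir, "rank_tests.tsv"))
message("rank-sum p (up genes, 6h vs D levels): ",
        signif(rc$p[rc$set1 == "up_D" & rc$set2 == "up_6h"], 3))

## cross-tab of mark gain/loss by light-response class
gain_set <- unique(categories$gene_id[categories$direction == "gain"])
loss_set <- unique(categories$gene_id[categories$direction == "loss"])
response <- list(up_6h = up6, down_6h = down6)
ct <- crosstab_mark_by_response(
  response, gain_set, loss_set, mm,
  marked_at = c(up_6h = "6h", down_6h = "D"),
  expression_universe = unique(de$gene_id))
write_tsv(ct, file.path(out_dir, "crosstab_mark_by_response.tsv"))
message("percent of eligible up-6h genes gaining H2Bub: ",
        round(ct$percent[ct$class == "up_6h" & ct$category == "gain"], 1))

## metagene profiles of up-and-marked vs down-and-marked genes
marked6 <- mm$gene_id[mm$`6h`]
markedD <- mm$gene_id[mm$D]
prof <- metagene(list(up_marked_6h = intersect(up6, marked6),
                      down_marked_D = intersect(down6, markedD)),
                 genes, tracks$`6h`, tiles)
write_tsv(prof, file.path(out_dir, "metagene_profiles.tsv"))

## expression-change vs H2Bub-change scatter (6 h vs dark)
summ <- delta_summary(levels, de, "wt_6h_vs_D", "D", "6h")
ds <- delta_scatter(summ)
write_tsv(ds$quadrants, file.path(out_dir, "delta_quadrants.tsv"))
write_tsv(ds$overall, file.path(out_dir, "delta_overall.tsv"))
write_tsv(ds$lowess, file.path(out_dir, "delta_lowess.tsv"))
message("overall r (up subset): ",
        round(ds$overall$r[ds$overall$subset == "up"], 3),
        "; (down subset): ",
        round(ds$overall$r[ds$overall$subset == "down"], 3))

## marked fraction by expression level bin (proxy: mean wt dark-ratio rank)
expr_level <- de %>% filter(comparison == "wt_6h_vs_D") %>%
  mutate(bin = dplyr::ntile(mean_log2, 5)) %>%
  select(gene_id, bin)
mf <- marked_fraction_by_expression(mm, expr_level, conds)
write_tsv(mf, file.path(out_dir, "marked_fraction_by_expression.tsv"))

## set over-representation of planted chromatin categories among the
## candidates' pool (annotation sets built from the planted truth)
universe <- genes$gene_id
ann <- list(planted_gain = truth$gene_id[truth$category %in%
                                           c("gain_1h", "gain_6h")],
            planted_stable = truth$gene_id[truth$category == "stable"],
            planted_unmarked = truth$gene_id[truth$category == "unmarked"])

## candidate screen: light-induced + H2Bub gain + defective in the mutant
wt_de <- de %>% filter(comparison %in% c("wt_1h_vs_D", "wt_6h_vs_D"))
up_genes <- unique(wt_de$gene_id[wt_de$de_flag == "up"])
gain_vs_dark <- categories %>%
  filter(direction == "gain", comparison %in% c("1h_vs_D", "6h_vs_D"))
cand <- select_candidates(up_genes, gain_vs_dark, defective)
write_tsv(cand, file.path(out_dir, "candidates.tsv"))
planted <- planted_candidates(truth)
message(sprintf("candidates: %d called, %d planted; sensitivity %.3f, false rate %.3f",
                nrow(cand), length(planted),
                mean(planted %in% cand$gene_id),
                if (nrow(cand)) mean(!(cand$gene_id %in% planted)) else 0))

enr <- set_enrichment(cand$gene_id, ann, universe)
write_tsv(enr, file.path(out_dir, "candidate_set_enrichment.tsv"))
message("candidate over-representation of planted-gain genes: p = ",
        signif(enr$p_over[enr$set == "planted_gain"], 3))
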