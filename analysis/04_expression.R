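#!/usr/bin/env Rscript
# Differential expression for the five comparisons (moderated one-sample t
# + Bonferroni), light-response kinetic classes including the transient
# Up&Down set, overlap of the mutant-dark misregulation with the wild-type
# light response, and SOM partitioning of the four light comparisons.

suppressPackageStartupMessages({
  library(h2bdyn)
  library(readr)
  library(dplyr)
})

data_dir <- "results/data"
out_dir <- "results/expression"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

expr <- read_tsv(file.path(data_dir, "expression_ratios.tsv"),
                 show_col_types = FALSE)
truth <- read_tsv(file.path(data_dir, "truth.tsv"), show_col_types = FALSE)

de <- call_de(expr, alpha = 0.05, correction = "bonferroni")
write_tsv(de, file.path(out_dir, "de_table.tsv"))
message("DE counts per comparison:")
print(de %>% filter(de_flag != "ns") %>% count(comparison, de_flag))

classes <- classify_light_response(de, fold_threshold = 2)
write_tsv(classes, file.path(out_dir, "light_response_classes.tsv"))
message(sprintf("kinetic classes: %d up-1h, %d up-6h, %d up&down, %d down-6h",
                sum(classes$up_1h), sum(classes$up_6h),
                sum(classes$up_and_down), sum(classes$down_6h)))

ov <- overlap_with_mutant(classes, de)
write_tsv(ov, file.path(out_dir, "mutant_dark_overlap.tsv"))
message("fraction of light classes mimicked by the mutant in darkness:")
print(ov)

mat <- som_input_matrix(de)
som <- som_cluster(mat, grid_rows = 4, grid_cols = 4, seed = 1,
                   iterations = 5000)
write_tsv(som$assignment, file.path(out_dir, "som_assignment.tsv"))
write_tsv(som$profiles, file.path(out_dir, "som_profiles.tsv"))
parts <- identify_defective_partitions(som, "defective_up")
defective <- som$assignment$gene_id[som$assignment$partition %in% parts]
writeLines(defective, file.path(out_dir, "defective_up_genes.txt"))
message(sprintf("SOM: %d genes clustered; defective-up partitions {%s} hold %d genes",
                nrow(mat), paste(parts, collapse = ","),
                length(defective)))
planted_def <- truth$gene_id[
  truth$hub_defective &
    truth$expr_class %in% c("up_1h", "up_6h", "up_and_down")]
message(sprintf("planted defective-up recovery: %.3f",
                mean(planted_def %in% defective)))
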