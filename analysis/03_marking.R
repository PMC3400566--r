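#!/usr/bin/env Rscript
# Decide per-gene H2Bub marking via the central-40% rule, tabulate the
# condition-wise Venn partition of marked genes, and combine differential
# domains with marking status into de-novo-gain / increased / loss gene
# categories. Evaluates the calls against the planted truth.

suppressPackageStartupMessages({
  library(h2bdyn)
  library(readr)
  library(dplyr)
})

data_dir <- "results/data"
dom_dir <- "results/domains"
out_dir <- "results/marking"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genes <- read_genes_gff3(file.path(data_dir, "genes.gff3"))
truth <- read_tsv(file.path(data_dir, "truth.tsv"), show_col_types = FALSE)
domains <- read_tsv(file.path(dom_dir, "domains.tsv"),
                    show_col_types = FALSE)
diff_domains <- read_tsv(file.path(dom_dir, "differential_domains.tsv"),
                         show_col_types = FALSE)

conds <- c("D", "1h", "6h")
crit <- marking_criterion()
mm <- build_mark_matrix(
  genes, lapply(setNames(conds, conds),
                function(cc) domains[domains$condition == cc, ]), crit)
write_tsv(mm, file.path(out_dir, "mark_matrix.tsv"))

for (cond in conds) {
  planted <- truth[[paste0("marked_", cond)]]
  called <- mm[[cond]][match(truth$gene_id, mm$gene_id)]
  message(sprintf("%s: %d marked called; recall %.3f, false rate %.3f",
                  cond, sum(called), mean(called[planted]),
                  mean(called[!planted])))
}

venn <- venn_partitions(mm, conds)
venn_out <- venn
venn_out$gene_ids <- vapply(venn$gene_ids, paste, "", collapse = ",")
write_tsv(venn_out, file.path(out_dir, "venn_partitions.tsv"))
jsonlite::write_json(setNames(as.list(venn$n), venn$class),
                     file.path(out_dir, "venn_counts.json"),
                     auto_unbox = TRUE)
message("Venn counts: ",
        paste(venn$class, venn$n, sep = "=", collapse = ", "))

categories <- bind_rows(lapply(c("1h_vs_D", "6h_vs_D", "6h_vs_1h"),
                               function(comp) {
  combine_differential_with_marking(diff_domains, genes, mm, comp, crit)
}))
write_tsv(categories, file.path(out_dir, "gain_loss_categories.tsv"))
message("category counts:")
print(count(categories, comparison, direction, subtype))

lq <- length_quantiles(genes, 8, c(1000, 3000))
write_tsv(lq, file.path(out_dir, "length_quantiles.tsv"))
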