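#!/usr/bin/env Rscript
# Step 1: generate the synthetic staged dataset with planted ground truth.
#
# Emulates the structure of the real study: 20 ordered stages, UMI counts
# with ERCC spike-in rows, sex-linked genes planted into MSCI categories,
# and fold-change steps planted between consecutive stages. Writes the
# fixture set (MTX + TSVs + truth tables) under results/data/.

suppressPackageStartupMessages(library(spermdyn))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_dataset(sim_spec(), seed = 20260921)

write_count_matrix(sim$counts, "results/data/counts.mtx",
                   "results/data/genes.tsv", "results/data/cells.tsv")
write.table(sim$cell_meta, "results/data/cell_meta.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$gene_annotation, "results/data/gene_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$msci, "results/data/truth_msci.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
deg_truth <- do.call(rbind, lapply(names(sim$truth$degs), function(k) {
  d <- sim$truth$degs[[k]]
  data.frame(transition = k,
             gene_id = c(d$up, d$down),
             direction = rep(c("up", "down"), c(length(d$up), length(d$down))))
}))
write.table(deg_truth, "results/data/truth_degs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sd_log(sprintf("simulated %d genes x %d cells across %d stages",
               length(sim$counts$genes), length(sim$counts$cells),
               length(unique(sim$cell_meta$stage))))
sd_log(sprintf("planted %d sex-linked category labels and %d DEG transitions",
               nrow(sim$truth$msci), length(sim$truth$degs)))
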