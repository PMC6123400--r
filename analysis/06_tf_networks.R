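#!/usr/bin/env Rscript
# Step 6: TF co-expression networks across the two major transitions.
# Mitotic-to-meiotic pools clusters C1+C2 (correlation > 0.35);
# meiotic-to-postmeiotic pools C4+C6 (correlation > 0.45); TFs keep at
# least 3 edges after pruning.

suppressPackageStartupMessages(library(spermdyn))

cm <- read_count_matrix("results/data/counts.mtx", "results/data/genes.tsv",
                        "results/data/cells.tsv")
meta <- read_cell_meta("results/data/cell_meta.tsv")
anno <- read_gene_annotation("results/data/gene_annotation.tsv")
lg <- log_expr(tpm(cm))
tfs <- anno$gene_id[anno$is_tf]
sd_log(sprintf("%d annotated TFs", length(tfs)))

for (cfg in list(list(tag = "mitotic_to_meiotic", clusters = c("C1", "C2")),
                 list(tag = "meiotic_to_postmeiotic",
                      clusters = c("C4", "C6")))) {
  cells <- meta$cell_id[meta$cluster %in% cfg$clusters]
  net <- withCallingHandlers(
    tf_network(lg, cells, tfs, transition = cfg$tag),
    warning = function(w) { sd_log(conditionMessage(w), "warn")
                            invokeRestart("muffleWarning") })
  write.table(net$edges, sprintf("results/tf_edges_%s.tsv", cfg$tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(tf = net$nodes),
              sprintf("results/tf_nodes_%s.tsv", cfg$tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sd_log(sprintf("%s: %d TFs, %d edges above %.2f", cfg$tag,
                 length(net$nodes), nrow(net$edges), net$threshold))
}
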