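#!/usr/bin/env Rscript
# Step 2: cell quality control and normalization.
#
# The published QC rule (> 40% mapping, > 2000 detected genes, 20k-1M UMI)
# states the detected-gene bound in units of the full ~20k-gene annotation;
# this scaled-down simulation keeps the study's sequencing depth (~3e5 UMI
# per cell) but carries ~1.1k genes, so only the detected-gene bound is
# rescaled by the gene-count ratio. Spike-in size factors are written for
# the later steps.

suppressPackageStartupMessages(library(spermdyn))
dir.create("results", showWarnings = FALSE)

cm <- read_count_matrix("results/data/counts.mtx", "results/data/genes.tsv",
                        "results/data/cells.tsv")
meta <- read_cell_meta("results/data/cell_meta.tsv")

n_endo <- length(cm$genes) - length(cm$spike_rows)
scale <- n_endo / 20088
th <- qc_thresholds(min_mapping_rate = 0.40,
                    min_genes_detected = round(2000 * scale),
                    umi_min = 20000, umi_max = 1e6)
qc <- qc_filter(cm, meta, th)
sd_log(sprintf("QC kept %d of %d cells", length(qc$kept), length(cm$cells)))
write.table(qc$rejected, "results/qc_rejected.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

kept <- subset_cells(cm, qc$kept)
f <- spike_size_factors(kept)
write.table(data.frame(cell_id = names(f), size_factor = f),
            "results/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
# the normalized/TPM/log matrices are cheap to recompute, so later steps
# rebuild them from the MTX fixtures instead of reading bulky tables
norm <- normalize_counts(kept, f)
tp <- tpm(kept)
sd_log(sprintf("size factors span [%.2f, %.2f], mean 1", min(f), max(f)))
sd_log(sprintf("TPM columns sum to 1e6 (max deviation %.1e)",
               max(abs(colSums(tp) - 1e6))))
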