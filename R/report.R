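# Publication-style summaries: percentage arithmetic, expressed-gene tallies,
# and per-stage detected-gene / normalized-UMI distributions.

#' Percentage with half-up rounding to one decimal
#'
#' round-half-up(100 * numerator / denominator, 1), the arithmetic behind all
#' reported fractions (e.g. 637 of 817 is 78.0).
#'
#' @param numerator,denominator Counts with 0 <= numerator <= denominator,
#'   denominator > 0.
#' @return Percentage with one decimal.
#' @export
percentage <- function(numerator, denominator) {
  if (denominator <= 0) {
    sd_stop("denominator must be positive", "spermdyn_validation_error")
  }
  if (numerator < 0 || numerator > denominator) {
    sd_stop("numerator must lie in [0, denominator]",
            "spermdyn_validation_error")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Expressed-gene tallies by biotype and chromosome class
#'
#' A gene counts as expressed when TPM >= 1 in at least `min_cells` cells
#' (default 1). Tallies are split by biotype and by chromosome class
#' (autosome / X / Y), and the splits are additive by construction.
#'
#' @param expr TPM matrix over endogenous genes.
#' @param annotation Gene annotation data.frame.
#' @param min_tpm Detection threshold (TPM >= min_tpm).
#' @param min_cells Minimum number of cells reaching the threshold.
#' @return List with `by_biotype` and `by_chromosome_class` data.frames
#'   (annotated genes, expressed genes, percentage) and the expressed gene
#'   ids.
#' @export
expressed_tally <- function(expr, annotation, min_tpm = 1, min_cells = 1) {
  anno <- annotation[annotation$biotype != "spike_in", , drop = FALSE]
  present <- intersect(anno$gene_id, rownames(expr))
  expressed <- present[rowSums(expr[present, , drop = FALSE] >= min_tpm) >=
                         min_cells]
  anno$expressed <- anno$gene_id %in% expressed
  anno$chrom_class <- ifelse(anno$chromosome %in% c("X", "Y"),
                             anno$chromosome, "autosome")
  tally <- function(key) {
    n <- tapply(anno$expressed, anno[[key]], length)
    k <- tapply(anno$expressed, anno[[key]], sum)
    data.frame(group = names(n), n_annotated = as.integer(n),
               n_expressed = as.integer(k),
               pct = mapply(percentage, as.integer(k), as.integer(n)),
               row.names = NULL)
  }
  list(by_biotype = tally("biotype"),
       by_chromosome_class = tally("chrom_class"),
       expressed_genes = expressed)
}

five_number <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  c(whisker_lo = lo, q1 = q[1], median = q[2], q3 = q[3], whisker_hi = hi)
}

#' Per-stage distributions of detected genes and normalized UMI
#'
#' For each stage: median, quartiles and 1.5 x IQR whiskers of the per-cell
#' number of detected genes (TPM >= 1) and of the per-cell normalized UMI
#' total — the boxplot summaries of the per-stage sequencing profile.
#'
#' @param expr TPM matrix over endogenous genes.
#' @param norm_counts Size-factor-normalized count matrix.
#' @param stages Stage labels per cell (named by cell id or in column order).
#' @return data.frame: one row per stage and measure (genes / umi) with the
#'   five summary numbers, cell count, and a `degenerate` flag for
#'   single-cell stages.
#' @export
per_stage_gene_umi_profile <- function(expr, norm_counts, stages) {
  if (!is.null(names(stages))) stages <- stages[colnames(expr)]
  genes_per_cell <- colSums(expr >= 1)
  umi_per_cell <- Matrix::colSums(norm_counts)[colnames(expr)]
  levs <- intersect(stage_codes(), unique(stages))
  rows <- lapply(levs, function(s) {
    sel <- stages == s
    rbind(
      data.frame(stage = s, measure = "genes_detected",
                 t(five_number(genes_per_cell[sel])),
                 n_cells = sum(sel), degenerate = sum(sel) < 2),
      data.frame(stage = s, measure = "normalized_umi",
                 t(five_number(umi_per_cell[sel])),
                 n_cells = sum(sel), degenerate = sum(sel) < 2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
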