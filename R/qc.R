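# Cell-level quality control, spike-in size factors, TPM and log transforms.
#
# Two distinct detection rules exist and are never conflated:
#   * QC gene detection: UMI count strictly > 1 ("transcript number > 1");
#   * expression analyses: TPM >= 1.

#' Quality-control thresholds
#'
#' Defaults are the study's filtering rules: mapping rate strictly > 40%,
#' number of detected genes strictly > 2000, and total UMI (over endogenous,
#' non-spike genes) between 20,000 and 1,000,000 inclusive.
#'
#' @param min_mapping_rate Exclusive lower bound on mapping rate.
#' @param min_genes_detected Exclusive lower bound on detected genes.
#' @param umi_min,umi_max Inclusive bounds on total endogenous UMI.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_mapping_rate = 0.40, min_genes_detected = 2000,
                          umi_min = 20000, umi_max = 1e6) {
  if (umi_min >= umi_max) {
    sd_stop("umi_min must be below umi_max", "spermdyn_config_error")
  }
  structure(list(min_mapping_rate = min_mapping_rate,
                 min_genes_detected = min_genes_detected,
                 umi_min = umi_min, umi_max = umi_max),
            class = "qc_thresholds")
}

#' Number of detected genes in one cell
#'
#' A gene is detected when its transcript (UMI) count is strictly greater
#' than 1.
#'
#' @param cell_counts Numeric vector of per-gene UMI counts for one cell
#'   (endogenous genes only).
#' @return Integer count of detected genes.
#' @export
genes_detected <- function(cell_counts) {
  sum(cell_counts > 1)
}

endo_counts <- function(cm) {
  if (length(cm$spike_rows)) cm$counts[-cm$spike_rows, , drop = FALSE]
  else cm$counts
}

#' Per-cell detected genes and UMI totals over endogenous genes
#'
#' @param cm A [count_matrix()].
#' @return data.frame with `cell_id`, `genes_detected` (UMI > 1 rule) and
#'   `total_umi` (spike-ins excluded).
#' @export
cell_qc_stats <- function(cm) {
  endo <- endo_counts(cm)
  data.frame(cell_id = cm$cells,
             genes_detected = Matrix::colSums(endo > 1),
             total_umi = Matrix::colSums(endo),
             row.names = NULL)
}

#' Filter cells on the three quality-control criteria
#'
#' A cell is kept iff mapping_rate > 40%, detected genes > 2000, and its total
#' endogenous UMI lies in \[20,000, 1,000,000\] (defaults; see
#' [qc_thresholds()]). Every rejected cell is reported with the full list of
#' criteria it failed.
#'
#' @param cm A [count_matrix()].
#' @param meta Cell metadata data.frame with `cell_id` and `mapping_rate`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` (character vector of cell ids), `rejected`
#'   (data.frame of cell_id and semicolon-separated failure reasons) and the
#'   per-cell `stats` table.
#' @export
qc_filter <- function(cm, meta, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!all(cm$cells %in% meta$cell_id)) {
    sd_stop("metadata missing for some cells", "spermdyn_validation_error")
  }
  rate <- meta$mapping_rate[match(cm$cells, meta$cell_id)]
  if (anyNA(rate)) {
    sd_stop("mapping_rate missing for some cells", "spermdyn_validation_error")
  }
  st <- cell_qc_stats(cm)
  fail <- cbind(
    mapping_rate   = !(rate > thresholds$min_mapping_rate),
    genes_detected = !(st$genes_detected > thresholds$min_genes_detected),
    total_umi      = !(st$total_umi >= thresholds$umi_min &
                       st$total_umi <= thresholds$umi_max))
  bad <- rowSums(fail) > 0
  rejected <- data.frame(
    cell_id = cm$cells[bad],
    reasons = apply(fail[bad, , drop = FALSE], 1,
                    function(f) paste(colnames(fail)[f], collapse = ";")),
    row.names = NULL)
  list(kept = cm$cells[!bad], rejected = rejected, stats = st)
}

#' Subset a count matrix to a set of cells
#'
#' @param cm A [count_matrix()].
#' @param cells Character vector of cell ids to keep.
#' @return A [count_matrix()] restricted to those cells.
#' @export
subset_cells <- function(cm, cells) {
  idx <- match(cells, cm$cells)
  if (anyNA(idx)) sd_stop("unknown cell ids", "spermdyn_validation_error")
  out <- cm
  out$counts <- cm$counts[, idx, drop = FALSE]
  out$cells <- cm$cells[idx]
  out
}

#' Spike-in size factors
#'
#' The per-cell technical size factor is the cell's total spike-in count
#' divided by the mean spike-in total over cells, so the factors always
#' average to 1. Spike-ins are added at fixed amounts per cell, so this ratio
#' captures per-cell capture/sequencing efficiency.
#'
#' @param cm A [count_matrix()] with spike-in rows.
#' @return Named numeric vector of positive per-cell factors, mean 1.
#' @export
spike_size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!length(cm$spike_rows)) {
    sd_stop("no spike-in rows in matrix", "spermdyn_normalization_error")
  }
  tot <- Matrix::colSums(cm$counts[cm$spike_rows, , drop = FALSE])
  if (any(tot <= 0)) {
    sd_stop(paste("zero spike-in total in cell(s):",
                  paste(cm$cells[tot <= 0], collapse = ", ")),
            "spermdyn_normalization_error")
  }
  f <- tot / mean(tot)
  names(f) <- cm$cells
  f
}

#' Normalize counts by size factors
#'
#' Divides each cell's counts by its size factor; optionally returns
#' log2(x + 1) of the normalized values.
#'
#' @param cm A [count_matrix()].
#' @param factors Positive per-cell factors (named or in cell order).
#' @param log2 If TRUE, apply log2(x + 1) after scaling.
#' @return A genes x cells `Matrix` of normalized values.
#' @export
normalize_counts <- function(cm, factors, log2 = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(names(factors))) factors <- factors[cm$cells]
  if (length(factors) != length(cm$cells) || any(!is.finite(factors)) ||
      any(factors <= 0)) {
    sd_stop("size factors must be positive, one per cell",
            "spermdyn_validation_error")
  }
  out <- cm$counts %*% Matrix::Diagonal(x = 1 / factors)
  dimnames(out) <- dimnames(cm$counts)
  if (log2) out <- log2(out + 1)
  out
}

#' Transcripts-per-million expression
#'
#' For UMI data, TPM is the per-cell count fraction times 1e6 with no
#' gene-length term (UMIs already count molecules). Spike-in genes are
#' excluded from the denominator and returned separately via the `spike`
#' attribute (scaled by the same endogenous denominator).
#'
#' @param cm A [count_matrix()].
#' @return Dense numeric matrix of TPM over endogenous genes (columns sum to
#'   1e6), with attribute `spike` holding the scaled spike-in rows.
#' @export
tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  endo <- endo_counts(cm)
  tot <- Matrix::colSums(endo)
  if (any(tot <= 0)) {
    sd_stop(paste("zero endogenous UMI total in cell(s):",
                  paste(cm$cells[tot <= 0], collapse = ", ")),
            "spermdyn_validation_error")
  }
  out <- as.matrix(endo %*% Matrix::Diagonal(x = 1e6 / tot))
  colnames(out) <- cm$cells
  if (length(cm$spike_rows)) {
    sp <- as.matrix(cm$counts[cm$spike_rows, , drop = FALSE] %*%
                      Matrix::Diagonal(x = 1e6 / tot))
    colnames(sp) <- cm$cells
    attr(out, "spike") <- sp
  }
  out
}

#' Log-scale expression transform
#'
#' Elementwise log2(TPM / 10 + 1), the working scale for clustering,
#' differential expression and network analysis.
#'
#' @param expr Non-negative TPM matrix.
#' @return Matrix of log2(TPM/10 + 1) values.
#' @export
log_expr <- function(expr) {
  if (any(expr < 0)) {
    sd_stop("expression values must be non-negative", "spermdyn_validation_error")
  }
  log2(expr / 10 + 1)
}
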