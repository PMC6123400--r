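# Differential expression: equal-variance t-test, BH adjustment, and the
# log-scale average-difference statistic, plus the splicing-regulator and
# surface-marker screens.

#' Average log-scale expression difference
#'
#' The fold-change statistic for log2(TPM/10 + 1) data: groups are averaged on
#' the de-logged scale before re-logging,
#' log2(mean(2^x - 1) + 1) - log2(mean(2^y - 1) + 1).
#' Base 2 throughout, matching the log2 working scale and thresholds.
#'
#' @param x,y Numeric vectors of log2-scale values for the two groups.
#' @return The average difference in log2 units (positive when x > y).
#' @export
avg_log_diff <- function(x, y) {
  if (!length(x) || !length(y)) {
    sd_stop("both groups must be non-empty", "spermdyn_validation_error")
  }
  log2(mean(2^x - 1) + 1) - log2(mean(2^y - 1) + 1)
}

# row-wise version over matrices (genes x cells)
row_avg_log_diff <- function(a, b) {
  log2(rowMeans(2^a - 1) + 1) - log2(rowMeans(2^b - 1) + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up adjustment (monotone in rank, capped at 1) over the
#' supplied vector.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    sd_stop("p-values must lie in [0, 1]", "spermdyn_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorized two-sample equal-variance (Student) t-test over matrix rows.
# Genes whose pooled variance is zero get p = 1 (reported not-significant),
# which also covers the all-ties case without NaN propagation.
row_t_test <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  p[sp2 <= 0] <- 1
  list(mean_a = ma, mean_b = mb, t = tstat, p = p)
}

#' Differential-expression thresholds
#'
#' The default call requires p < 0.05 AND FDR < 0.05 AND |average difference|
#' strictly > 1 log2 unit. The screens use the inclusive variant
#' (FDR <= 0.05, |difference| >= 1).
#'
#' @param p Significance cut on the raw p-value (strict <).
#' @param fdr Cut on the BH-adjusted value.
#' @param diff Cut on the absolute average log2 difference.
#' @param inclusive If TRUE, the fdr and diff cuts are inclusive (<=, >=).
#' @return A list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(p = 0.05, fdr = 0.05, diff = 1, inclusive = FALSE) {
  structure(list(p = p, fdr = fdr, diff = diff, inclusive = inclusive),
            class = "deg_thresholds")
}

#' Per-gene differential expression between two cell groups
#'
#' Two-tailed Student's (equal-variance) t-test per gene on log2(TPM/10 + 1)
#' values, BH adjustment over all tested genes, and the [avg_log_diff()]
#' statistic. Calls: `up` when significant with difference above the cut,
#' `down` when significant with difference below minus the cut, else `ns`.
#'
#' @param mat Log-scale expression matrix (genes x cells, column names are
#'   cell ids).
#' @param cells_a,cells_b Disjoint character vectors of cell ids (each >= 2).
#' @param thresholds A [deg_thresholds()].
#' @return data.frame with gene_id, group means, avg_diff, p_value, fdr, call.
#' @export
deg_test <- function(mat, cells_a, cells_b, thresholds = deg_thresholds()) {
  if (length(intersect(cells_a, cells_b))) {
    sd_stop("cell groups overlap", "spermdyn_validation_error")
  }
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    sd_stop("each group needs at least 2 cells", "spermdyn_validation_error")
  }
  ia <- match(cells_a, colnames(mat)); ib <- match(cells_b, colnames(mat))
  if (anyNA(ia) || anyNA(ib)) {
    sd_stop("unknown cell ids", "spermdyn_validation_error")
  }
  a <- mat[, ia, drop = FALSE]; b <- mat[, ib, drop = FALSE]
  tt <- row_t_test(a, b)
  diff <- row_avg_log_diff(a, b)
  fdr <- bh_adjust(tt$p)
  th <- thresholds
  if (th$inclusive) {
    sig <- tt$p < th$p & fdr <= th$fdr
    up <- sig & diff >= th$diff
    down <- sig & diff <= -th$diff
  } else {
    sig <- tt$p < th$p & fdr < th$fdr
    up <- sig & diff > th$diff
    down <- sig & diff < -th$diff
  }
  data.frame(gene_id = rownames(mat),
             mean_a = tt$mean_a, mean_b = tt$mean_b,
             avg_diff = diff, p_value = tt$p, fdr = fdr,
             call = ifelse(up, "up", ifelse(down, "down", "ns")),
             row.names = NULL)
}

#' Screen splicing-regulator genes for differential expression
#'
#' [deg_test()] restricted to the annotated splicing-regulator set, with the
#' inclusive significance convention (p < 0.05, FDR <= 0.05,
#' |average difference| >= 1); BH is computed over the tested (regulator)
#' genes only.
#'
#' @param mat Log-scale expression matrix.
#' @param cells_a,cells_b Cell groups as in [deg_test()].
#' @param regulators Character vector of splicing-regulator gene ids.
#' @return data.frame as from [deg_test()], regulator genes only.
#' @export
splicing_regulator_screen <- function(mat, cells_a, cells_b, regulators) {
  if (!length(regulators)) {
    sd_stop("empty splicing-regulator set", "spermdyn_config_error")
  }
  present <- intersect(regulators, rownames(mat))
  if (!length(present)) {
    warning("no splicing-regulator genes present in the matrix")
    return(data.frame(gene_id = character(), mean_a = numeric(),
                      mean_b = numeric(), avg_diff = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      call = character()))
  }
  deg_test(mat[present, , drop = FALSE], cells_a, cells_b,
           thresholds = deg_thresholds(inclusive = TRUE))
}

#' Screen surface-marker genes per cluster
#'
#' One-vs-rest [deg_test()] for each cluster, restricted to annotated surface
#' markers and ranked by decreasing average difference, to find markers
#' specific to spermatid subpopulations.
#'
#' @param mat Log-scale expression matrix.
#' @param clusters Named character vector of cluster labels, names are cell
#'   ids (must cover the matrix columns used).
#' @param markers Character vector of surface-marker gene ids.
#' @return Named list (one data.frame per cluster) of ranked marker results.
#' @export
surface_marker_screen <- function(mat, clusters, markers) {
  clusters <- clusters[intersect(names(clusters), colnames(mat))]
  levs <- unique(clusters)
  if (length(levs) < 2) {
    sd_stop("need at least 2 clusters", "spermdyn_validation_error")
  }
  present <- intersect(markers, rownames(mat))
  if (!length(present)) {
    warning("no surface-marker genes present in the matrix")
    return(stats::setNames(vector("list", length(levs)), levs))
  }
  sub <- mat[present, names(clusters), drop = FALSE]
  out <- lapply(levs, function(cl) {
    res <- deg_test(sub, names(clusters)[clusters == cl],
                    names(clusters)[clusters != cl])
    res[order(-res$avg_diff), ]
  })
  stats::setNames(out, levs)
}
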