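# Transcript sharing between haploid spermatids: per-cell sex-linked
# expression loads and a silhouette-based separability score. Under
# intercellular transcript sharing, X- and Y-bearing spermatids are
# transcriptionally indistinguishable on sex-linked genes; without sharing
# they split into two clear groups.

#' Per-cell X- and Y-linked expression loads
#'
#' Sums of log-scale expression over X-linked and Y-linked protein-coding
#' genes for each cell of a stage.
#'
#' @param mat Log-scale expression matrix (genes x cells).
#' @param annotation Gene annotation data.frame.
#' @param cells Cell ids of the stage.
#' @return data.frame with cell_id, x_load, y_load.
#' @export
sex_load <- function(mat, annotation, cells) {
  idx <- match(cells, colnames(mat))
  if (anyNA(idx)) sd_stop("unknown cell ids", "spermdyn_validation_error")
  xg <- intersect(annotation$gene_id[annotation$chromosome == "X" &
                                     annotation$biotype == "protein_coding"],
                  rownames(mat))
  yg <- intersect(annotation$gene_id[annotation$chromosome == "Y" &
                                     annotation$biotype == "protein_coding"],
                  rownames(mat))
  if (!length(xg) && !length(yg)) {
    sd_stop("no sex-linked protein-coding genes in matrix",
            "spermdyn_validation_error")
  }
  data.frame(cell_id = cells,
             x_load = colSums(mat[xg, idx, drop = FALSE]),
             y_load = colSums(mat[yg, idx, drop = FALSE]),
             row.names = NULL)
}

#' Separability score of a stage's spermatids on sex-linked expression
#'
#' Cells are projected on the first principal axis of the sex-linked
#' log-expression submatrix and split by 2-means on that axis; the score is
#' the mean silhouette width of the split computed on Euclidean distances in
#' the full sex-linked submatrix. A high score means the stage's cells fall
#' into two separable groups (X- vs Y-bearing, no sharing); a score near
#' zero is consistent with transcript sharing. Degenerate input (all cells
#' identical) returns score -1 with a flag.
#'
#' @param mat Sex-linked log-scale submatrix (genes x cells, >= 4 cells).
#' @return List with `score` in \[-1, 1\], integer `partition` (1/2 per
#'   cell), and `degenerate` flag.
#' @export
separation_score <- function(mat) {
  n <- ncol(mat)
  if (n < 4) sd_stop("need at least 4 cells", "spermdyn_validation_error")
  x <- t(mat)
  if (all(apply(x, 2, stats::var) == 0)) {
    return(list(score = -1, partition = rep(1L, n), degenerate = TRUE))
  }
  pc1 <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, 1]
  km <- stats::kmeans(pc1, centers = 2, nstart = 10)
  part <- as.integer(km$cluster)
  if (length(unique(part)) < 2) {
    return(list(score = -1, partition = part, degenerate = TRUE))
  }
  sil <- cluster::silhouette(part, stats::dist(x))
  list(score = mean(sil[, "sil_width"]), partition = part, degenerate = FALSE)
}

#' Per-stage transcript-sharing report
#'
#' For each requested stage (metaphase and round-spermatid stages by
#' default): the separability score, the sizes of the two PC1 groups, and a
#' two-tailed Student's t-test of x_load between them. Note the t-test p is
#' selection-biased (the partition is chosen to separate), so it supports
#' the non-sharing alternative rather than calibrating the null.
#'
#' @param mat Full log-scale expression matrix.
#' @param annotation Gene annotation data.frame.
#' @param meta Cell metadata with cell_id and stage.
#' @param stages Stage codes to analyse.
#' @return data.frame, one row per stage: score, degenerate flag, group
#'   sizes, t-test p on x_load.
#' @export
sharing_report <- function(mat, annotation, meta,
                           stages = c("MI", "MII", "RS2", "RS4", "RS6", "RS8")) {
  sexg <- intersect(annotation$gene_id[annotation$chromosome %in% c("X", "Y") &
                                       annotation$biotype == "protein_coding"],
                    rownames(mat))
  if (!length(sexg)) {
    sd_stop("no sex-linked protein-coding genes in matrix",
            "spermdyn_validation_error")
  }
  rows <- lapply(intersect(stages, unique(meta$stage)), function(s) {
    cells <- intersect(meta$cell_id[meta$stage == s], colnames(mat))
    if (length(cells) < 4) return(NULL)
    sc <- separation_score(mat[sexg, cells, drop = FALSE])
    loads <- sex_load(mat, annotation, cells)
    g1 <- loads$x_load[sc$partition == 1]
    g2 <- loads$x_load[sc$partition == 2]
    p <- if (length(g1) >= 2 && length(g2) >= 2 &&
             (stats::var(g1) > 0 || stats::var(g2) > 0)) {
      stats::t.test(g1, g2, var.equal = TRUE)$p.value
    } else NA_real_
    data.frame(stage = s, score = sc$score, degenerate = sc$degenerate,
               n_group1 = sum(sc$partition == 1),
               n_group2 = sum(sc$partition == 2),
               xload_t_p = p, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(stage = character(), score = numeric(),
                      degenerate = logical(), n_group1 = integer(),
                      n_group2 = integer(), xload_t_p = numeric()))
  }
  do.call(rbind, rows)
}
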