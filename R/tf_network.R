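# Transcription-factor co-expression networks for the mitotic-to-meiotic and
# meiotic-to-postmeiotic transitions: thresholded correlation edges and
# minimum-degree pruning.

#' Pairwise TF correlations over pooled cells
#'
#' Pearson (default) correlation of log2(TPM/10 + 1) profiles over the pooled
#' cells of a cluster pair. TFs with zero variance are dropped with a
#' warning (their correlation is undefined).
#'
#' @param mat Log-scale expression matrix (genes x cells).
#' @param cells Character vector of cell ids to pool (>= 3).
#' @param tfs Character vector of transcription-factor gene ids.
#' @param method Correlation method, "pearson" or "spearman".
#' @return Symmetric correlation matrix over the retained TFs.
#' @export
tf_correlations <- function(mat, cells, tfs,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(cells) < 3) {
    sd_stop("need at least 3 cells for correlations", "spermdyn_validation_error")
  }
  idx <- match(cells, colnames(mat))
  if (anyNA(idx)) sd_stop("unknown cell ids", "spermdyn_validation_error")
  tfs <- intersect(tfs, rownames(mat))
  sub <- mat[tfs, idx, drop = FALSE]
  v <- apply(sub, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance TF(s)", sum(v == 0)))
    sub <- sub[v > 0, , drop = FALSE]
  }
  stats::cor(t(sub), method = method)
}

#' Build a pruned TF co-expression network
#'
#' Edges connect TF pairs whose correlation strictly exceeds the threshold
#' (signed; strong negative correlations do not form edges). Nodes with
#' degree below `min_degree` are then removed iteratively until a fixed point
#' (the k-core), so the emitted network satisfies both invariants: every edge
#' weight > threshold and every node degree >= `min_degree`. A `one_pass`
#' mode removes low-degree nodes only once.
#'
#' @param correlations Symmetric correlation matrix from [tf_correlations()].
#' @param threshold Edge threshold in (0, 1); 0.35 for the
#'   mitotic-to-meiotic transition, 0.45 for meiotic-to-postmeiotic.
#' @param min_degree Minimum node degree (default 3).
#' @param mode "iterative" (default) or "one_pass" pruning.
#' @return List of class `tf_network`: `nodes`, `edges` (tf1, tf2, weight)
#'   and the `igraph` graph.
#' @export
build_network <- function(correlations, threshold, min_degree = 3,
                          mode = c("iterative", "one_pass")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1) {
    sd_stop("threshold must lie in (0, 1)", "spermdyn_config_error")
  }
  adj <- correlations > threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    low <- deg < min_degree
    if (!any(low) || mode == "one_pass") {
      if (mode == "one_pass" && any(low)) keep[keep][low] <- FALSE
      break
    }
    keep[keep][low] <- FALSE
  }
  nodes <- rownames(adj)[keep]
  sub <- adj[keep, keep, drop = FALSE]
  idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(tf1 = nodes[idx[, 1]], tf2 = nodes[idx[, 2]],
                      weight = correlations[keep, keep][idx],
                      row.names = NULL)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  # in iterative mode the invariants hold by construction; assert anyway
  if (mode == "iterative" && length(nodes)) {
    stopifnot(all(igraph::degree(g) >= min_degree),
              all(edges$weight > threshold))
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold, min_degree = min_degree),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("tf_network: %d TFs, %d edges (correlation > %.2f, degree >= %d)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$min_degree))
  invisible(x)
}

#' TF co-expression network for a developmental transition
#'
#' Pools the cells of the two clusters flanking a transition and applies the
#' transition's correlation threshold: > 0.35 for mitotic-to-meiotic
#' (clusters C1 vs C2), > 0.45 for meiotic-to-postmeiotic (C4 vs C6), keeping
#' TFs with at least 3 edges.
#'
#' @param mat Log-scale expression matrix.
#' @param cells Pooled cell ids of the two clusters.
#' @param tfs Transcription-factor gene ids.
#' @param transition "mitotic_to_meiotic" or "meiotic_to_postmeiotic".
#' @param ... Passed to [build_network()].
#' @return A `tf_network` tagged with the transition.
#' @export
tf_network <- function(mat, cells, tfs,
                       transition = c("mitotic_to_meiotic",
                                      "meiotic_to_postmeiotic"), ...) {
  transition <- match.arg(transition)
  threshold <- if (transition == "mitotic_to_meiotic") 0.35 else 0.45
  cm <- tf_correlations(mat, cells, tfs)
  net <- build_network(cm, threshold = threshold, ...)
  net$transition <- transition
  net
}
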