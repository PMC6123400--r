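# Alternative-splicing post-processing: event consideration, AS-gene calls,
# the five-situation transition classifier between consecutive merged-stage
# samples, and the expression-splicing association.

#' Minimum in-band samples under the 10% branch
#'
#' The consideration rule requires an event to be mid-range in at least 10%
#' of the samples with sufficient coverage; with 50 covered samples the
#' threshold is 5. Ceiling is used (50 -> 5, 66 -> 7).
#'
#' @param n_cov Number of samples with sufficient coverage.
#' @return Integer threshold.
#' @export
consideration_threshold <- function(n_cov) {
  as.integer(ceiling(0.10 * n_cov))
}

#' Is a splice event considered?
#'
#' An event is considered when its inclusion value lies in \[10, 90\] in at
#' least 10% of the sufficiently covered samples, OR in at least 3 such
#' samples. With no covered samples the event is simply not considered.
#' (The OR branch makes the 10% branch non-binding whenever its ceiling is
#' >= 3; the rule is applied literally.)
#'
#' @param psi Numeric vector of inclusion values across samples.
#' @param covered Logical vector of sufficient-coverage flags.
#' @return Logical flag.
#' @export
event_considered <- function(psi, covered) {
  n_cov <- sum(covered)
  if (n_cov == 0) return(FALSE)
  k <- sum(covered & !is.na(psi) & psi >= 10 & psi <= 90)
  k >= consideration_threshold(n_cov) || k >= 3
}

# Per-event global consideration flags and per-sample "active" matrix
# (covered AND mid-range). A gene's considered event set in a sample is the
# set of globally considered events active in that sample.
splice_event_status <- function(st) {
  stopifnot(inherits(st, "splice_table"))
  inband <- st$covered & !is.na(st$psi) & st$psi >= 10 & st$psi <= 90
  n_cov <- rowSums(st$covered)
  k <- rowSums(inband)
  considered <- n_cov > 0 & (k >= ceiling(0.10 * n_cov) | k >= 3)
  list(considered = considered, active = inband & considered)
}

#' Considered event set of a gene in one sample
#'
#' @param st A [splice_table()].
#' @param gene Gene id.
#' @param sample Sample (merged stage) name.
#' @return data.frame of the gene's considered, active events in that sample
#'   (event_id, event_type).
#' @export
considered_events <- function(st, gene, sample) {
  status <- splice_event_status(st)
  idx <- which(st$events$gene_id == gene & status$active[, sample])
  st$events[idx, c("event_id", "event_type"), drop = FALSE]
}

#' Genes with alternative splicing in a sample
#'
#' AS genes carry considered events of at least 2 distinct types (of EEJ, IR,
#' ALTD, ALTA) in the given sample.
#'
#' @param st A [splice_table()].
#' @param sample Sample name.
#' @return Character vector of gene ids.
#' @export
as_genes <- function(st, sample) {
  status <- splice_event_status(st)
  act <- status$active[, sample]
  if (!any(act)) return(character())
  tt <- tapply(st$events$event_type[act], st$events$gene_id[act],
               function(x) length(unique(x)))
  names(tt)[tt >= 2]
}

classify_sets <- function(sx_ids, sx_types, sy_ids, sy_types) {
  ex <- length(sx_ids) > 0; ey <- length(sy_ids) > 0
  if (!ex && !ey) return(NA_integer_)
  if (ex && !ey) return(4L)
  if (!ex && ey) return(5L)
  if (setequal(sx_ids, sy_ids)) return(1L)
  if (!setequal(unique(sx_types), unique(sy_types))) return(3L)
  2L
}

#' Classify a gene's splicing transition between consecutive samples
#'
#' Five situations comparing the gene's considered event sets Sx, Sy in two
#' consecutive merged-stage samples:
#' 1. events kept still (Sx = Sy, non-empty);
#' 2. events changed but types kept still;
#' 3. event types changed (e.g. EEJ to IR);
#' 4. events in x, none in y (e.g. EEJ to NA);
#' 5. none in x, events in y (e.g. NA to EEJ).
#' Genes with no considered events in either sample are not emitted
#' (situation NA). Situations 2-5 mark the gene splicing-regulated.
#'
#' @param st A [splice_table()].
#' @param gene Gene id.
#' @param sample_x,sample_y Consecutive sample names (checked against
#'   `sample_order`).
#' @param sample_order Sample order; defaults to the table's column order.
#' @return One-row data.frame (gene_id, sample_x, sample_y, situation,
#'   is_splicing_regulated), or zero rows when both sets are empty.
#' @export
classify_transition <- function(st, gene, sample_x, sample_y,
                                sample_order = st$samples) {
  ix <- match(sample_x, sample_order); iy <- match(sample_y, sample_order)
  if (is.na(ix) || is.na(iy) || iy != ix + 1) {
    sd_stop("samples must be consecutive in the configured order",
            "spermdyn_validation_error")
  }
  status <- splice_event_status(st)
  gi <- st$events$gene_id == gene
  sx <- gi & status$active[, sample_x]
  sy <- gi & status$active[, sample_y]
  sit <- classify_sets(st$events$event_id[sx], st$events$event_type[sx],
                       st$events$event_id[sy], st$events$event_type[sy])
  out <- data.frame(gene_id = gene, sample_x = sample_x, sample_y = sample_y,
                    situation = sit,
                    is_splicing_regulated = sit %in% 2:5)
  out[!is.na(out$situation), , drop = FALSE]
}

#' All gene transitions between consecutive samples
#'
#' Runs the five-situation classifier for every gene over every consecutive
#' sample pair of the table.
#'
#' @param st A [splice_table()].
#' @param sample_order Sample order; defaults to the table's column order.
#' @return data.frame (gene_id, sample_x, sample_y, situation,
#'   is_splicing_regulated), genes with empty sets in both samples omitted.
#' @export
splicing_transitions <- function(st, sample_order = st$samples) {
  status <- splice_event_status(st)
  genes <- unique(st$events$gene_id)
  rows <- list()
  for (i in seq_len(length(sample_order) - 1)) {
    sx <- sample_order[i]; sy <- sample_order[i + 1]
    for (g in genes) {
      gi <- st$events$gene_id == g
      ax <- gi & status$active[, sx]
      ay <- gi & status$active[, sy]
      sit <- classify_sets(st$events$event_id[ax], st$events$event_type[ax],
                           st$events$event_id[ay], st$events$event_type[ay])
      if (!is.na(sit)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = g, sample_x = sx, sample_y = sy,
                     situation = sit, is_splicing_regulated = sit %in% 2:5)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), sample_x = character(),
                      sample_y = character(), situation = integer(),
                      is_splicing_regulated = logical()))
  }
  do.call(rbind, rows)
}

#' Event-level change tally between two consecutive samples
#'
#' For reporting, each event whose active status changes between sample x and
#' sample y is classified by its status in the latter sample: its type when
#' active in y, "NA" when it dropped out.
#'
#' @param st A [splice_table()].
#' @param sample_x,sample_y Consecutive sample names.
#' @return Named integer vector of changed-event counts per latter-stage
#'   status (EEJ, IR, ALTD, ALTA, NA).
#' @export
event_change_tally <- function(st, sample_x, sample_y) {
  status <- splice_event_status(st)
  ax <- status$active[, sample_x]; ay <- status$active[, sample_y]
  changed <- xor(ax, ay)
  lab <- ifelse(ay[changed], st$events$event_type[changed], "NA")
  tab <- table(factor(lab, levels = c("EEJ", "IR", "ALTD", "ALTA", "NA")))
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

#' Associate expression changes with splicing status
#'
#' For each up-regulated gene, reports its AS status (the sorted set of
#' considered event types, or "NA" when none) in the latter sample; for each
#' down-regulated gene, in the former sample.
#'
#' @param deg data.frame from [deg_test()] comparing the latter stage (group
#'   A) against the former stage (group B), so `call == "up"` means higher in
#'   the latter stage.
#' @param st A [splice_table()].
#' @param sample_x,sample_y The former and latter merged samples.
#' @return List with per-gene `status` data.frame (gene_id, direction,
#'   as_status) and per-direction `fractions` of each status.
#' @export
expression_splicing_association <- function(deg, st, sample_x, sample_y) {
  status <- splice_event_status(st)
  status_of <- function(g, sample) {
    act <- st$events$gene_id == g & status$active[, sample]
    if (!any(act)) "NA"
    else paste(sort(unique(st$events$event_type[act])), collapse = "+")
  }
  up <- deg$gene_id[deg$call == "up"]
  down <- deg$gene_id[deg$call == "down"]
  tabs <- data.frame(
    gene_id = c(up, down),
    direction = rep(c("up", "down"), c(length(up), length(down))),
    as_status = c(vapply(up, status_of, "", sample = sample_y),
                  vapply(down, status_of, "", sample = sample_x)),
    row.names = NULL)
  fractions <- lapply(split(tabs$as_status, tabs$direction),
                      function(x) prop.table(table(x)))
  list(status = tabs, fractions = fractions)
}
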