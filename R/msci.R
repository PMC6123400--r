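# Sex-chromosome gene classification: per-stage expressed calls and the
# MSCI / escape-MSCI / PMSC / RS-specific decision tree with TypeI/TypeII
# subtypes.

#' Per-gene, per-stage expression summary
#'
#' For every gene and stage: the mean TPM over the stage's cells and the
#' number of cells with TPM >= 1. This table feeds [expressed_at_stage()] and
#' the sex-linked classifier.
#'
#' @param expr TPM matrix (genes x cells, column names are cell ids).
#' @param stages Character vector of stage codes, one per matrix column (or
#'   named by cell id).
#' @param stage_levels Stage codes defining column order of the result;
#'   defaults to the full 20-stage order.
#' @return List of class `stage_expr` with matrices `mean_tpm` and `n_ge1`
#'   (genes x stages) and integer vector `n_cells` per stage.
#' @export
stage_expression_table <- function(expr, stages,
                                   stage_levels = stage_codes()) {
  if (!is.null(names(stages))) stages <- stages[colnames(expr)]
  if (length(stages) != ncol(expr)) {
    sd_stop("one stage label per cell required", "spermdyn_validation_error")
  }
  stage_index(stages) # validate codes
  levs <- intersect(stage_levels, unique(stages))
  mean_tpm <- matrix(NA_real_, nrow(expr), length(levs),
                     dimnames = list(rownames(expr), levs))
  n_ge1 <- mean_tpm
  n_cells <- integer(length(levs)); names(n_cells) <- levs
  for (s in levs) {
    cols <- which(stages == s)
    n_cells[s] <- length(cols)
    sub <- expr[, cols, drop = FALSE]
    mean_tpm[, s] <- rowMeans(sub)
    n_ge1[, s] <- rowSums(sub >= 1)
  }
  structure(list(mean_tpm = mean_tpm, n_ge1 = n_ge1, n_cells = n_cells),
            class = "stage_expr")
}

#' Is a gene expressed at a stage?
#'
#' Expressed iff the stage mean TPM is strictly > 1 AND TPM >= 1 in at least
#' 3 cells of that stage. Stages with fewer than 3 cells make the rule
#' undecidable and raise a staging error.
#'
#' @param tbl A [stage_expression_table()].
#' @param gene Gene id.
#' @param stage Stage code.
#' @return Logical flag.
#' @export
expressed_at_stage <- function(tbl, gene, stage) {
  em <- expressed_matrix(tbl)
  if (!gene %in% rownames(em) || !stage %in% colnames(em)) {
    sd_stop("unknown gene or stage not present in table",
            "spermdyn_validation_error")
  }
  em[gene, stage]
}

#' Expressed-at-stage logical matrix
#'
#' Applies the expressed rule (mean TPM > 1 and >= 3 cells with TPM >= 1) to
#' every gene and stage of a [stage_expression_table()].
#'
#' @param tbl A [stage_expression_table()].
#' @return Logical genes x stages matrix.
#' @export
expressed_matrix <- function(tbl) {
  stopifnot(inherits(tbl, "stage_expr"))
  small <- tbl$n_cells < 3
  if (any(small)) {
    sd_stop(paste("stage(s) with fewer than 3 cells:",
                  paste(names(tbl$n_cells)[small], collapse = ", ")),
            "spermdyn_staging_error")
  }
  tbl$mean_tpm > 1 & tbl$n_ge1 >= 3
}

#' Sex-linked protein-coding expression universe
#'
#' Protein-coding genes on chromosomes X and Y with TPM >= 1 in at least one
#' cell, plus the subset expressed (per the stage rule) at >= 1 stage.
#'
#' @param annotation Gene annotation data.frame.
#' @param expr TPM matrix over QC-passed cells.
#' @param stages Stage labels per cell (for the per-stage expressed subset).
#' @param biotype Biotype to analyse; the lncRNA analysis reuses the same
#'   rules with `biotype = "lncRNA"`.
#' @return List with `universe` (detected sex-linked gene ids),
#'   `stage_expressed` (subset expressed at >= 1 stage) and the expressed
#'   logical matrix `E` over the universe.
#' @export
sex_linked_universe <- function(annotation, expr, stages,
                                biotype = "protein_coding") {
  sex <- annotation$gene_id[annotation$chromosome %in% c("X", "Y") &
                            annotation$biotype == biotype]
  sex <- intersect(sex, rownames(expr))
  detected <- sex[rowSums(expr[sex, , drop = FALSE] >= 1) >= 1]
  tbl <- stage_expression_table(expr[detected, , drop = FALSE], stages)
  em <- expressed_matrix(tbl)
  # align to the full 20-stage order; absent stages are an error upstream of
  # classification, not here
  list(universe = detected,
       stage_expressed = detected[rowSums(em) >= 1],
       E = em)
}

#' Classify sex-linked genes into MSCI categories
#'
#' Decision tree over the expressed-at-stage profile E(s) of each gene (all
#' 20 stages required). Let PRE = stages before eP (A1..Z), PACH = eP/mP/lP,
#' POST = MII..RS8, PREMII = A1..MI. Then:
#'
#' 1. MSCI iff expressed at some PRE stage and not expressed at D. Subtype
#'    TYPE_I when silent across all of PACH, else TYPE_II. Within MSCI, the
#'    default (`pmsc_semantics = "silent_postmeiotic"`) labels genes silent
#'    across POST as MSCI_PMSC (still repressed by postmeiotic sex chromatin)
#'    and genes re-expressed at some POST stage as MSCI_ESCAPE_PMSC;
#'    `"expressed_postmeiotic"` flips the two names.
#' 2. ESCAPE_MSCI iff expressed at some PRE stage and expressed at D.
#' 3. RS_SPECIFIC iff silent at every stage before MII and expressed at some
#'    POST stage.
#' 4. Otherwise OTHER.
#'
#' @param E Logical genes x stages matrix with all 20 stage columns; every
#'   gene must be expressed at >= 1 stage.
#' @param pmsc_semantics Which naming convention to use for the MSCI
#'   subcategories (see above).
#' @return data.frame with gene_id, category, subtype (TYPE_I / TYPE_II for
#'   MSCI genes, NA otherwise).
#' @export
classify_msci <- function(E, pmsc_semantics = c("silent_postmeiotic",
                                                "expressed_postmeiotic")) {
  pmsc_semantics <- match.arg(pmsc_semantics)
  if (!all(stage_codes() %in% colnames(E))) {
    sd_stop("expressed matrix must cover all 20 stages",
            "spermdyn_staging_error")
  }
  E <- E[, stage_codes(), drop = FALSE]
  if (any(rowSums(E) == 0)) {
    sd_stop("genes expressed at no stage are outside the classified universe",
            "spermdyn_validation_error")
  }
  pre <- rowSums(E[, stages_before_ep(), drop = FALSE]) >= 1
  pach <- rowSums(E[, stages_pachytene(), drop = FALSE]) >= 1
  at_d <- E[, "D"]
  post <- rowSums(E[, stages_postmeiotic(), drop = FALSE]) >= 1
  premii <- rowSums(E[, stages_before_mii(), drop = FALSE]) >= 1

  category <- rep("OTHER", nrow(E))
  subtype <- rep(NA_character_, nrow(E))

  is_msci <- pre & !at_d
  if (pmsc_semantics == "silent_postmeiotic") {
    category[is_msci & !post] <- "MSCI_PMSC"
    category[is_msci & post] <- "MSCI_ESCAPE_PMSC"
  } else {
    category[is_msci & post] <- "MSCI_PMSC"
    category[is_msci & !post] <- "MSCI_ESCAPE_PMSC"
  }
  subtype[is_msci] <- ifelse(pach[is_msci], "TYPE_II", "TYPE_I")
  category[pre & at_d] <- "ESCAPE_MSCI"
  category[!premii & post & !(pre & at_d) & !is_msci] <- "RS_SPECIFIC"

  data.frame(gene_id = rownames(E), category = category, subtype = subtype,
             row.names = NULL)
}

#' Classify one gene from a stage expression table
#'
#' Convenience wrapper: builds the expressed profile and runs the decision
#' tree for a single gene.
#'
#' @param gene Gene id.
#' @param tbl A [stage_expression_table()] covering all 20 stages.
#' @param ... Passed to [classify_msci()].
#' @return One-row data.frame (gene_id, category, subtype).
#' @export
classify_sex_linked <- function(gene, tbl, ...) {
  em <- expressed_matrix(tbl)
  classify_msci(em[gene, , drop = FALSE], ...)
}

#' MSCI analysis for lncRNAs
#'
#' Identical rules to the protein-coding analysis, applied to the lncRNA
#' biotype on X and Y.
#'
#' @param annotation Gene annotation data.frame.
#' @param expr TPM matrix.
#' @param stages Stage labels per cell.
#' @param ... Passed to [classify_msci()].
#' @return data.frame of labels for expressed sex-linked lncRNAs.
#' @export
lncrna_msci_mode <- function(annotation, expr, stages, ...) {
  u <- sex_linked_universe(annotation, expr, stages, biotype = "lncRNA")
  classify_msci(u$E[u$stage_expressed, , drop = FALSE], ...)
}

#' Summarise MSCI classification
#'
#' Category counts and the percentage arithmetic of the study: MSCI vs escape
#' percentages over genes expressed before early pachynema (MSCI + escape
#' denominators), and TypeI/TypeII plus PMSC-silent/escape splits over MSCI
#' genes. All percentages are round-half-up to one decimal.
#'
#' @param labels data.frame from [classify_msci()].
#' @return List with `counts` (per category), `n_pre_ep` (MSCI + escape
#'   denominator), `percentages` and the subtype x category cross-tab.
#' @export
msci_summary <- function(labels) {
  cats <- c("MSCI_PMSC", "MSCI_ESCAPE_PMSC", "ESCAPE_MSCI", "RS_SPECIFIC",
            "OTHER")
  counts <- vapply(cats, function(k) sum(labels$category == k), integer(1))
  n_msci <- counts[["MSCI_PMSC"]] + counts[["MSCI_ESCAPE_PMSC"]]
  n_pre_ep <- n_msci + counts[["ESCAPE_MSCI"]]
  pct <- function(n, d) if (d > 0) percentage(n, d) else NA_real_
  n_t1 <- sum(labels$subtype == "TYPE_I", na.rm = TRUE)
  n_t2 <- sum(labels$subtype == "TYPE_II", na.rm = TRUE)
  list(counts = as.list(counts),
       n_msci = n_msci,
       n_pre_ep = n_pre_ep,
       percentages = list(
         msci = pct(n_msci, n_pre_ep),
         escape_msci = pct(counts[["ESCAPE_MSCI"]], n_pre_ep),
         type_i = pct(n_t1, n_msci),
         type_ii = pct(n_t2, n_msci),
         pmsc_silent = pct(counts[["MSCI_PMSC"]], n_msci),
         pmsc_escape = pct(counts[["MSCI_ESCAPE_PMSC"]], n_msci)),
       subtype_by_category = table(labels$subtype, labels$category,
                                   useNA = "no"))
}
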