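# Domain containers and file I/O: sparse UMI count matrices (Matrix Market),
# cell metadata / gene annotation / splice-event TSVs, and JSON reports.

#' Construct a UMI count matrix container
#'
#' Bundles a genes x cells matrix of non-negative integer UMI counts with its
#' axis labels and the index set of spike-in rows (identified by gene id
#' pattern, by default the standard "ERCC-" prefix).
#'
#' @param counts Matrix (base or `Matrix`) of non-negative integers,
#'   genes in rows, cells in columns.
#' @param genes Character vector of gene ids (rows).
#' @param cells Character vector of cell ids (columns).
#' @param spike_pattern Regular expression identifying spike-in gene ids.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `genes`, `cells` and `spike_rows` (integer indices).
#' @export
count_matrix <- function(counts, genes, cells, spike_pattern = "^ERCC-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    sd_stop(sprintf("matrix is %d x %d but %d gene ids and %d cell ids given",
                    nrow(counts), ncol(counts), length(genes), length(cells)),
            "spermdyn_format_error")
  }
  if (anyDuplicated(genes)) {
    sd_stop("duplicate gene ids", "spermdyn_validation_error")
  }
  if (anyDuplicated(cells)) {
    sd_stop("duplicate cell ids", "spermdyn_validation_error")
  }
  v <- counts@x
  if (length(v) && (min(v) < 0 || !is_wholenumber(v))) {
    sd_stop("counts must be non-negative integers", "spermdyn_validation_error")
  }
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts,
                 genes = as.character(genes),
                 cells = as.character(cells),
                 spike_rows = grep(spike_pattern, genes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d spike-in) x %d cells; %d nonzero\n",
              length(x$genes), length(x$spike_rows), length(x$cells),
              length(x$counts@x)))
  invisible(x)
}

#' Read a sparse UMI count matrix from Matrix Market files
#'
#' @param mtx_path Path to the Matrix Market file (1-based indices per the
#'   standard).
#' @param genes_path Path to a text file with one gene id per row (first
#'   column if tab-separated).
#' @param cells_path Path to a text file with one cell id per row.
#' @param spike_pattern Regular expression identifying spike-in gene ids.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path,
                              spike_pattern = "^ERCC-") {
  for (p in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(p)) sd_stop(paste("file not found:", p), "spermdyn_io_error")
  }
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) sd_stop(paste("invalid MTX:", conditionMessage(e)),
                                            "spermdyn_format_error"))
  genes <- read.delim(genes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.delim(cells_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  count_matrix(m, genes, cells, spike_pattern = spike_pattern)
}

#' Write a count matrix to Matrix Market files
#'
#' @param cm A [count_matrix()].
#' @param mtx_path,genes_path,cells_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(cm, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(cm, "count_matrix"))
  Matrix::writeMM(cm$counts, mtx_path)
  writeLines(cm$genes, genes_path)
  writeLines(cm$cells, cells_path)
  invisible(c(mtx_path, genes_path, cells_path))
}

validate_cell_meta <- function(df) {
  req <- c("cell_id", "stage", "mapping_rate")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    sd_stop(paste("cell metadata missing column(s):", paste(miss, collapse = ", ")),
            "spermdyn_schema_error")
  }
  if (anyDuplicated(df$cell_id)) {
    sd_stop("duplicate cell_id in cell metadata", "spermdyn_validation_error")
  }
  stage_index(df$stage) # errors on unknown codes
  if (anyNA(df$mapping_rate) || any(df$mapping_rate < 0 | df$mapping_rate > 1)) {
    sd_stop("mapping_rate must lie in [0, 1]", "spermdyn_validation_error")
  }
  if ("cluster" %in% names(df)) {
    bad <- !is.na(df$cluster) & !df$cluster %in% paste0("C", 1:7)
    if (any(bad)) sd_stop("cluster labels must be C1..C7", "spermdyn_validation_error")
  }
  df
}

#' Read cell metadata
#'
#' Expects a TSV with header and at least `cell_id`, `stage` (one of the 20
#' stage codes) and `mapping_rate` in \[0, 1\]; `cluster` (C1..C7) and `batch`
#' are optional. Unknown columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_cell_meta <- function(path) {
  validate_cell_meta(read.delim(path, stringsAsFactors = FALSE))
}

validate_gene_annotation <- function(df) {
  req <- c("gene_id", "chromosome", "biotype")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    sd_stop(paste("gene annotation missing column(s):", paste(miss, collapse = ", ")),
            "spermdyn_schema_error")
  }
  if (anyDuplicated(df$gene_id)) {
    sd_stop("duplicate gene_id in annotation", "spermdyn_validation_error")
  }
  ok_bt <- c("protein_coding", "lncRNA", "spike_in")
  if (!all(df$biotype %in% ok_bt)) {
    sd_stop(paste("biotype must be one of:", paste(ok_bt, collapse = ", ")),
            "spermdyn_validation_error")
  }
  if (!all((df$biotype == "spike_in") == (df$chromosome == "ERCC"))) {
    sd_stop("spike_in biotype must coincide with chromosome ERCC",
            "spermdyn_validation_error")
  }
  for (fl in c("is_tf", "is_splicing_regulator", "is_surface_marker")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE else df[[fl]] <- as.logical(df[[fl]])
  }
  df
}

#' Read gene annotation
#'
#' Expects a TSV with header and `gene_id`, `chromosome` (autosome name, "X",
#' "Y" or "ERCC") and `biotype` (protein_coding / lncRNA / spike_in); optional
#' logical flags `is_tf`, `is_splicing_regulator`, `is_surface_marker` default
#' to FALSE when absent.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_gene_annotation <- function(path) {
  validate_gene_annotation(read.delim(path, stringsAsFactors = FALSE))
}

#' Construct a splice-event inclusion table
#'
#' Per-event inclusion values (PSI/PSU/PIR, 0-100) and sufficient-coverage
#' flags across merged stage samples, in the style of an inclusion table from
#' junction-based splicing quantification.
#'
#' @param events data.frame with columns `gene_id`, `event_id`, `event_type`
#'   (EEJ, IR, ALTD or ALTA).
#' @param psi Numeric matrix, events x samples.
#' @param covered Logical matrix of the same shape; TRUE where read coverage is
#'   sufficient for the value to be interpreted.
#' @return An object of class `splice_table`.
#' @export
splice_table <- function(events, psi, covered) {
  req <- c("gene_id", "event_id", "event_type")
  if (!all(req %in% names(events))) {
    sd_stop("events needs gene_id, event_id, event_type", "spermdyn_schema_error")
  }
  ok_types <- c("EEJ", "IR", "ALTD", "ALTA")
  if (!all(events$event_type %in% ok_types)) {
    sd_stop(paste("event_type must be one of:", paste(ok_types, collapse = ", ")),
            "spermdyn_validation_error")
  }
  if (anyDuplicated(paste(events$gene_id, events$event_id))) {
    sd_stop("event_id must be unique within gene", "spermdyn_validation_error")
  }
  psi <- as.matrix(psi)
  covered <- as.matrix(covered)
  if (!identical(dim(psi), dim(covered)) || nrow(psi) != nrow(events)) {
    sd_stop("psi/covered dimensions must match events", "spermdyn_format_error")
  }
  v <- psi[covered]
  if (length(v) && any(!is.na(v) & (v < 0 | v > 100))) {
    sd_stop("inclusion values must lie in [0, 100] where coverage is sufficient",
            "spermdyn_validation_error")
  }
  rownames(psi) <- rownames(covered) <- paste(events$gene_id, events$event_id,
                                              sep = "|")
  structure(list(events = events, psi = psi, covered = covered,
                 samples = colnames(psi)),
            class = "splice_table")
}

#' @export
print.splice_table <- function(x, ...) {
  cat(sprintf("splice_table: %d events in %d genes x %d samples\n",
              nrow(x$events), length(unique(x$events$gene_id)),
              ncol(x$psi)))
  invisible(x)
}

#' Read a splice-event inclusion table from TSV
#'
#' Wide format: columns `gene_id`, `event_id`, `event_type`, then one
#' inclusion column per sample plus a matching `<sample>.Q` coverage column
#' with values "OK" (sufficient) or "LOW".
#'
#' @param path Path to the TSV file.
#' @return A [splice_table()].
#' @export
read_splice_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- c("gene_id", "event_id", "event_type")
  if (!all(key %in% names(df))) {
    sd_stop("splice table needs gene_id, event_id, event_type columns",
            "spermdyn_schema_error")
  }
  qcols <- grep("\\.Q$", names(df), value = TRUE)
  samples <- sub("\\.Q$", "", qcols)
  if (!length(samples) || !all(samples %in% names(df))) {
    sd_stop("each sample column needs a matching <sample>.Q coverage column",
            "spermdyn_schema_error")
  }
  psi <- as.matrix(df[samples])
  covered <- as.matrix(df[qcols]) == "OK"
  colnames(psi) <- colnames(covered) <- samples
  splice_table(df[key], psi, covered)
}

#' Write a splice-event inclusion table to TSV
#'
#' @param st A [splice_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_splice_table <- function(st, path) {
  stopifnot(inherits(st, "splice_table"))
  out <- st$events
  for (s in st$samples) {
    out[[s]] <- st$psi[, s]
    out[[paste0(s, ".Q")]] <- ifelse(st$covered[, s], "OK", "LOW")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structured analysis report as JSON
#'
#' Keys are written in the order given; scalars stay scalars and data.frames
#' become arrays of records, so the file is machine-readable and round-trips
#' through [read_report()].
#'
#' @param report A named list of scalars, vectors and data.frames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  ok <- tryCatch(suppressWarnings({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    sd_stop(paste("cannot write report:", conditionMessage(ok)),
            "spermdyn_io_error")
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The parsed list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
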