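#' Construct an expression dataset
#'
#' The core single-cell container: a cells-by-genes raw count matrix with
#' per-cell metadata (cluster, condition, donor, compartment) and an optional
#' log-normalized layer. Counts must be non-negative integers; gene symbols
#' and cell barcodes must be unique (use [load_counts()] for automatic symbol
#' deduplication when reading files).
#'
#' @param counts cells x genes numeric matrix of non-negative integer counts,
#'   with rownames = cell barcodes and colnames = gene symbols.
#' @param cell_meta optional data.frame keyed by `cell_id` (column or
#'   rownames) with any of the columns `cluster`, `condition`, `donor`,
#'   `compartment`. Missing columns are initialized as `NA`.
#' @param normalized optional numeric matrix, same shape and dimnames as
#'   `counts`.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `counts`, `cell_meta`, `normalized` (possibly `NULL`).
#' @export
expression_dataset <- function(counts, cell_meta = NULL, normalized = NULL) {
  counts <- as_count_matrix(counts)
  cell_ids <- rownames(counts)
  meta <- empty_cell_meta(cell_ids)
  ds <- structure(list(counts = counts, cell_meta = meta, normalized = NULL),
                  class = "ExpressionDataset")
  if (!is.null(cell_meta)) ds <- attach_metadata(ds, cell_meta, strict = FALSE)
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!identical(dim(normalized), dim(counts)))
      stopf("normalized layer shape %s does not match counts shape %s",
            paste(dim(normalized), collapse = "x"), paste(dim(counts), collapse = "x"))
    dimnames(normalized) <- dimnames(counts)
    ds$normalized <- normalized
  }
  ds
}

empty_cell_meta <- function(cell_ids) {
  data.frame(cluster = rep(NA_character_, length(cell_ids)),
             condition = NA_character_, donor = NA_character_,
             compartment = NA_character_,
             row.names = cell_ids, stringsAsFactors = FALSE)
}

as_count_matrix <- function(counts) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stopf("count matrix is empty (%d cells x %d genes)", nrow(counts), ncol(counts))
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stopf("duplicate cell barcodes in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicate gene symbols in counts")
  counts
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "" else " (normalized layer present)"))
  filled <- names(x$cell_meta)[colSums(!is.na(x$cell_meta)) > 0]
  if (length(filled)) cat("  cell_meta:", paste(filled, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

cell_ids <- function(ds) rownames(ds$counts)
gene_ids <- function(ds) colnames(ds$counts)

#' Load a count matrix from disk
#'
#' Reads either a 10x-style MatrixMarket directory (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, optionally gzipped) or a dense TSV with
#' genes as rows (first column = gene symbol) and cells as columns.
#' Duplicate gene symbols are deduplicated with `-1`, `-2`, ... suffixes so
#' downstream symbol lookups are unambiguous.
#'
#' @param path directory (for `mtx_dir`) or file (for `dense_tsv`).
#' @param format one of `"mtx_dir"`, `"dense_tsv"`.
#' @return an [expression_dataset()] with empty metadata columns.
#' @export
load_counts <- function(path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stopf("directory not found: %s", path)
    mtx <- find_sidecar(path, "matrix.mtx")
    feat <- find_sidecar(path, "features.tsv", alt = "genes.tsv")
    bc <- find_sidecar(path, "barcodes.tsv")
    m <- tryCatch(Matrix::readMM(mtx), error = function(e)
      stopf("malformed MatrixMarket file %s: %s", mtx, conditionMessage(e)))
    if (nrow(m) == 0L || ncol(m) == 0L) stopf("empty matrix file: %s", mtx)
    ftab <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
    btab <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(ftab) != nrow(m))
      stopf("features file has %d rows but matrix has %d genes", nrow(ftab), nrow(m))
    if (nrow(btab) != ncol(m))
      stopf("barcodes file has %d rows but matrix has %d cells", nrow(btab), ncol(m))
    symbols <- if (ncol(ftab) >= 2L) ftab[[2L]] else ftab[[1L]]
    counts <- t(as.matrix(m))
    rownames(counts) <- btab[[1L]]
    colnames(counts) <- dedup_symbols(as.character(symbols))
  } else {
    if (!file.exists(path)) stopf("file not found: %s", path)
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L) stopf("empty matrix file: %s", path)
    symbols <- dedup_symbols(as.character(tab[[1L]]))
    counts <- t(as.matrix(tab[, -1L, drop = FALSE]))
    colnames(counts) <- symbols
  }
  if (anyNA(counts) || any(counts != floor(counts)) || any(counts < 0))
    stopf("non-integer or negative entries in count matrix at %s", path)
  expression_dataset(counts)
}

find_sidecar <- function(dir, name, alt = NULL) {
  for (cand in c(name, paste0(name, ".gz"),
                 if (!is.null(alt)) c(alt, paste0(alt, ".gz")))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  stopf("required file '%s' not found in %s", name, dir)
}

#' Attach per-cell metadata to a dataset
#'
#' @param ds an [expression_dataset()].
#' @param meta data.frame with a `cell_id` column (or cell ids as rownames)
#'   and metadata columns to merge. Barcode matching is exact string match
#'   (no `-1` suffix stripping).
#' @param strict if `TRUE`, every cell of `ds` must appear in `meta`;
#'   otherwise absent cells keep `NA` markers. Extra rows in `meta` are
#'   ignored with a warning.
#' @return the dataset with merged `cell_meta`.
#' @export
attach_metadata <- function(ds, meta, strict = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if ("cell_id" %in% names(meta)) {
    ids <- as.character(meta$cell_id)
    meta <- meta[, setdiff(names(meta), "cell_id"), drop = FALSE]
  } else {
    ids <- rownames(meta)
  }
  if (is.null(ids)) stopf("metadata must carry cell ids (column 'cell_id' or rownames)")
  if (anyDuplicated(ids))
    stopf("duplicate cell_id in metadata: %s",
          paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  ds_ids <- cell_ids(ds)
  missing <- setdiff(ds_ids, ids)
  if (strict && length(missing))
    stopf("metadata missing %d cell(s): %s", length(missing),
          paste(utils::head(missing, 5L), collapse = ", "))
  extra <- setdiff(ids, ds_ids)
  if (length(extra))
    warnf("%d metadata row(s) for unknown barcodes ignored: %s", length(extra),
          paste(utils::head(extra, 5L), collapse = ", "))
  keep <- ids %in% ds_ids
  meta <- meta[keep, , drop = FALSE]
  ids <- ids[keep]
  for (col in names(meta)) {
    v <- ds$cell_meta[[col]]
    if (is.null(v)) v <- rep(NA, length(ds_ids))
    v[match(ids, ds_ids)] <- meta[[col]]
    ds$cell_meta[[col]] <- v
  }
  ds
}

#' Write a dataset as a 10x-style MTX directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `cell_meta.tsv`
#' under `dir`; [load_counts()] + [attach_metadata()] on the output
#' reproduce the dataset exactly.
#'
#' @param ds an [expression_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = gene_ids(ds), symbol = gene_ids(ds)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(ds), file.path(dir, "barcodes.tsv"))
  meta <- cbind(cell_id = cell_ids(ds), ds$cell_meta)
  utils::write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a bulk expression table (genes x samples TSV)
#'
#' First column = gene symbol, remaining columns = samples; values are
#' TPM-like non-negative expression. Duplicate gene symbols are deduplicated
#' as in [load_counts()].
#'
#' @param path TSV file.
#' @return numeric matrix genes x samples.
#' @export
load_bulk <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stopf("empty bulk table: %s", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- dedup_symbols(as.character(tab[[1L]]))
  if (anyDuplicated(colnames(m))) stopf("duplicate sample ids in bulk table")
  if (anyNA(m) || any(m < 0)) stopf("bulk expression must be non-negative")
  m
}
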