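#' Cells-by-genes expression container
#'
#' Lightweight S3 container for a single-cell expression matrix together with
#' its per-cell annotations. Rows are cells, columns are genes. Two layers are
#' carried: raw `counts` (sparse, nonnegative integers) and, once
#' [log_normalize()] has been applied, `logcounts` (log-normalized values).
#'
#' @param counts sparse or dense numeric matrix, cells in rows, genes in
#'   columns; dimnames give cell barcodes and gene identifiers.
#' @param cells data.frame with one row per cell; must contain columns
#'   `barcode`, `detailed_type`, `abstract_type` and `donor`.
#' @param logcounts optional matrix of log-normalized values with the same
#'   shape as `counts`.
#'
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cells, logcounts = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  required <- c("barcode", "detailed_type", "abstract_type", "donor")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols))
    stop("cell annotations lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cells) != nrow(counts))
    stop("annotation rows (", nrow(cells), ") do not match cells (",
         nrow(counts), ")", call. = FALSE)
  if (any(counts@x < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- cells$barcode
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%06d", seq_len(ncol(counts)))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  out <- structure(list(counts = counts, cells = cells, logcounts = NULL),
                   class = "cell_matrix")
  if (!is.null(logcounts)) {
    logcounts <- methods::as(methods::as(logcounts, "CsparseMatrix"), "generalMatrix")
    stopifnot(all(dim(logcounts) == dim(counts)))
    dimnames(logcounts) <- dimnames(counts)
    out$logcounts <- logcounts
  }
  out
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @export
dimnames.cell_matrix <- function(x) dimnames(x$counts)

#' Number of cells / genes
#' @param x a `cell_matrix`
#' @return integer count.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Gene identifiers of a cell matrix
#' @param x a `cell_matrix`
#' @return character vector of gene IDs in matrix column order.
#' @export
gene_ids <- function(x) colnames(x$counts)

# Active expression layer: logcounts when present, else raw counts.
expr_layer <- function(x, layer = c("auto", "counts", "logcounts")) {
  layer <- match.arg(layer)
  if (layer == "counts") return(x$counts)
  if (layer == "logcounts" || (layer == "auto" && !is.null(x$logcounts))) {
    if (is.null(x$logcounts))
      stop("matrix has no log-normalized layer; run log_normalize() first",
           call. = FALSE)
    return(x$logcounts)
  }
  x$counts
}

# Subset cells (i) and/or genes (j), keeping layers and annotations aligned.
subset_cells <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$counts))
  if (is.null(j)) j <- seq_len(ncol(x$counts))
  cell_matrix(x$counts[i, j, drop = FALSE], x$cells[i, , drop = FALSE],
              logcounts = if (!is.null(x$logcounts)) x$logcounts[i, j, drop = FALSE])
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  zero_frac <- 1 - length(x$counts@x[x$counts@x != 0]) / prod(dim(x$counts))
  cat(sprintf("  sparsity: %.1f%% zeros | layers: counts%s\n", 100 * zero_frac,
              if (!is.null(x$logcounts)) ", logcounts" else ""))
  tab <- sort(table(x$cells$abstract_type), decreasing = TRUE)
  cat("  abstract types:",
      paste(sprintf("%s (%.1f%%)", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  cat("  donors:", length(unique(x$cells$donor)), "\n")
  invisible(x)
}

#' Write a cell matrix to a directory of exchange files
#'
#' Writes `matrix.mtx` (MatrixMarket, genes stored column-wise as written),
#' `barcodes.tsv`, `features.tsv` and `annotations.tsv`
#' (barcode, detailed_type, abstract_type, donor).
#'
#' @param x a `cell_matrix`
#' @param dir output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  utils::write.table(x$cells, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell matrix from a directory of exchange files
#'
#' Inverse of [write_cell_matrix()]; the roundtrip is lossless for the counts
#' layer and annotations.
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` and `annotations.tsv`.
#' @return a `cell_matrix`.
#' @export
read_cell_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                            "annotations.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  if (length(barcodes) != nrow(m))
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix.mtx has ",
         nrow(m), " rows", call. = FALSE)
  if (length(features) != ncol(m))
    stop("features.tsv has ", length(features), " entries but matrix.mtx has ",
         ncol(m), " columns", call. = FALSE)
  ann <- utils::read.table(paths[4], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(ann) != nrow(m) || !all(ann$barcode == barcodes))
    stop("annotations.tsv does not align with barcodes.tsv", call. = FALSE)
  incomplete <- vapply(ann, function(col) any(is.na(col) | col == ""), logical(1))
  if (any(incomplete)) {
    bad <- ann$barcode[rowSums(is.na(ann) | ann == "") > 0]
    stop("empty annotation values for barcodes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dimnames(m) <- list(barcodes, features)
  cell_matrix(m, ann)
}
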