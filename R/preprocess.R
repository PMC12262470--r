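#' Quality-control thresholds
#'
#' Standard droplet scRNA-seq cell/gene filters: minimum UMI per cell (500),
#' minimum detected genes per cell (250), minimum log10(genes)/log10(UMI)
#' complexity ratio (0.85, strict inequality), and minimum cells per gene
#' (10). `scale_factor` and `n_hvg` parameterize the downstream
#' normalization and highly-variable-gene steps.
#'
#' @param min_umi,min_genes_per_cell inclusive per-cell minimums.
#' @param min_log10_genes_per_umi strict lower bound on
#'   `log10(detected genes) / log10(UMI)`.
#' @param min_cells_per_gene inclusive minimum number of (surviving) cells a
#'   gene must be detected in.
#' @param scale_factor per-cell library scale used by [log_normalize()].
#' @param n_hvg number of highly variable genes selected by
#'   [select_hvg_vst()].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 500, min_genes_per_cell = 250,
                          min_log10_genes_per_umi = 0.85,
                          min_cells_per_gene = 10, scale_factor = 1e4,
                          n_hvg = 2000) {
  vals <- c(min_umi, min_genes_per_cell, min_log10_genes_per_umi,
            min_cells_per_gene, scale_factor, n_hvg)
  if (any(vals < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  structure(list(min_umi = min_umi, min_genes_per_cell = min_genes_per_cell,
                 min_log10_genes_per_umi = min_log10_genes_per_umi,
                 min_cells_per_gene = min_cells_per_gene,
                 scale_factor = scale_factor, n_hvg = n_hvg),
            class = "qc_thresholds")
}

#' Filter cells and genes by quality-control criteria
#'
#' Cells are kept when UMI >= `min_umi`, detected genes >=
#' `min_genes_per_cell`, and `log10(genes)/log10(UMI) >
#' min_log10_genes_per_umi`; genes are then kept when detected in at least
#' `min_cells_per_gene` of the surviving cells. Cell and gene order is
#' preserved. The removal counts per step are attached as attribute
#' `qc_report` (a data.frame with columns step, cells_before, cells_after,
#' genes_before, genes_after).
#'
#' @param x a [cell_matrix()] of raw counts.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `cell_matrix`.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  counts <- x$counts
  umi <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  ratio <- ifelse(umi > 1, log10(pmax(ngene, 1)) / log10(umi), 0)
  keep_cells <- umi >= thresholds$min_umi &
    ngene >= thresholds$min_genes_per_cell &
    ratio > thresholds$min_log10_genes_per_umi
  if (!any(keep_cells)) stop("all cells removed", call. = FALSE)
  n_cells0 <- nrow(counts); n_genes0 <- ncol(counts)
  sub <- counts[keep_cells, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(sub > 0)
  keep_genes <- cells_per_gene >= thresholds$min_cells_per_gene
  if (!any(keep_genes)) stop("all genes removed", call. = FALSE)
  out <- subset_cells(x, which(keep_cells), which(keep_genes))
  attr(out, "qc_report") <- data.frame(
    step = c("cell_filter", "gene_filter"),
    cells_before = c(n_cells0, sum(keep_cells)),
    cells_after = c(sum(keep_cells), sum(keep_cells)),
    genes_before = c(n_genes0, n_genes0),
    genes_after = c(n_genes0, sum(keep_genes)))
  out
}

#' Log-normalize counts
#'
#' Each entry becomes `ln(1 + count / cell_total * scale_factor)`; zeros map
#' to zero and the transform is strictly monotone within a cell, invariant
#' to uniform scaling of a cell's counts.
#'
#' @param x a [cell_matrix()] with nonnegative counts and no all-zero cells.
#' @param scale_factor per-cell library size target (default 10,000).
#' @return `x` with a `logcounts` layer added.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) stop("cell with zero total count", call. = FALSE)
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% x$counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  norm <- methods::as(norm, "generalMatrix")
  dimnames(norm) <- dimnames(x$counts)
  x$logcounts <- norm
  x
}

#' Select highly variable genes by variance-stabilizing transformation
#'
#' Ranks genes by standardized variance: a loess curve (span 0.3) of
#' log10(variance) on log10(mean) over genes with positive variance predicts
#' each gene's expected standard deviation; counts are standardized by
#' observed mean and expected sd, clipped at `sqrt(n_cells)`, and the
#' variance of the clipped values ranks the genes.
#'
#' @param x a [cell_matrix()]; raw counts are used.
#' @param n_hvg number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of `n_hvg` gene IDs, most variable first.
#' @export
select_hvg_vst <- function(x, n_hvg = 2000, loess_span = 0.3) {
  stopifnot(inherits(x, "cell_matrix"))
  counts <- x$counts
  n <- nrow(counts)
  if (n_hvg > ncol(counts)) stop("n_hvg exceeds number of genes", call. = FALSE)
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  std_var <- numeric(ncol(counts))
  pos <- v > 0 & mu > 0
  if (sum(pos) > 2) {
    fit <- stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = loess_span,
                        degree = 2)
    exp_sd <- sqrt(10^stats::predict(fit))
    clip <- sqrt(n)
    idx <- which(pos)
    for (k in seq_along(idx)) {
      g <- idx[k]
      xs <- counts[, g]
      z <- (as.numeric(xs) - mu[g]) / exp_sd[k]
      z <- pmin(pmax(z, -clip), clip)
      std_var[g] <- sum((z - mean(z))^2) / (n - 1)
    }
  }
  ord <- order(std_var, decreasing = TRUE)
  colnames(counts)[ord[seq_len(n_hvg)]]
}

#' Per-gene z-scoring of the log-normalized layer
#'
#' Optional scaling step for consumers that want unit-variance features;
#' drug scoring uses the log-normalized layer directly.
#'
#' @param x a [cell_matrix()] with a `logcounts` layer.
#' @param genes optional subset of gene IDs to scale (default all).
#' @return dense matrix of z-scored values (cells x genes).
#' @export
scale_genes <- function(x, genes = NULL) {
  m <- as.matrix(expr_layer(x, "logcounts"))
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  scale(m)
}
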