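#' Build a drug-by-gene binary target matrix
#'
#' Entry (d, g) is 1 iff gene g is a target of drug d and is measured in the
#' gene universe. Drugs whose targets are all absent from the universe are
#' excluded with a warning (they cannot be scored).
#'
#' @param db a `drug_target_db` (see [simulate_drug_db()] /
#'   [read_drug_db()]).
#' @param gene_universe ordered character vector of measured gene IDs.
#' @return sparse binary matrix, drugs in rows (drug IDs as rownames), genes
#'   in columns in `gene_universe` order; attribute `excluded` lists dropped
#'   drug IDs and attribute `nephrotoxic` carries the retained drugs' flags.
#' @export
build_target_matrix <- function(db, gene_universe) {
  stopifnot(inherits(db, "drug_target_db"))
  if (!length(gene_universe)) stop("empty gene universe", call. = FALSE)
  if (!nrow(db)) stop("empty drug database", call. = FALSE)
  ii <- rep(seq_len(nrow(db)), lengths(db$target_genes))
  jj <- match(unlist(db$target_genes), gene_universe)
  keep <- !is.na(jj)
  tm <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                             dims = c(nrow(db), length(gene_universe)),
                             dimnames = list(db$drug_id, gene_universe))
  tm@x[] <- 1  # duplicate target entries collapse to 1
  measured <- Matrix::rowSums(tm) > 0
  if (any(!measured)) {
    warning(sum(!measured), " drug(s) with no measured targets excluded: ",
            paste(utils::head(db$drug_id[!measured], 5), collapse = ", "),
            call. = FALSE)
  }
  out <- tm[measured, , drop = FALSE]
  attr(out, "excluded") <- db$drug_id[!measured]
  attr(out, "nephrotoxic") <- stats::setNames(db$nephrotoxic[measured],
                                              db$drug_id[measured])
  out
}

#' Score drugs onto cells from target-gene expression
#'
#' The composite drug score of a cell for a drug is the arithmetic mean of
#' the cell's (log-normalized) expression over the drug's measured target
#' genes; it is independent of all non-target genes and monotone in each
#' target's expression.
#'
#' @param x a [cell_matrix()] with a log-normalized layer.
#' @param targets drug-by-gene matrix from [build_target_matrix()], aligned
#'   to `x`'s gene universe.
#' @return object of class `drug_score_matrix`: list with `raw` (cells x
#'   drugs dense matrix), `logged` (NULL until [log_transform_scores()]),
#'   `cells` (annotation data.frame) and `nephrotoxic` (named flags).
#' @export
score_cells <- function(x, targets) {
  stopifnot(inherits(x, "cell_matrix"))
  m <- expr_layer(x, "logcounts")
  if (ncol(m) != ncol(targets) || !identical(colnames(m), colnames(targets)))
    stop("gene universes of matrix and target matrix are misaligned",
         call. = FALSE)
  k <- Matrix::rowSums(targets)
  raw <- as.matrix(m %*% Matrix::t(targets)) /
    matrix(k, nrow = nrow(m), ncol = nrow(targets), byrow = TRUE)
  dimnames(raw) <- list(rownames(m), rownames(targets))
  structure(list(raw = raw, logged = NULL, cells = x$cells,
                 nephrotoxic = attr(targets, "nephrotoxic"),
                 log_epsilon = NULL),
            class = "drug_score_matrix")
}

#' Log-transform drug scores
#'
#' Adds a logged layer `ln(raw + epsilon)`; the pseudocount keeps zero
#' scores finite. Natural log fixes the downstream fold-change convention
#' `FC = exp(logFC)`.
#'
#' @param scores a `drug_score_matrix`.
#' @param epsilon pseudocount added before the log (default 1e-9, recorded
#'   in the object).
#' @return the `drug_score_matrix` with `logged` filled in.
#' @export
log_transform_scores <- function(scores, epsilon = 1e-9) {
  stopifnot(inherits(scores, "drug_score_matrix"))
  if (any(scores$raw < 0))
    stop("negative raw drug score: upstream contract violated", call. = FALSE)
  scores$logged <- log(scores$raw + epsilon)
  scores$log_epsilon <- epsilon
  scores
}

#' @export
print.drug_score_matrix <- function(x, ...) {
  cat("drug_score_matrix:", nrow(x$raw), "cells x", ncol(x$raw), "drugs",
      if (!is.null(x$logged)) "(raw + logged layers)" else "(raw layer)", "\n")
  if (!is.null(x$nephrotoxic))
    cat("  nephrotoxic drugs:", sum(x$nephrotoxic), "/", length(x$nephrotoxic), "\n")
  invisible(x)
}

#' Aggregate drug scores to cell-type level
#'
#' For each (drug, cell type) pair, the mean of the logged drug scores over
#' the cells of that type — the representative per-type drug score used by
#' the signature tests and the classifier features.
#'
#' @param scores a `drug_score_matrix` with a logged layer.
#' @param level `"abstract4"` or `"detailed32"`.
#' @return data.frame of class `cell_type_score_table` with columns
#'   `drug_id`, `cell_type`, `level`, `mean_score`, `nephrotoxic`.
#' @export
aggregate_by_cell_type <- function(scores, level = c("detailed32", "abstract4")) {
  level <- match.arg(level)
  stopifnot(inherits(scores, "drug_score_matrix"))
  if (is.null(scores$logged))
    stop("scores must be log-transformed first (log_transform_scores)",
         call. = FALSE)
  col <- if (level == "abstract4") "abstract_type" else "detailed_type"
  if (is.null(scores$cells[[col]]))
    stop("cell annotations lack ", col, call. = FALSE)
  types <- factor(scores$cells[[col]])
  sums <- rowsum(scores$logged, types)          # type x drug
  means <- sums / as.vector(table(types))
  out <- data.frame(
    drug_id = rep(colnames(means), each = nrow(means)),
    cell_type = rep(rownames(means), times = ncol(means)),
    level = level,
    mean_score = as.vector(means),
    stringsAsFactors = FALSE)
  out$nephrotoxic <- unname(scores$nephrotoxic[out$drug_id])
  class(out) <- c("cell_type_score_table", "data.frame")
  out
}
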