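#' Stratified subsampling preserving cell-type prevalence
#'
#' Draws `round(fraction * n_type)` cells per detailed cell type, without
#' replacement, so the subsample reproduces the original cell-type
#' composition. Donor labels are carried through. Types whose allocation
#' rounds to zero are dropped with a warning.
#'
#' @param x a [cell_matrix()].
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return a `cell_matrix` subsample.
#' @export
subsample_preserving_prevalence <- function(x, fraction = 0.10, seed = 1L) {
  stopifnot(inherits(x, "cell_matrix"))
  assert_fraction(fraction, "fraction", allow_zero = FALSE)
  types <- x$cells$detailed_type
  idx <- with_seed(seed, {
    picked <- lapply(split(seq_along(types), types), function(i) {
      k <- round(fraction * length(i))
      if (k == 0L) return(integer(0))
      sample(i, k)
    })
    dropped <- names(picked)[!lengths(picked)]
    if (length(dropped))
      warning("cell types dropped by subsampling: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    sort(unlist(picked, use.names = FALSE))
  })
  subset_cells(x, idx)
}

#' Apply a multiplicative drug effect to responding cells of one type
#'
#' Selects `floor(response_rate * n_type)` cells (at least one when the rate
#' is positive and the type nonempty) of the given cell type uniformly at
#' random and multiplies their whole expression vector by `(1 +
#' effect_size)`. All other cells are untouched; the input is not mutated.
#' The effect acts on the log-normalized layer when present, otherwise on
#' counts (configurable via `layer`).
#'
#' @param x a [cell_matrix()].
#' @param cell_type name of the affected type; matched against the detailed
#'   annotation first, then the abstract one.
#' @param effect_size nonnegative multiplier increment `e` (responding
#'   expression becomes `baseline * (1 + e)`).
#' @param response_rate fraction of the type's cells that respond.
#' @param seed integer seed selecting the responding cells.
#' @param layer `"auto"` (logcounts when available), `"counts"` or
#'   `"logcounts"`.
#' @param genes optional character vector restricting the effect to a gene
#'   subset; default all genes of a responding cell.
#' @return a modified `cell_matrix`; attribute `responding` holds the row
#'   indices of responding cells.
#' @export
apply_drug_effect <- function(x, cell_type, effect_size, response_rate,
                              seed = 1L, layer = "auto", genes = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  if (effect_size < 0) stop("effect_size must be nonnegative", call. = FALSE)
  assert_fraction(response_rate, "response_rate", allow_zero = FALSE)
  in_type <- which(x$cells$detailed_type == cell_type)
  if (!length(in_type)) in_type <- which(x$cells$abstract_type == cell_type)
  if (!length(in_type)) stop("unknown cell type: ", cell_type, call. = FALSE)
  n_resp <- max(1L, floor(response_rate * length(in_type)))
  responding <- with_seed(seed, sample(in_type, n_resp))
  m <- expr_layer(x, layer)
  scale_vec <- rep(1, nrow(m))
  scale_vec[responding] <- 1 + effect_size
  if (is.null(genes)) {
    mod <- Matrix::Diagonal(x = scale_vec) %*% m
  } else {
    j <- match(genes, colnames(m))
    if (anyNA(j)) stop("unknown genes in effect subset", call. = FALSE)
    mod <- m
    mod[responding, j] <- mod[responding, j, drop = FALSE] * (1 + effect_size)
  }
  mod <- methods::as(methods::as(mod, "CsparseMatrix"), "generalMatrix")
  dimnames(mod) <- dimnames(m)
  out <- x
  if (!is.null(x$logcounts) && layer != "counts") out$logcounts <- mod
  else out$counts <- mod
  attr(out, "responding") <- responding
  out
}

#' Pseudo-bulk a cell matrix
#'
#' Averages expression per gene over cells, masking cell-type identity:
#' with `group_by = "donor"` one profile per donor (the replicate structure
#' for pseudo-bulk t-tests), with `group_by = "none"` a single global
#' profile.
#'
#' @param x a [cell_matrix()].
#' @param group_by `"donor"` or `"none"`.
#' @param layer expression layer to average (see [apply_drug_effect()]).
#' @return matrix with genes in rows and one column per profile.
#' @export
pseudo_bulk <- function(x, group_by = c("donor", "none"), layer = "auto") {
  group_by <- match.arg(group_by)
  stopifnot(inherits(x, "cell_matrix"))
  m <- expr_layer(x, layer)
  if (group_by == "none") {
    out <- matrix(Matrix::colMeans(m), ncol = 1,
                  dimnames = list(colnames(m), "bulk"))
    return(out)
  }
  donors <- factor(x$cells$donor)
  ind <- Matrix::sparseMatrix(i = seq_along(donors),
                              j = as.integer(donors),
                              x = 1, dims = c(length(donors), nlevels(donors)))
  prof <- Matrix::crossprod(m, ind)                       # genes x donors
  prof <- sweep(as.matrix(prof), 2, as.numeric(table(donors)), `/`)
  dimnames(prof) <- list(colnames(m), levels(donors))
  prof
}

#' Simulation grid for the statistical power analysis
#'
#' @param effect_sizes nonnegative multiplier increments; default 13 values
#'   log-spaced from 0.001 to 10.
#' @param response_rates fractions of a type's cells that respond; defaults
#'   0.3, 0.8 (the assumed standard response rate) and 0.95.
#' @param subsample_fraction prevalence-preserving subsample fraction.
#' @param significance_threshold per-gene p-value cutoff (default 2.5e-6,
#'   a Bonferroni-style 0.05 / 20,000).
#' @param abstraction_level `"abstract4"` or `"detailed32"` — which
#'   annotation the affected types are taken from.
#' @param n_replicate_runs number of independent simulation repeats averaged
#'   into each power estimate.
#' @param seed integer master seed.
#' @return list of class `simulation_grid`.
#' @export
simulation_grid <- function(effect_sizes = 10^seq(-3, 1, length.out = 13),
                            response_rates = c(0.3, 0.8, 0.95),
                            subsample_fraction = 0.10,
                            significance_threshold = 2.5e-6,
                            abstraction_level = c("abstract4", "detailed32"),
                            n_replicate_runs = 10L, seed = 1L) {
  abstraction_level <- match.arg(abstraction_level)
  if (any(effect_sizes < 0)) stop("effect sizes must be >= 0", call. = FALSE)
  assert_fraction(response_rates, "response_rates", allow_zero = FALSE)
  assert_fraction(significance_threshold, "significance_threshold",
                  allow_zero = FALSE, allow_one = FALSE)
  structure(list(effect_sizes = effect_sizes,
                 response_rates = response_rates,
                 subsample_fraction = subsample_fraction,
                 significance_threshold = significance_threshold,
                 abstraction_level = abstraction_level,
                 n_replicate_runs = assert_count(n_replicate_runs,
                                                 "n_replicate_runs"),
                 seed = as.integer(seed)),
            class = "simulation_grid")
}

#' Run the drug-effect power simulation over a grid
#'
#' For every (effect size, response rate, affected cell type) combination
#' and each replicate run: draw a fresh prevalence-preserving subsample of
#' the baseline, apply the multiplicative drug effect to responding cells of
#' the affected type, and test every gene between the treated and untreated
#' versions with a Welch t-test. Power is the fraction of all genes with p
#' below `significance_threshold`, averaged over runs.
#'
#' In `pseudo_bulk` mode the test compares donor-level pseudo-bulk profiles
#' of the treated vs untreated subsample (donors are the replicates) with
#' cell-type annotations masked, as in bulk RNA-seq. In `cell_level` mode
#' the annotations remain available — the defining advantage of single-cell
#' data — so treated cells are compared against untreated cells within the
#' affected cell type. Genes with no variance information (e.g. all-zero in
#' the subsample) never count as significant, which is what caps pseudo-bulk
#' power below 1 at the fraction of genes expressed above the noise floor.
#'
#' @param baseline a [cell_matrix()]; must carry donor labels for
#'   `pseudo_bulk` mode. If no `logcounts` layer is present the matrix is
#'   log-normalized first.
#' @param grid a [simulation_grid()].
#' @param mode `"pseudo_bulk"` or `"cell_level"`.
#' @param cell_types affected cell types; default all types at the grid's
#'   abstraction level.
#' @return data.frame of class `power_grid` with columns effect_size,
#'   response_rate, cell_type, mode, n_significant (mean over runs), n_genes,
#'   power, n_runs; sorted by cell_type, response_rate, effect_size.
#' @export
run_power_grid <- function(baseline, grid = simulation_grid(),
                           mode = c("pseudo_bulk", "cell_level"),
                           cell_types = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "cell_matrix"), inherits(grid, "simulation_grid"))
  if (is.null(baseline$logcounts)) baseline <- log_normalize(baseline)
  type_col <- if (grid$abstraction_level == "abstract4") "abstract_type"
              else "detailed_type"
  if (is.null(cell_types)) cell_types <- sort(unique(baseline$cells[[type_col]]))
  n_genes_total <- n_genes(baseline)

  combos <- expand.grid(effect_size = grid$effect_sizes,
                        response_rate = grid$response_rates,
                        cell_type = cell_types,
                        stringsAsFactors = FALSE)
  power_acc <- matrix(0, nrow = nrow(combos), ncol = grid$n_replicate_runs)
  for (r in seq_len(grid$n_replicate_runs)) {
    sub <- subsample_preserving_prevalence(
      baseline, grid$subsample_fraction,
      seed = derive_seed(grid$seed, "subsample", r))
    untreated <- if (mode == "pseudo_bulk") pseudo_bulk(sub, "donor")
                 else t(as.matrix(expr_layer(sub)))
    for (i in seq_len(nrow(combos))) {
      ct <- combos$cell_type[i]
      in_type <- if (type_col == "abstract_type")
        which(sub$cells$abstract_type == ct)
      else which(sub$cells$detailed_type == ct)
      if (length(in_type) < (if (mode == "cell_level") 2L else 1L)) {
        power_acc[i, r] <- NA; next
      }
      treated_mat <- apply_drug_effect(
        sub, ct, combos$effect_size[i], combos$response_rate[i],
        seed = derive_seed(grid$seed, paste0("effect", i), r))
      if (mode == "pseudo_bulk") {
        treated <- pseudo_bulk(treated_mat, "donor")
        res <- row_welch(treated, untreated)
      } else {
        treated <- t(as.matrix(expr_layer(treated_mat)))[, in_type,
                                                         drop = FALSE]
        res <- row_welch(treated, untreated[, in_type, drop = FALSE])
      }
      sig <- sum(res$p < grid$significance_threshold, na.rm = TRUE)
      power_acc[i, r] <- sig / n_genes_total
    }
  }
  out <- combos
  out$mode <- mode
  out$n_significant <- rowMeans(power_acc, na.rm = TRUE) * n_genes_total
  out$n_genes <- n_genes_total
  out$power <- rowMeans(power_acc, na.rm = TRUE)
  out$n_runs <- rowSums(!is.na(power_acc))
  out <- out[order(out$cell_type, out$response_rate, out$effect_size), ]
  rownames(out) <- NULL
  class(out) <- c("power_grid", "data.frame")
  out
}

#' @export
print.power_grid <- function(x, ...) {
  cat("power_grid:", nrow(x), "grid points |", x$mode[1], "mode |",
      x$n_genes[1], "genes\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Plot power curves
#'
#' Power against effect size (log x-axis), one panel-free base-graphics plot
#' with a line per (cell type, response rate).
#'
#' @param x a `power_grid`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.power_grid <- function(x, ...) {
  key <- interaction(x$cell_type, x$response_rate, drop = TRUE)
  effs <- sort(unique(x$effect_size))
  m <- sapply(split(x, key), function(d) d$power[order(d$effect_size)])
  graphics::matplot(effs, m, type = "b", log = "x", pch = 16,
                    xlab = "effect size (1 + e multiplier)",
                    ylab = "power (significant / total genes)", ...)
  graphics::legend("topleft", legend = levels(key), col = seq_len(ncol(m)),
                   lty = seq_len(ncol(m)), cex = 0.7, bty = "n")
  invisible(x)
}
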