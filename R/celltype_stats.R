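#' Test per cell type for nephrotoxic vs non-nephrotoxic score differences
#'
#' For each cell type, compares the logged per-type mean drug scores of
#' nephrotoxic drugs against non-nephrotoxic drugs with a Welch two-sample
#' t-test (the drug is the unit of observation). The log fold change is the
#' difference of group means on the logged scale, the fold change its
#' exponential, and the 95% CI the exponential of the Welch interval for the
#' mean difference. P-values are Benjamini-Hochberg corrected across the
#' cell types of the same abstraction level; rows are sorted by corrected
#' p ascending, ties broken by |t| descending.
#'
#' @param table a `cell_type_score_table` from [aggregate_by_cell_type()].
#' @return data.frame of class `signature_table` with columns `cell_type`,
#'   `level`, `t_statistic`, `log_fold_change`, `fold_change`, `ci_lower_95`,
#'   `ci_upper_95`, `p_value`, `corrected_p`, `n_toxic`, `n_nontoxic`.
#' @export
compare_groups <- function(table) {
  stopifnot(inherits(table, "cell_type_score_table"))
  rows <- lapply(split(table, table$cell_type), function(d) {
    tox <- d$mean_score[d$nephrotoxic]
    non <- d$mean_score[!d$nephrotoxic]
    if (length(tox) < 2L || length(non) < 2L)
      stop("degenerate group for cell type ", d$cell_type[1],
           " (need >= 2 drugs per group)", call. = FALSE)
    tt <- stats::t.test(tox, non, var.equal = FALSE, conf.level = 0.95)
    lfc <- mean(tox) - mean(non)
    data.frame(cell_type = d$cell_type[1], level = d$level[1],
               t_statistic = unname(tt$statistic),
               log_fold_change = lfc,
               fold_change = exp(lfc),
               ci_lower_95 = exp(tt$conf.int[1]),
               ci_upper_95 = exp(tt$conf.int[2]),
               p_value = tt$p.value,
               n_toxic = length(tox), n_nontoxic = length(non),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- bh_fdr(out$p_value)
  out <- out[order(out$corrected_p, -abs(out$t_statistic)), ]
  out <- out[c("cell_type", "level", "t_statistic", "log_fold_change",
               "fold_change", "ci_lower_95", "ci_upper_95", "p_value",
               "corrected_p", "n_toxic", "n_nontoxic")]
  rownames(out) <- NULL
  class(out) <- c("signature_table", "data.frame")
  out
}

#' @export
print.signature_table <- function(x, ...) {
  cat("signature_table:", nrow(x), "cell types (", x$level[1], ") —",
      sum(x$corrected_p < 0.05), "significant at FDR 0.05\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin, validated front end over the standard step-up adjustment: outputs
#' are order-preserving, lie in [0, 1], and are non-decreasing when the
#' inputs are sorted.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
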