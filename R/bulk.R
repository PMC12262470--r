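#' Bulk signature profile set
#'
#' Container for samples-by-genes bulk expression signatures (z-score-like,
#' possibly negative) with per-sample drug identity and nephrotoxicity flag
#' — the structure of replicate-level perturbation-signature compendia.
#'
#' @param profiles numeric matrix, samples in rows, genes in columns.
#' @param meta data.frame with columns `sample_id`, `drug_id`,
#'   `nephrotoxic` aligned to the rows of `profiles`.
#' @return list of class `bulk_profile_set`.
#' @export
bulk_profile_set <- function(profiles, meta) {
  profiles <- as.matrix(profiles)
  required <- c("sample_id", "drug_id", "nephrotoxic")
  if (!all(required %in% names(meta)))
    stop("meta must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != nrow(profiles))
    stop("metadata rows do not match profiles", call. = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id", call. = FALSE)
  rownames(profiles) <- meta$sample_id
  structure(list(profiles = profiles,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "bulk_profile_set")
}

#' Simulate a bulk signature compendium
#'
#' Synthetic stand-in for a replicate-level perturbation-signature dataset:
#' each drug has `n_replicates` standard-normal signature profiles sharing a
#' drug-specific mean vector; nephrotoxic drugs optionally shift a subset of
#' genes by `effect` to embed a recoverable differential signal.
#'
#' @param n_toxic,n_nontoxic drug counts per class.
#' @param n_genes number of genes.
#' @param n_replicates replicates per drug.
#' @param effect mean shift applied to `n_affected` genes in nephrotoxic
#'   drugs' profiles (0 = null data).
#' @param n_affected number of shifted genes.
#' @param seed integer seed.
#' @return a [bulk_profile_set()]; attribute `affected_genes` names the
#'   shifted genes.
#' @export
simulate_bulk_profiles <- function(n_toxic = 19L, n_nontoxic = 60L,
                                   n_genes = 978L, n_replicates = 3L,
                                   effect = 0, n_affected = 20L, seed = 1L) {
  genes <- sprintf("G%06d", seq_len(n_genes))
  drugs <- sprintf("D%04d", seq_len(n_toxic + n_nontoxic))
  toxic <- rep(c(TRUE, FALSE), c(n_toxic, n_nontoxic))
  with_seed(seed, {
    affected <- sample(genes, min(n_affected, n_genes))
    drug_mean <- matrix(stats::rnorm(length(drugs) * n_genes, sd = 0.5),
                        nrow = length(drugs),
                        dimnames = list(drugs, genes))
    drug_mean[toxic, affected] <- drug_mean[toxic, affected] + effect
    rows <- rep(seq_along(drugs), each = n_replicates)
    profiles <- drug_mean[rows, , drop = FALSE] +
      matrix(stats::rnorm(length(rows) * n_genes), nrow = length(rows))
  })
  meta <- data.frame(
    sample_id = sprintf("%s_rep%d", drugs[rows], sequence(rep(n_replicates,
                                                              length(drugs)))),
    drug_id = drugs[rows], nephrotoxic = toxic[rows],
    stringsAsFactors = FALSE)
  out <- bulk_profile_set(profiles, meta)
  attr(out, "affected_genes") <- affected
  out
}

#' Collapse replicate profiles to one profile per drug
#'
#' Averages the expression values over each drug's replicates; metadata is
#' carried through with one row per drug.
#'
#' @param x a [bulk_profile_set()].
#' @return a `bulk_profile_set` with one sample per drug.
#' @export
collapse_replicates <- function(x) {
  stopifnot(inherits(x, "bulk_profile_set"))
  if (!nrow(x$profiles)) stop("empty profile set", call. = FALSE)
  drug <- factor(x$meta$drug_id, levels = unique(x$meta$drug_id))
  collapsed <- rowsum(x$profiles, drug, reorder = FALSE) /
    as.vector(table(drug)[levels(drug)])
  meta <- x$meta[!duplicated(x$meta$drug_id), c("drug_id", "nephrotoxic")]
  meta <- data.frame(sample_id = meta$drug_id, meta,
                     stringsAsFactors = FALSE, row.names = NULL)
  bulk_profile_set(collapsed, meta)
}

#' Per-gene differential expression between toxic and non-toxic profiles
#'
#' Welch t-test per gene between nephrotoxic and non-nephrotoxic samples;
#' the log2-scale fold change is reported as the difference of group means
#' (profiles are signature-scale, already log-like) together with both
#' group means and Benjamini-Hochberg FDR across genes. Genes are selected
#' by `p < p_cut` combined with a bound on `|log2FC|`: `selection =
#' "at_most"` (default) keeps `|log2FC| <= lfc_cut`, the rule as commonly
#' printed alongside signature-scale compendia analyses; `"at_least"` keeps
#' `|log2FC| >= lfc_cut`, the conventional effect-size floor.
#'
#' @param x a [bulk_profile_set()].
#' @param p_cut p-value cutoff (default 0.05).
#' @param lfc_cut |log2FC| bound (default 1).
#' @param selection `"at_most"` or `"at_least"` (see above).
#' @return data.frame of class `de_result` with columns `gene`, `p_value`,
#'   `log2_fold_change`, `mean_toxic`, `mean_nontoxic`, `fdr`, `selected`;
#'   attribute `selected_genes` lists the selected gene IDs.
#' @export
differential_expression <- function(x, p_cut = 0.05, lfc_cut = 1,
                                    selection = c("at_most", "at_least")) {
  selection <- match.arg(selection)
  stopifnot(inherits(x, "bulk_profile_set"))
  tox <- x$meta$nephrotoxic
  if (sum(tox) < 2L || sum(!tox) < 2L)
    stop("need >= 2 samples in each class", call. = FALSE)
  res <- row_welch(t(x$profiles[tox, , drop = FALSE]),
                   t(x$profiles[!tox, , drop = FALSE]))
  out <- data.frame(gene = colnames(x$profiles),
                    p_value = res$p,
                    log2_fold_change = res$mean_x - res$mean_y,
                    mean_toxic = res$mean_x,
                    mean_nontoxic = res$mean_y,
                    fdr = bh_fdr(ifelse(is.na(res$p), 1, res$p)),
                    stringsAsFactors = FALSE)
  lfc_ok <- if (selection == "at_most") abs(out$log2_fold_change) <= lfc_cut
            else abs(out$log2_fold_change) >= lfc_cut
  out$selected <- !is.na(out$p_value) & out$p_value < p_cut & lfc_ok
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "selected_genes") <- out$gene[out$selected]
  attr(out, "lfc_convention") <- "difference of group means (signature scale)"
  out
}
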