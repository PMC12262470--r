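#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Unknown names are rejected.
#' Stage toggles: `simulate_data`, `preprocess`, `score`, `signatures`,
#' `classify` form the core chain (each requires its predecessor);
#' `power_sim` and `bulk_de` are optional side arms.
#'
#' @param out_dir artifact directory.
#' @param seed global seed; every stage derives its own seed from it.
#' @param stages named logical vector toggling stages.
#' @param n_cells,n_genes,n_donors,target_sparsity generator settings
#'   ([synthetic_config()]).
#' @param n_toxic,n_nontoxic drug database class sizes.
#' @param susceptible_types,enrichment_strength embedded toxicity signal
#'   ([signal_spec()]).
#' @param level abstraction level used for scoring/signatures/features.
#' @param qc a [qc_thresholds()].
#' @param grid a [simulation_grid()] (used when `power_sim` is on).
#' @param families classifier families for the `classify` stage.
#' @param k cross-validation folds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "nephrosig_out", seed = 1L,
                            stages = c(simulate_data = TRUE, preprocess = TRUE,
                                       score = TRUE, signatures = TRUE,
                                       classify = TRUE, power_sim = FALSE,
                                       bulk_de = FALSE),
                            n_cells = 3000L, n_genes = 2000L, n_donors = 8L,
                            target_sparsity = 0.85,
                            n_toxic = 215L, n_nontoxic = 641L,
                            susceptible_types = character(0),
                            enrichment_strength = 0,
                            level = "detailed32",
                            qc = qc_thresholds(),
                            grid = NULL,
                            families = c("extra_trees", "random_forest"),
                            k = 5L) {
  known <- c("simulate_data", "preprocess", "score", "signatures", "classify",
             "power_sim", "bulk_de")
  if (is.null(names(stages)) || !all(names(stages) %in% known))
    stop("unknown stage name(s): ",
         paste(setdiff(names(stages), known), collapse = ", "), call. = FALSE)
  st <- stats::setNames(rep(FALSE, length(known)), known)
  st[names(stages)] <- as.logical(stages)
  chain <- c("simulate_data", "preprocess", "score", "signatures", "classify")
  on_idx <- unname(which(st[chain]))
  if (length(on_idx) && !identical(on_idx, seq(min(on_idx), max(on_idx))))
    stop("core stages must form a contiguous chain", call. = FALSE)
  if (length(on_idx) && min(on_idx) > 1L)
    stop("pipeline runs must start from simulate_data in this artifact",
         call. = FALSE)
  level <- match.arg(level, c("detailed32", "abstract4"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = st,
                 n_cells = n_cells, n_genes = n_genes, n_donors = n_donors,
                 target_sparsity = target_sparsity, n_toxic = n_toxic,
                 n_nontoxic = n_nontoxic,
                 susceptible_types = susceptible_types,
                 enrichment_strength = enrichment_strength, level = level,
                 qc = qc, grid = grid, families = families, k = k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected before any stage runs.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), c("qc", "grid"))
  extra <- setdiff(names(raw), c(allowed, "qc", "grid"))
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  if (!is.null(raw$grid)) raw$grid <- do.call(simulation_grid, raw$grid)
  do.call(pipeline_config, raw)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order (simulate-data, preprocess, score,
#' signatures, classify; optionally power-sim and bulk-de), writing each
#' stage's outputs under `config$out_dir` and a `manifest.json` recording
#' the stage order, per-stage derived seeds, output file MD5 hashes and the
#' package version, so any artifact is reproducible from the manifest alone.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  results <- list()
  manifest <- list(package = "nephrosig",
                   version = as.character(utils::packageVersion("nephrosig")),
                   seed = config$seed, stages = list())
  note <- function(stage, seed, files) {
    h <- tools::md5sum(files)
    names(h) <- basename(names(h))
    manifest$stages[[stage]] <<- list(seed = seed, files = as.list(h))
  }

  if (st[["simulate_data"]]) {
    s <- derive_seed(config$seed, "simulate_data")
    specs <- kidney_cell_type_specs(
      n_genes = config$n_genes,
      level = if (config$level == "abstract4") "abstract4" else "detailed32",
      seed = s)
    cfg <- synthetic_config(n_cells = config$n_cells, n_genes = config$n_genes,
                            n_donors = config$n_donors,
                            target_sparsity = config$target_sparsity,
                            seed = s, cell_type_specs = specs)
    mat <- simulate_cell_matrix(cfg)
    db <- simulate_drug_db(config$n_toxic, config$n_nontoxic,
                           signal_spec(config$susceptible_types,
                                       config$enrichment_strength),
                           gene_universe = gene_ids(mat),
                           markers = marker_genes(specs),
                           seed = derive_seed(config$seed, "drug_db"))
    mdir <- file.path(config$out_dir, "matrix")
    write_cell_matrix(mat, mdir)
    write_drug_db(db, file.path(config$out_dir, "drugs.csv"))
    results$matrix <- mat; results$drug_db <- db; results$specs <- specs
    note("simulate_data", s,
         c(list.files(mdir, full.names = TRUE),
           file.path(config$out_dir, "drugs.csv")))
  }

  if (st[["preprocess"]]) {
    filt <- qc_filter(results$matrix, config$qc)
    filt <- log_normalize(filt, config$qc$scale_factor)
    results$matrix <- filt
    qc_path <- write_tsv(attr(filt, "qc_report"),
                         file.path(config$out_dir, "qc_report.tsv"))
    note("preprocess", NA, qc_path)
  }

  if (st[["score"]]) {
    tm <- build_target_matrix(results$drug_db, gene_ids(results$matrix))
    sc <- log_transform_scores(score_cells(results$matrix, tm))
    results$scores <- sc
    results$score_table <- aggregate_by_cell_type(sc, config$level)
    p <- write_tsv(results$score_table,
                   file.path(config$out_dir, "celltype_scores.tsv"))
    note("score", NA, p)
  }

  if (st[["signatures"]]) {
    results$signatures <- compare_groups(results$score_table)
    p <- write_tsv(results$signatures,
                   file.path(config$out_dir, "signatures.tsv"))
    note("signatures", NA, p)
  }

  if (st[["classify"]]) {
    feats <- build_feature_table(results$score_table)
    s <- derive_seed(config$seed, "classify")
    results$eval <- evaluate_models(feats, config$families, k = config$k,
                                    seed = s)
    p <- write_tsv(results$eval, file.path(config$out_dir, "eval.tsv"))
    note("classify", s, p)
  }

  if (st[["power_sim"]]) {
    grid <- if (is.null(config$grid))
      simulation_grid(seed = derive_seed(config$seed, "power"))
    else config$grid
    results$power <- run_power_grid(results$matrix, grid, "pseudo_bulk")
    p <- write_tsv(results$power, file.path(config$out_dir, "power.tsv"))
    note("power_sim", grid$seed, p)
  }

  if (st[["bulk_de"]]) {
    s <- derive_seed(config$seed, "bulk_de")
    bulk <- simulate_bulk_profiles(seed = s)
    de <- differential_expression(collapse_replicates(bulk))
    results$bulk_de <- de
    p <- write_tsv(de, file.path(config$out_dir, "bulk_de.tsv"))
    note("bulk_de", s, p)
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
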