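# Shared fixtures: everything is generated in code at test time.

# Small kidney-like spec set (detailed 32-type hierarchy at a small gene
# universe) and the matching synthetic matrix.
tiny_specs <- function(n_genes = 300, level = "detailed32",
                       markers_per_type = 4, seed = 11) {
  kidney_cell_type_specs(n_genes = n_genes, level = level,
                         markers_per_type = markers_per_type, seed = seed)
}

tiny_matrix <- function(n_cells = 600, n_genes = 300, n_donors = 6,
                        level = "detailed32", seed = 21, specs = NULL,
                        normalize = TRUE) {
  if (is.null(specs)) specs <- tiny_specs(n_genes = n_genes, level = level)
  cfg <- synthetic_config(n_cells = n_cells, n_genes = n_genes,
                          n_donors = n_donors, seed = seed,
                          cell_type_specs = specs)
  m <- simulate_cell_matrix(cfg)
  if (normalize) m <- log_normalize(m) else m
}

# One-type spec with uniform means; handy for degenerate cases.
one_type_specs <- function(n_genes = 50) {
  cell_type_specs("OnlyType", "Nephron", 1.0,
                  gene_ids = sprintf("G%06d", seq_len(n_genes)))
}

# A hand-built cell_matrix from a dense matrix of values; the values are
# installed as both counts and logcounts so downstream layers are exact.
manual_matrix <- function(values, types = NULL, donors = NULL,
                          abstract = NULL) {
  n <- nrow(values)
  if (is.null(types)) types <- rep("TypeA", n)
  if (is.null(abstract)) abstract <- types
  if (is.null(donors)) donors <- rep(sprintf("donor%02d", 1:2), length.out = n)
  rownames(values) <- sprintf("cell%06d", seq_len(n))
  colnames(values) <- sprintf("G%06d", seq_len(ncol(values)))
  cells <- data.frame(barcode = rownames(values), detailed_type = types,
                      abstract_type = abstract, donor = donors,
                      stringsAsFactors = FALSE)
  cell_matrix(values, cells, logcounts = values)
}

# End-to-end per-cell-type signature table from a freshly generated dataset
# with a configurable embedded toxicity signal.
signature_run <- function(seed, enrichment = 0,
                          susceptible = "Proximal tubule",
                          n_cells = 300, n_genes = 200, n_toxic = 24,
                          n_nontoxic = 72, level = "detailed32") {
  specs <- tiny_specs(n_genes = n_genes, level = level, seed = seed)
  m <- tiny_matrix(n_cells = n_cells, n_genes = n_genes, n_donors = 4,
                   seed = seed + 1, specs = specs)
  db <- simulate_drug_db(n_toxic, n_nontoxic,
                         signal_spec(susceptible, enrichment),
                         gene_universe = gene_ids(m),
                         markers = marker_genes(specs), seed = seed + 2)
  tm <- build_target_matrix(db, gene_ids(m))
  sc <- log_transform_scores(score_cells(m, tm))
  list(matrix = m, db = db, specs = specs, scores = sc,
       table = aggregate_by_cell_type(sc, level))
}

# Independent brute-force BH step-up (kept deliberately naive).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {          # for each rank, the step-up minimum
    adj[o[r]] <- min(1, min(p[o[r:m]] * m / (r:m)))
  }
  adj
}
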