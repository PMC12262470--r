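test_that("a single cell type at prevalence 1 annotates every cell with it", {
  cfg <- synthetic_config(n_cells = 40, n_genes = 50, n_donors = 2, seed = 1,
                          cell_type_specs = one_type_specs(50))
  m <- simulate_cell_matrix(cfg)
  expect_true(all(m$cells$detailed_type == "OnlyType"))
  expect_true(all(m$cells$abstract_type == "Nephron"))
})

test_that("abstract compartment fractions land within binomial sampling bounds", {
  specs <- tiny_specs(n_genes = 60, level = "abstract4", markers_per_type = 2)
  cfg <- synthetic_config(n_cells = 10000, n_genes = 60, n_donors = 4,
                          seed = 42, cell_type_specs = specs)
  m <- simulate_cell_matrix(cfg)
  frac <- mean(m$cells$abstract_type == "Nephron")
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.824) / 10000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  specs <- tiny_specs(n_genes = 80)
  cfg <- synthetic_config(n_cells = 120, n_genes = 80, n_donors = 3,
                          seed = 7, cell_type_specs = specs)
  m1 <- simulate_cell_matrix(cfg)
  m2 <- simulate_cell_matrix(cfg)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_identical(m1$cells, m2$cells)
  cfg2 <- synthetic_config(n_cells = 120, n_genes = 80, n_donors = 3,
                           seed = 8, cell_type_specs = specs)
  m3 <- simulate_cell_matrix(cfg2)
  expect_false(identical(as.matrix(m1$counts), as.matrix(m3$counts)))
})

test_that("realized prevalences converge to the configured ones", {
  specs <- tiny_specs(n_genes = 20, level = "abstract4", markers_per_type = 1)
  cfg <- synthetic_config(n_cells = 100000, n_genes = 20, n_donors = 4,
                          seed = 5, cell_type_specs = specs)
  m <- simulate_cell_matrix(cfg)
  want <- c(Nephron = 0.824, Endothelium = 0.078, Immune = 0.071,
            Stroma = 0.026) / 0.999
  got <- table(m$cells$abstract_type)[names(want)] / 100000
  expect_lt(max(abs(got - want)), 0.01)
})

test_that("realized sparsity tracks the configured target", {
  for (target in c(0.80, 0.90)) {
    specs <- tiny_specs(n_genes = 200)
    cfg <- synthetic_config(n_cells = 400, n_genes = 200, n_donors = 4,
                            seed = 9, target_sparsity = target,
                            cell_type_specs = specs)
    m <- simulate_cell_matrix(cfg)
    zf <- 1 - Matrix::nnzero(m$counts) / prod(dim(m))
    expect_lt(abs(zf - target), 0.05)
  }
})

test_that("generator rejects invalid configurations", {
  expect_error(synthetic_config(n_donors = 1), "n_donors")
  specs <- one_type_specs(10)
  specs$OnlyType$prevalence <- 0.5
  expect_error(synthetic_config(n_cells = 10, n_genes = 10,
                                cell_type_specs = specs), "sum to 1")
  cfg <- synthetic_config(n_cells = 10, n_genes = 300, n_donors = 2,
                          cell_type_specs = tiny_specs(300))
  expect_error(simulate_cell_matrix(cfg), "too few cells")
})

test_that("drug database honors class sizes and enrichment boundaries", {
  specs <- tiny_specs(n_genes = 300)
  genes <- attr(specs, "gene_ids")
  db <- simulate_drug_db(215, 641, signal_spec(), genes, seed = 1)
  expect_equal(nrow(db), 856)
  expect_equal(sum(db$nephrotoxic), 215)
  expect_false(anyDuplicated(db$drug_id) > 0)
  expect_true(all(lengths(db$target_genes) >= 1))

  mk <- marker_genes(specs)
  db1 <- simulate_drug_db(20, 20, signal_spec("Podocyte", 1), genes,
                          markers = mk, seed = 2)
  pod <- mk[["Podocyte"]]
  for (t in db1$target_genes[db1$nephrotoxic])
    expect_true(all(t %in% pod))

  expect_error(simulate_drug_db(5, 5, signal_spec("Podocyte", 0.5), genes,
                                markers = list(Podocyte = character(0)),
                                seed = 3),
               "nonempty marker sets")
})

test_that("null databases decouple target composition from the label", {
  specs <- tiny_specs(n_genes = 300)
  genes <- attr(specs, "gene_ids")
  mk_all <- unique(unlist(marker_genes(specs)))
  # pooled over 50 seeds: marker-membership of targets vs toxicity label
  counts <- matrix(0, 2, 2)
  for (s in 1:50) {
    db <- simulate_drug_db(15, 45, signal_spec(), genes, seed = 100 + s)
    in_marker <- vapply(db$target_genes,
                        function(t) sum(t %in% mk_all), numeric(1))
    out_marker <- lengths(db$target_genes) - in_marker
    counts <- counts + rbind(c(sum(in_marker[db$nephrotoxic]),
                               sum(out_marker[db$nephrotoxic])),
                             c(sum(in_marker[!db$nephrotoxic]),
                               sum(out_marker[!db$nephrotoxic])))
  }
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("drug database CSV roundtrip is lossless", {
  specs <- tiny_specs(n_genes = 100)
  db <- simulate_drug_db(8, 12, signal_spec(), attr(specs, "gene_ids"),
                         seed = 4)
  path <- file.path(tempdir(), "drugs.csv")
  write_drug_db(db, path)
  back <- read_drug_db(path)
  expect_equal(back$drug_id, db$drug_id)
  expect_equal(back$nephrotoxic, db$nephrotoxic)
  expect_equal(back$target_genes, db$target_genes)
})
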