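test_that("subsampling preserves per-type counts and is seed-stratified", {
  m <- tiny_matrix(n_cells = 400, n_genes = 100, normalize = FALSE)
  all_back <- subsample_preserving_prevalence(m, 1.0, seed = 1)
  expect_equal(n_cells(all_back), n_cells(m))

  # a type with exactly 1000 cells yields exactly 100 at fraction 0.10
  vals <- matrix(rpois(1300 * 20, 2), nrow = 1300)
  types <- rep(c("Big", "Small"), c(1000, 300))
  m2 <- manual_matrix(vals, types = types)
  sub <- suppressWarnings(subsample_preserving_prevalence(m2, 0.10, seed = 2))
  expect_equal(sum(sub$cells$detailed_type == "Big"), 100)
  expect_equal(sum(sub$cells$detailed_type == "Small"), 30)

  s1 <- subsample_preserving_prevalence(m2, 0.10, seed = 3)
  s2 <- subsample_preserving_prevalence(m2, 0.10, seed = 4)
  expect_false(identical(s1$cells$barcode, s2$cells$barcode))
  expect_equal(table(s1$cells$detailed_type), table(s2$cells$detailed_type))

  # types whose allocation rounds to zero are dropped with a warning
  m3 <- manual_matrix(matrix(1, 102, 5), types = rep(c("A", "B"), c(100, 2)))
  expect_warning(subsample_preserving_prevalence(m3, 0.10, seed = 5),
                 "dropped")
})

test_that("drug effects multiply responding cells by (1 + effect) only", {
  vals <- matrix(c(2, 0, 1,
                   4, 1, 0,
                   3, 2, 2,
                   5, 0, 1), nrow = 4, byrow = TRUE)
  m <- manual_matrix(vals, types = rep(c("Hit", "Other"), each = 2))

  none <- apply_drug_effect(m, "Hit", 0, 1, seed = 1)
  expect_equal(as.matrix(none$logcounts), as.matrix(m$logcounts))

  hit <- apply_drug_effect(m, "Hit", 10, 1, seed = 1)
  expect_equal(hit$logcounts[1, 1], 22)               # 2 * (1 + 10)
  expect_equal(as.matrix(hit$logcounts[3:4, ]),
               as.matrix(m$logcounts[3:4, ]))          # others untouched
  expect_equal(as.matrix(hit$logcounts[1:2, ]),
               as.matrix(m$logcounts[1:2, ]) * 11)

  doubled <- apply_drug_effect(m, "Hit", 1, 1, seed = 1)
  expect_equal(as.matrix(doubled$logcounts[1:2, ]),
               as.matrix(m$logcounts[1:2, ]) * 2)

  # zeros stay zero and the input is not mutated
  expect_equal(hit$logcounts[1, 2], 0)
  expect_equal(m$logcounts[1, 1], 2)
  expect_error(apply_drug_effect(m, "NoSuchType", 1, 1), "unknown cell type")

  # floor-with-minimum-one responding-cell rule
  low <- apply_drug_effect(m, "Hit", 1, 0.4, seed = 1)
  expect_length(attr(low, "responding"), 1)            # floor(0.8) -> min 1
})

test_that("pseudo-bulk averages per gene, by donor or globally", {
  same <- manual_matrix(matrix(rep(c(1, 2, 3), each = 4), nrow = 4))
  pb <- pseudo_bulk(same, "none")
  expect_equal(as.numeric(pb), c(1, 2, 3))

  two <- manual_matrix(matrix(c(1, 3), nrow = 2, ncol = 1))
  expect_equal(as.numeric(pseudo_bulk(two, "none")), 2)

  # dilution arithmetic: 2.6% of cells at 10, rest 0 -> bulk 0.26
  n <- 1000
  vals <- matrix(0, n, 1); vals[1:26, 1] <- 10
  dil <- manual_matrix(vals, types = rep(c("Rare", "Common"), c(26, 974)))
  expect_equal(as.numeric(pseudo_bulk(dil, "none")), 0.26)

  # donor grouping returns one profile per donor
  m <- tiny_matrix(n_cells = 200, n_genes = 50, n_donors = 4)
  prof <- pseudo_bulk(m, "donor")
  expect_equal(ncol(prof), 4)
  d <- m$cells$donor == "donor01"
  expect_equal(prof[, "donor01"],
               Matrix::colMeans(m$logcounts[d, , drop = FALSE]))
})

test_that("a toy one-signal-gene design yields power exactly 1/3", {
  # 3 genes, 2 donors per arm; gene 1 carries tight signal, genes 2-3 are
  # all-zero (no variance information -> never significant)
  vals <- cbind(1 + c(0, 2e-7, 1e-7, 3e-7), 0, 0)
  m <- manual_matrix(vals, types = rep("OnlyType", 4),
                     donors = rep(c("donor01", "donor02"), each = 2))
  grid <- simulation_grid(effect_sizes = 10, response_rates = 1,
                          subsample_fraction = 1, n_replicate_runs = 1,
                          seed = 1)
  res <- run_power_grid(m, grid, "pseudo_bulk", cell_types = "OnlyType")
  expect_equal(res$power, 1 / 3)
})

test_that("null effects produce essentially no significant genes", {
  m <- tiny_matrix(n_cells = 400, n_genes = 400, n_donors = 6)
  grid <- simulation_grid(effect_sizes = 0, response_rates = 0.8,
                          n_replicate_runs = 3, seed = 5)
  res <- suppressWarnings(
    run_power_grid(m, grid, "pseudo_bulk", cell_types = "Nephron"))
  expect_lte(res$power, 0.001)
})

test_that("power is non-decreasing in effect size", {
  m <- tiny_matrix(n_cells = 600, n_genes = 300, n_donors = 8,
                   level = "abstract4",
                   specs = tiny_specs(300, "abstract4"))
  grid <- simulation_grid(effect_sizes = c(0.001, 0.1, 1, 10),
                          response_rates = 0.8, n_replicate_runs = 5,
                          seed = 11)
  res <- run_power_grid(m, grid, "pseudo_bulk", cell_types = "Nephron")
  ord <- order(res$effect_size)
  expect_gte(suppressWarnings(cor(res$effect_size[ord], res$power[ord],
                                  method = "spearman")), 0)
  expect_true(all(diff(res$power[ord]) >= -1e-9))
})

test_that("power is invariant to gene ordering", {
  specs <- tiny_specs(200, "abstract4")
  m <- tiny_matrix(n_cells = 300, n_genes = 200, n_donors = 4,
                   level = "abstract4", specs = specs)
  perm <- sample(n_genes(m))
  mp <- cell_matrix(m$counts[, perm], m$cells,
                    logcounts = m$logcounts[, perm])
  grid <- simulation_grid(effect_sizes = c(1, 10), response_rates = 0.8,
                          n_replicate_runs = 2, seed = 3)
  r1 <- run_power_grid(m, grid, "pseudo_bulk", cell_types = "Nephron")
  r2 <- run_power_grid(mp, grid, "pseudo_bulk", cell_types = "Nephron")
  expect_equal(r1$power, r2$power)
})

test_that("pseudo-bulk power saturates below 1 at extreme effect sizes", {
  m <- tiny_matrix(n_cells = 600, n_genes = 400, n_donors = 8,
                   level = "abstract4",
                   specs = tiny_specs(400, "abstract4"))
  grid <- simulation_grid(effect_sizes = 1e4, response_rates = 0.95,
                          n_replicate_runs = 3, seed = 13)
  res <- run_power_grid(m, grid, "pseudo_bulk", cell_types = "Nephron")
  expect_lt(res$power, 1)
})
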