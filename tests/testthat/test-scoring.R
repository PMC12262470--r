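make_db <- function(targets, toxic) {
  db <- data.frame(drug_id = sprintf("D%04d", seq_along(targets)),
                   nephrotoxic = toxic, stringsAsFactors = FALSE)
  db$target_genes <- targets
  class(db) <- c("drug_target_db", "data.frame")
  db
}

test_that("target matrix encodes membership and excludes unmeasured drugs", {
  db <- make_db(list(c("A", "B"), "Z"), c(TRUE, FALSE))
  expect_warning(tm <- build_target_matrix(db, c("A", "B", "C")),
                 "no measured targets")
  expect_equal(dim(tm), c(1L, 3L))
  expect_equal(as.numeric(tm["D0001", ]), c(1, 1, 0))
  expect_equal(attr(tm, "excluded"), "D0002")
  expect_error(build_target_matrix(db, character(0)), "empty gene universe")

  # count oracle on a generated database: exclusions only
  specs <- tiny_specs(n_genes = 100)
  big <- simulate_drug_db(20, 40, signal_spec(), attr(specs, "gene_ids"),
                          seed = 2)
  tm2 <- build_target_matrix(big, attr(specs, "gene_ids"))
  expect_lte(nrow(tm2), 60)
  expect_equal(nrow(tm2) + length(attr(tm2, "excluded")), 60)
})

test_that("drug scores are target-gene means, vs brute-force recomputation", {
  m <- tiny_matrix(n_cells = 60, n_genes = 40)
  genes <- gene_ids(m)
  db <- make_db(list(genes[5], genes[c(2, 9)], genes[c(1, 3, 7, 20)]),
                c(TRUE, FALSE, FALSE))
  tm <- build_target_matrix(db, genes)
  sc <- score_cells(m, tm)

  # single target: score equals that gene's expression for every cell
  expect_equal(unname(sc$raw[, "D0001"]), as.numeric(m$logcounts[, 5]))

  # brute force: loop over cells and drugs
  for (d in seq_len(nrow(db))) {
    manual <- apply(as.matrix(m$logcounts[, db$target_genes[[d]],
                                          drop = FALSE]), 1, mean)
    expect_equal(unname(sc$raw[, d]), unname(manual))
  }

  # arithmetic-mean example: targets at 1.0 and 3.0 average to 2.0
  mm <- manual_matrix(matrix(c(1, 3, 99), nrow = 1))
  db2 <- make_db(list(c("G000001", "G000002")), TRUE)
  sc2 <- score_cells(mm, build_target_matrix(db2, gene_ids(mm)))
  expect_equal(unname(sc2$raw[1, 1]), 2)

  expect_error(score_cells(m, tm[, 1:10]), "misaligned")
})

test_that("scores ignore non-target genes and respect permutations", {
  m <- tiny_matrix(n_cells = 40, n_genes = 30)
  genes <- gene_ids(m)
  db <- make_db(list(genes[c(3, 8)], genes[c(10, 11, 12)]), c(TRUE, FALSE))
  tm <- build_target_matrix(db, genes)
  base_scores <- score_cells(m, tm)$raw

  # perturb a non-target gene: scores unchanged
  m2 <- m
  m2$logcounts[, 25] <- m2$logcounts[, 25] + 5
  expect_equal(score_cells(m2, tm)$raw, base_scores)

  # raise a target gene: that drug's score never decreases
  m3 <- m
  m3$logcounts[, 3] <- m3$logcounts[, 3] + 1
  up <- score_cells(m3, tm)$raw
  expect_true(all(up[, 1] >= base_scores[, 1]))
  expect_equal(up[, 2], base_scores[, 2])

  # permuting gene columns together with the target matrix changes nothing
  perm <- sample(length(genes))
  mp <- cell_matrix(m$counts[, perm], m$cells, logcounts = m$logcounts[, perm])
  tmp <- build_target_matrix(db, genes[perm])
  expect_equal(score_cells(mp, tmp)$raw, base_scores)
})

test_that("log transform floors zeros, preserves order, fixes FC convention", {
  mm <- manual_matrix(matrix(c(0, 1, 3), nrow = 1))
  db <- make_db(list("G000001", "G000002", "G000003"), c(TRUE, FALSE, FALSE))
  sc <- log_transform_scores(score_cells(mm,
                                         build_target_matrix(db, gene_ids(mm))))
  expect_equal(unname(sc$logged[1, 1]), log(1e-9))
  expect_true(all(is.finite(sc$logged)))
  expect_true(sc$logged[1, 1] < sc$logged[1, 2])
  expect_true(sc$logged[1, 2] < sc$logged[1, 3])
  expect_equal(sc$log_epsilon, 1e-9)

  bad <- sc; bad$raw[1, 1] <- -1
  expect_error(log_transform_scores(bad), "negative")

  # natural-log fold-change convention: FC = exp(logFC)
  expect_equal(exp(-0.524), 0.592, tolerance = 1e-3)
})

test_that("cell-type aggregation averages logged scores consistently", {
  m <- tiny_matrix(n_cells = 200, n_genes = 60)
  db <- simulate_drug_db(10, 20, signal_spec(), gene_ids(m), seed = 3)
  sc <- log_transform_scores(score_cells(m, build_target_matrix(db,
                                                                gene_ids(m))))
  det <- aggregate_by_cell_type(sc, "detailed32")
  ab <- aggregate_by_cell_type(sc, "abstract4")

  n_drugs <- ncol(sc$raw)
  expect_equal(nrow(ab), 4 * n_drugs)
  expect_equal(nrow(det),
               length(unique(m$cells$detailed_type)) * n_drugs)

  # constant-score type aggregates to the constant
  d1 <- det[det$drug_id == "D0001", ]
  t1 <- d1$cell_type[1]
  cells_t1 <- m$cells$detailed_type == t1
  expect_equal(d1$mean_score[d1$cell_type == t1],
               mean(sc$logged[cells_t1, "D0001"]))

  # weighted-mean identity: detailed means within a parent, weighted by
  # cell counts, equal the abstract mean
  for (drug in c("D0001", "D0015")) {
    for (par in unique(m$cells$abstract_type)) {
      dts <- unique(m$cells$detailed_type[m$cells$abstract_type == par])
      w <- table(factor(m$cells$detailed_type,
                        levels = dts))[dts]
      dmeans <- det$mean_score[det$drug_id == drug &
                               det$cell_type %in% dts]
      names(dmeans) <- det$cell_type[det$drug_id == drug &
                                     det$cell_type %in% dts]
      expected <- sum(dmeans[dts] * as.numeric(w)) / sum(w)
      got <- ab$mean_score[ab$drug_id == drug & ab$cell_type == par]
      expect_equal(got, expected)
    }
  }

  # aggregation requires the logged layer
  raw_only <- score_cells(m, build_target_matrix(db, gene_ids(m)))
  expect_error(aggregate_by_cell_type(raw_only), "log-transform")
})
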