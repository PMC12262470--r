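#' Kidney cell-type specifications
#'
#' Builds the default synthetic kidney cell-type hierarchy: four abstract
#' compartments (Nephron, Endothelium, Immune, Stroma) at prevalences
#' 82.4/7.8/7.1/2.6%, optionally partitioned into 32 detailed subtypes
#' (e.g. Indistinct intercalated cell under Nephron, MNP-b/non-classical
#' monocyte derived under Immune, Peritubular capillary endothelium 1 under
#' Endothelium). Within a compartment, subtype prevalences follow a 1/rank
#' (Zipf) series so a few subtypes dominate, as in real kidney atlases.
#'
#' Each spec carries per-gene negative-binomial parameters: a base mean
#' vector shared across types with type-specific marker genes boosted by
#' `marker_fold`, and a per-gene dispersion. Marker genes are disjoint
#' across types and are, by construction, among the top-expressed genes of
#' their own type.
#'
#' @param n_genes number of genes in the universe.
#' @param level `"detailed32"` for the 32-subtype hierarchy or `"abstract4"`
#'   for the four compartments only.
#' @param markers_per_type number of exclusive marker genes per (detailed)
#'   type; reduced automatically if the universe is too small.
#' @param marker_fold multiplicative boost of a marker gene's mean within its
#'   own type. Default 8, a typical fold for discriminative cell-type markers.
#' @param mean_sdlog log-scale standard deviation of the lognormal base gene
#'   means.
#' @param seed seed controlling base means, dispersions and marker placement.
#'
#' @return A list of class `cell_type_specs`: elements named by detailed type,
#'   each with `name`, `abstract_parent`, `prevalence`, `marker_genes`,
#'   `base_mean` and `dispersion`; attribute `gene_ids` gives the universe.
#' @export
kidney_cell_type_specs <- function(n_genes = 20000L,
                                   level = c("detailed32", "abstract4"),
                                   markers_per_type = 25L,
                                   marker_fold = 8,
                                   mean_sdlog = 1.25,
                                   seed = 1L) {
  level <- match.arg(level)
  n_genes <- assert_count(n_genes, "n_genes")
  # published compartment fractions (82.4/7.8/7.1/2.6%) sum to 0.999;
  # renormalized so the prevalence invariant holds exactly
  abstract <- c(Nephron = 0.824, Endothelium = 0.078, Immune = 0.071,
                Stroma = 0.026)
  abstract <- abstract / sum(abstract)
  map <- detailed_abstract_map(level)
  genes <- sprintf("G%06d", seq_len(n_genes))

  # split each compartment's prevalence over its subtypes by 1/rank weights
  prev <- numeric(nrow(map))
  for (a in names(abstract)) {
    idx <- which(map$abstract == a)
    w <- 1 / seq_along(idx)
    prev[idx] <- abstract[[a]] * w / sum(w)
  }

  n_types <- nrow(map)
  markers_per_type <- min(markers_per_type, floor(n_genes / max(1L, n_types)))
  with_seed(seed, {
    base_mean <- stats::rlnorm(n_genes, meanlog = 0, sdlog = mean_sdlog)
    dispersion <- stats::runif(n_genes, 0.5, 2)
    marker_pool <- sample.int(n_genes, n_types * markers_per_type)
    specs <- vector("list", n_types)
    for (i in seq_len(n_types)) {
      mk <- if (markers_per_type > 0)
        marker_pool[((i - 1L) * markers_per_type + 1L):(i * markers_per_type)]
      else integer(0)
      mu <- base_mean
      mu[mk] <- mu[mk] * marker_fold
      specs[[i]] <- list(name = map$detailed[i],
                         abstract_parent = map$abstract[i],
                         prevalence = prev[i],
                         marker_genes = genes[mk],
                         base_mean = mu,
                         dispersion = dispersion)
    }
  })
  names(specs) <- map$detailed
  structure(specs, gene_ids = genes, class = "cell_type_specs")
}

# Detailed -> abstract mapping table. The 32 subtype names follow the kidney
# cell atlas nomenclature; counts per compartment: 18/5/6/3.
detailed_abstract_map <- function(level) {
  if (level == "abstract4") {
    return(data.frame(
      detailed = c("Nephron", "Endothelium", "Immune", "Stroma"),
      abstract = c("Nephron", "Endothelium", "Immune", "Stroma"),
      stringsAsFactors = FALSE))
  }
  nephron <- c("Proximal tubule", "Distinct proximal tubule 1",
               "Distinct proximal tubule 2", "Proliferating Proximal Tubule",
               "Epithelial progenitor cell", "Indistinct intercalated cell",
               "Type A intercalated cell", "Type B intercalated cell",
               "Principal cell", "Connecting tubule",
               "Distal convoluted tubule",
               "Thick ascending limb of Loop of Henle",
               "Thin ascending limb", "Descending thin limb", "Podocyte",
               "Parietal epithelial cell", "Transitional urothelium",
               "Pelvic epithelium")
  endo <- c("Peritubular capillary endothelium 1",
            "Peritubular capillary endothelium 2", "Glomerular endothelium",
            "Ascending vasa recta endothelium",
            "Descending vasa recta endothelium")
  immune <- c("MNP-a/classical monocyte derived",
              "MNP-b/non-classical monocyte derived", "CD4 T cell",
              "CD8 T cell", "B cell", "NK cell")
  stroma <- c("Fibroblast", "Myofibroblast", "Vascular smooth muscle cell")
  data.frame(detailed = c(nephron, endo, immune, stroma),
             abstract = rep(c("Nephron", "Endothelium", "Immune", "Stroma"),
                            c(length(nephron), length(endo), length(immune),
                              length(stroma))),
             stringsAsFactors = FALSE)
}

#' Construct custom cell-type specifications
#'
#' Lower-level companion to [kidney_cell_type_specs()] for bespoke
#' hierarchies (single-type degenerate cases, toy fixtures, non-kidney
#' tissues). Base means and dispersions may be given per type or recycled
#' from a single vector.
#'
#' @param names detailed type names (unique).
#' @param parents abstract parent per type.
#' @param prevalences fractions summing to 1 (tolerance 1e-9).
#' @param gene_ids the gene universe.
#' @param base_mean nonnegative mean vector (length `length(gene_ids)`), or
#'   a list of one such vector per type.
#' @param dispersion positive per-gene size parameter vector.
#' @param markers optional named list of marker gene sets per type.
#' @return a `cell_type_specs` object.
#' @export
cell_type_specs <- function(names, parents, prevalences, gene_ids,
                            base_mean = rep(1, length(gene_ids)),
                            dispersion = rep(1, length(gene_ids)),
                            markers = NULL) {
  stopifnot(length(names) == length(parents),
            length(names) == length(prevalences),
            !anyDuplicated(names))
  if (!is.list(base_mean)) base_mean <- rep(list(base_mean), length(names))
  specs <- lapply(seq_along(names), function(i) {
    list(name = names[i], abstract_parent = parents[i],
         prevalence = prevalences[i],
         marker_genes = if (is.null(markers)) character(0)
                        else markers[[names[i]]],
         base_mean = base_mean[[i]], dispersion = dispersion)
  })
  names(specs) <- names
  out <- structure(specs, gene_ids = gene_ids, class = "cell_type_specs")
  validate_specs(out, length(gene_ids))
  out
}

#' Marker gene sets of a specification
#' @param specs a `cell_type_specs` object.
#' @return named list of character vectors (marker gene IDs per type).
#' @export
marker_genes <- function(specs) {
  stopifnot(inherits(specs, "cell_type_specs"))
  lapply(specs, `[[`, "marker_genes")
}

#' Synthetic dataset configuration
#'
#' Bundles generator settings. Defaults emulate a multi-donor integrated
#' kidney dataset: a 20,000-gene universe, eight donors, and ~85% zero
#' entries, with counts drawn from a per-type negative-binomial model with
#' multiplicative dropout and lognormal per-donor depth factors.
#'
#' @param n_cells,n_genes,n_donors dataset dimensions; `n_donors >= 2` so
#'   that donor-level pseudo-bulk replicates support t-tests. The default 24
#'   donors mirrors a multi-sample integrated atlas; 6,000 cells keeps the
#'   default dataset desk-scale.
#' @param target_sparsity desired zero fraction of the counts matrix; the
#'   generator calibrates a global mean scale so the realized zero fraction
#'   lands within a few percentage points of this.
#' @param dropout per-entry multiplicative dropout probability on top of
#'   negative-binomial zeros.
#' @param donor_sdlog log-scale sd of the lognormal per-donor depth factor.
#' @param seed integer; fully determines the generated matrix.
#' @param cell_type_specs a `cell_type_specs` object; defaults to
#'   [kidney_cell_type_specs()] at the requested `n_genes`.
#'
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 6000L, n_genes = 20000L,
                             n_donors = 24L, target_sparsity = 0.85,
                             dropout = 0.05, donor_sdlog = 0.3, seed = 1L,
                             cell_type_specs = NULL) {
  n_cells <- assert_count(n_cells, "n_cells")
  n_genes <- assert_count(n_genes, "n_genes")
  n_donors <- assert_count(n_donors, "n_donors")
  if (n_donors < 2L) stop("n_donors must be >= 2 (replicates for t-tests)",
                          call. = FALSE)
  assert_fraction(target_sparsity, "target_sparsity")
  assert_fraction(dropout, "dropout", allow_one = FALSE)
  if (is.null(cell_type_specs))
    cell_type_specs <- kidney_cell_type_specs(n_genes = n_genes, seed = seed)
  validate_specs(cell_type_specs, n_genes)
  structure(list(n_cells = n_cells, n_genes = n_genes, n_donors = n_donors,
                 target_sparsity = target_sparsity, dropout = dropout,
                 donor_sdlog = donor_sdlog, seed = as.integer(seed),
                 cell_type_specs = cell_type_specs),
            class = "synthetic_config")
}

validate_specs <- function(specs, n_genes) {
  if (!inherits(specs, "cell_type_specs")) stop("cell_type_specs must be built by kidney_cell_type_specs() or compatible", call. = FALSE)
  prev <- vapply(specs, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-9)
    stop("cell-type prevalences must sum to 1 (got ", sum(prev), ")",
         call. = FALSE)
  genes <- attr(specs, "gene_ids")
  if (length(genes) != n_genes)
    stop("spec gene universe (", length(genes), ") does not match n_genes (",
         n_genes, ")", call. = FALSE)
  for (s in specs) {
    if (length(s$base_mean) != n_genes || any(s$base_mean < 0))
      stop("base_mean must be a nonnegative vector of length n_genes",
           call. = FALSE)
    if (any(s$dispersion <= 0)) stop("dispersion must be positive", call. = FALSE)
    if (!all(s$marker_genes %in% genes))
      stop("marker genes outside the gene universe", call. = FALSE)
  }
  invisible(specs)
}

#' Generate a synthetic annotated single-cell counts matrix
#'
#' Draws cell types multinomially at the configured prevalences, assigns
#' cells to donors in near-equal blocks, and samples counts from a per-type
#' negative-binomial model with per-donor lognormal depth factors and
#' per-entry multiplicative dropout. A global mean scale is first calibrated
#' analytically so the expected zero fraction matches
#' `config$target_sparsity`.
#'
#' @param config a [synthetic_config()].
#' @return a [cell_matrix()] with annotations `detailed_type`,
#'   `abstract_type` and `donor`.
#' @export
simulate_cell_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- config$cell_type_specs
  if (config$n_cells < length(specs)) stop("too few cells", call. = FALSE)
  genes <- attr(specs, "gene_ids")
  prev <- vapply(specs, `[[`, numeric(1), "prevalence")
  mu_mat <- do.call(rbind, lapply(specs, `[[`, "base_mean"))   # types x genes
  disp <- specs[[1]]$dispersion

  with_seed(config$seed, {
    type_idx <- sample.int(length(specs), config$n_cells, replace = TRUE,
                           prob = prev)
    donor <- sample(rep_len(sprintf("donor%02d", seq_len(config$n_donors)),
                            config$n_cells))
    donor_factor <- stats::rlnorm(config$n_donors, 0, config$donor_sdlog)
    names(donor_factor) <- sprintf("donor%02d", seq_len(config$n_donors))
    cell_factor <- donor_factor[donor]

    scale_c <- calibrate_sparsity(mu_mat, disp, prev, donor_factor,
                                  config$target_sparsity, config$dropout)

    n_cells <- config$n_cells
    block <- max(1L, min(config$n_genes, floor(5e6 / n_cells)))
    starts <- seq(1L, config$n_genes, by = block)
    blocks <- vector("list", length(starts))
    for (b in seq_along(starts)) {
      j <- starts[b]:min(starts[b] + block - 1L, config$n_genes)
      mu <- mu_mat[type_idx, j, drop = FALSE] * cell_factor * scale_c
      size <- matrix(disp[j], nrow = n_cells, ncol = length(j), byrow = TRUE)
      x <- stats::rnbinom(length(mu), mu = as.vector(mu), size = as.vector(size))
      if (config$dropout > 0)
        x[stats::runif(length(x)) < config$dropout] <- 0L
      blocks[[b]] <- Matrix::Matrix(matrix(as.double(x), nrow = n_cells),
                                    sparse = TRUE)
    }
    counts <- do.call(cbind, blocks)
  })
  dimnames(counts) <- list(sprintf("cell%06d", seq_len(config$n_cells)), genes)
  cells <- data.frame(
    barcode = rownames(counts),
    detailed_type = names(specs)[type_idx],
    abstract_type = vapply(specs, `[[`, character(1), "abstract_parent")[type_idx],
    donor = donor,
    stringsAsFactors = FALSE)
  cell_matrix(counts, cells)
}

# Solve for a scalar multiplier on the mean matrix so the expected zero
# fraction equals the target:  P0 = d + (1-d) * (size/(size + c*mu))^size,
# averaged over genes (subsampled), types (prevalence-weighted) and donors.
calibrate_sparsity <- function(mu_mat, disp, prev, donor_factor, target, dropout) {
  n_genes <- ncol(mu_mat)
  j <- if (n_genes > 2000L) sort(sample.int(n_genes, 2000L)) else seq_len(n_genes)
  mu_s <- mu_mat[, j, drop = FALSE]
  disp_s <- disp[j]
  dm <- matrix(disp_s, nrow = nrow(mu_s), ncol = length(j), byrow = TRUE)
  expected_zero <- function(logc) {
    c0 <- 10^logc
    p0 <- 0
    for (f in donor_factor) {
      nb0 <- (dm / (dm + c0 * f * mu_s))^dm
      p0 <- p0 + sum(prev * rowMeans(nb0))
    }
    dropout + (1 - dropout) * p0 / length(donor_factor)
  }
  lo <- expected_zero(6); hi <- expected_zero(-6)
  if (target <= lo) return(10^6)
  if (target >= hi) return(10^-6)
  10^stats::uniroot(function(lc) expected_zero(lc) - target,
                    c(-6, 6), tol = 1e-4)$root
}

#' Toxicity signal specification for the drug database generator
#'
#' @param susceptible_types character vector of cell-type names whose marker
#'   genes are over-represented among nephrotoxic drugs' targets.
#' @param enrichment_strength fraction in `[0, 1]` of a nephrotoxic drug's
#'   targets drawn from susceptible-type marker genes; 0 yields a null
#'   database in which labels are independent of target composition.
#' @return list of class `signal_spec`.
#' @export
signal_spec <- function(susceptible_types = character(0),
                        enrichment_strength = 0) {
  assert_fraction(enrichment_strength, "enrichment_strength")
  structure(list(susceptible_types = as.character(susceptible_types),
                 enrichment_strength = enrichment_strength),
            class = "signal_spec")
}

#' Generate a drug -> target-genes -> toxicity database
#'
#' Emulates a curated drug-target-toxicity resource: each drug carries a
#' nonempty target gene set and a binary nephrotoxicity flag. Nephrotoxic
#' drugs draw `enrichment_strength` of their targets from the marker genes
#' of the susceptible cell types; all remaining targets (and all targets of
#' non-nephrotoxic drugs) are drawn uniformly from the gene universe. The
#' default class sizes follow the 215:641 nephrotoxic:non-nephrotoxic ratio
#' of curated FDA-label drug sets.
#'
#' @param n_toxic,n_nontoxic numbers of nephrotoxic / non-nephrotoxic drugs.
#' @param signal a [signal_spec()].
#' @param gene_universe character vector of valid gene IDs.
#' @param markers named list of marker gene sets per cell type (see
#'   [marker_genes()]); required when `enrichment_strength > 0`.
#' @param mean_targets expected number of targets per drug (target set sizes
#'   are `1 + Poisson(mean_targets - 1)`).
#' @param seed integer seed.
#'
#' @return data.frame of class `drug_target_db` with columns `drug_id`,
#'   `target_genes` (list column of character vectors) and `nephrotoxic`
#'   (logical).
#' @export
simulate_drug_db <- function(n_toxic = 215L, n_nontoxic = 641L,
                             signal = signal_spec(),
                             gene_universe, markers = NULL,
                             mean_targets = 6, seed = 1L) {
  n_toxic <- assert_count(n_toxic, "n_toxic")
  n_nontoxic <- assert_count(n_nontoxic, "n_nontoxic")
  if (!length(gene_universe)) stop("gene universe is empty", call. = FALSE)
  stopifnot(inherits(signal, "signal_spec"))
  pool <- character(0)
  if (signal$enrichment_strength > 0) {
    pool <- unique(unlist(markers[signal$susceptible_types]))
    pool <- intersect(pool, gene_universe)
    if (!length(pool))
      stop("enrichment_strength > 0 requires nonempty marker sets for the susceptible types",
           call. = FALSE)
  }
  n <- n_toxic + n_nontoxic
  with_seed(seed, {
    toxic <- rep(c(TRUE, FALSE), c(n_toxic, n_nontoxic))
    k <- 1L + stats::rpois(n, max(0, mean_targets - 1))
    k <- pmin(k, length(gene_universe))
    targets <- vector("list", n)
    for (i in seq_len(n)) {
      if (toxic[i] && signal$enrichment_strength > 0) {
        k_m <- round(signal$enrichment_strength * k[i])
        if (signal$enrichment_strength >= 1) k_m <- k[i]
        k_m <- min(k_m, length(pool))
        from_pool <- sample(pool, k_m)
        rest_n <- k[i] - k_m
        rest <- if (rest_n > 0 && signal$enrichment_strength < 1)
          sample(setdiff(gene_universe, from_pool), rest_n)
        else character(0)
        targets[[i]] <- c(from_pool, rest)
      } else {
        targets[[i]] <- sample(gene_universe, k[i])
      }
    }
  })
  db <- data.frame(drug_id = sprintf("D%04d", seq_len(n)),
                   nephrotoxic = toxic, stringsAsFactors = FALSE)
  db$target_genes <- targets
  class(db) <- c("drug_target_db", "data.frame")
  db[c("drug_id", "target_genes", "nephrotoxic")]
}

#' Write / read a drug-target database as CSV
#'
#' Targets are semicolon-joined; `nephrotoxic` is stored as 0/1.
#' @param db a `drug_target_db`.
#' @param path CSV file path.
#' @return `path` (write) or a `drug_target_db` (read).
#' @export
write_drug_db <- function(db, path) {
  out <- data.frame(drug_id = db$drug_id,
                    target_genes = vapply(db$target_genes, paste,
                                          character(1), collapse = ";"),
                    nephrotoxic = as.integer(db$nephrotoxic))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_drug_db
#' @export
read_drug_db <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  db <- data.frame(drug_id = as.character(raw$drug_id),
                   nephrotoxic = as.logical(raw$nephrotoxic),
                   stringsAsFactors = FALSE)
  db$target_genes <- strsplit(raw$target_genes, ";", fixed = TRUE)
  if (anyDuplicated(db$drug_id)) stop("duplicate drug_id in database", call. = FALSE)
  if (any(!lengths(db$target_genes))) stop("drug with empty target set", call. = FALSE)
  class(db) <- c("drug_target_db", "data.frame")
  db[c("drug_id", "target_genes", "nephrotoxic")]
}
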