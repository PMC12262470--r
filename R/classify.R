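#' Build a drugs-by-cell-types feature table
#'
#' Pivots a [aggregate_by_cell_type()] table to wide format: one row per
#' drug, one column per cell type holding the mean logged drug score, plus
#' the nephrotoxicity label. Column order is sorted type names.
#'
#' @param table a `cell_type_score_table`.
#' @param level abstraction level to keep (defaults to the table's level).
#' @return data.frame of class `feature_table`: column `drug_id`, the
#'   feature columns, and logical column `nephrotoxic`.
#' @export
build_feature_table <- function(table, level = NULL) {
  stopifnot(inherits(table, "cell_type_score_table"))
  if (!nrow(table)) stop("empty score table", call. = FALSE)
  if (!is.null(level)) table <- table[table$level == level, , drop = FALSE]
  if (!nrow(table)) stop("no rows at requested level", call. = FALSE)
  types <- sort(unique(table$cell_type))
  drugs <- unique(table$drug_id)
  wide <- matrix(NA_real_, nrow = length(drugs), ncol = length(types),
                 dimnames = list(drugs, types))
  wide[cbind(match(table$drug_id, drugs), match(table$cell_type, types))] <-
    table$mean_score
  if (anyNA(wide)) {
    bad <- drugs[rowSums(is.na(wide)) > 0]
    stop("drug(s) missing cell-type scores: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  labels <- table$nephrotoxic[match(drugs, table$drug_id)]
  out <- data.frame(drug_id = drugs, wide, nephrotoxic = labels,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC of scores for a binary label;
#' invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric predicted scores, higher meaning more likely
#'   positive.
#' @param labels logical (or 0/1) true labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified bootstrap CI for AUROC over pooled out-of-fold scores.
auroc_boot_ci <- function(scores, labels, n_boot = 2000L, seed = 1L,
                          conf = 0.95) {
  labels <- as.logical(labels)
  i1 <- which(labels); i0 <- which(!labels)
  stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    auroc(scores[idx], labels[idx])
  }, numeric(1)))
  a <- (1 - conf) / 2
  stats::quantile(stats, c(a, 1 - a), names = FALSE)
}

# --- model family wrappers -------------------------------------------------
# Each fit_* takes a numeric feature matrix and a 0/1 label vector and
# returns a function mapping new feature rows to positive-class
# probabilities. Default hyperparameters throughout; no tuning.

fit_family <- function(family, x, y, seed) {
  switch(family,
    "regularized_linear" = {
      fit <- with_seed(seed, glmnet::cv.glmnet(x, y, family = "binomial",
                                               nfolds = 5))
      function(newx) as.numeric(stats::predict(fit, newx = newx,
                                               s = "lambda.min",
                                               type = "response"))
    },
    "kernel_svm" = {
      fit <- with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)),
                                        probability = TRUE, kernel = "radial"))
      function(newx) {
        pr <- stats::predict(fit, newx, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    "random_forest" = {
      fit <- with_seed(seed, randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = 500))
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    "extra_trees" = {
      fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                            probability = TRUE, splitrule = "extratrees",
                            num.random.splits = 1, replace = FALSE,
                            sample.fraction = 1, num.trees = 500,
                            num.threads = 1, seed = seed)
      function(newx) stats::predict(fit, data = newx,
                                    num.threads = 1)$predictions[, "1"]
    },
    "gradient_boosting" = {
      fit <- xgb_fit(x, y, seed, eta = 0.1, max_depth = 3, nrounds = 150,
                     subsample = 0.8)
      function(newx) xgb_predict(fit, newx)
    },
    "xgboost" = {
      fit <- xgb_fit(x, y, seed, eta = 0.3, max_depth = 6, nrounds = 100,
                     subsample = 1)
      function(newx) xgb_predict(fit, newx)
    },
    "mlp" = {
      fit <- with_seed(seed, nnet::nnet(x = x, y = y, size = 8, decay = 0.01,
                                        maxit = 300, entropy = TRUE,
                                        trace = FALSE))
      function(newx) as.numeric(stats::predict(fit, newx))
    },
    stop("unknown model family: ", family, call. = FALSE)
  )
}

xgb_fit <- function(x, y, seed, eta, max_depth, nrounds, subsample) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "binary:logistic", eta = eta,
                 max_depth = max_depth, subsample = subsample,
                 nthread = 1, seed = as.integer(seed) %% 100000L)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

xgb_predict <- function(fit, newx) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(newx)))
}

#' Supported classifier families
#' @return character vector of family names accepted by [cross_validate()].
#' @export
model_families <- function() {
  c("regularized_linear", "kernel_svm", "random_forest", "extra_trees",
    "gradient_boosting", "xgboost", "ensemble", "mlp")
}

# Stratified fold assignment; returns integer fold ids per row.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    folds <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Cross-validated evaluation of a nephrotoxicity classifier
#'
#' Stratified k-fold cross-validation of one model family on a
#' [build_feature_table()] table. Out-of-fold positive-class probabilities
#' are pooled and summarized as accuracy, F1, AUROC, sensitivity and
#' specificity (positive class = nephrotoxic, probability threshold 0.5);
#' the AUROC 95% CI comes from a stratified bootstrap (default 2,000
#' resamples) of the pooled out-of-fold scores.
#'
#' @param features a `feature_table`.
#' @param model_family one of [model_families()]; `"ensemble"` soft-votes
#'   (averages probabilities over) the six base families.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds, model fits and the bootstrap.
#' @param n_boot bootstrap resamples for the AUROC CI.
#' @return data.frame of class `eval_report` with one row: model_name,
#'   accuracy, f1, auroc, sensitivity, specificity, auroc_ci_lower,
#'   auroc_ci_upper, plus attribute `oof` holding the pooled out-of-fold
#'   scores and labels.
#' @export
cross_validate <- function(features, model_family = "extra_trees", k = 5L,
                           seed = 1L, n_boot = 2000L) {
  stopifnot(inherits(features, "feature_table"))
  k <- assert_count(k, "k")
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  model_family <- match.arg(model_family, model_families())
  y <- as.integer(features$nephrotoxic)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  x <- as.matrix(features[, setdiff(names(features),
                                    c("drug_id", "nephrotoxic")), drop = FALSE])
  storage.mode(x) <- "double"

  folds <- NULL
  for (attempt in 0:9) {
    f <- stratified_folds(y, k, derive_seed(seed, "folds", attempt))
    ok <- all(vapply(seq_len(k), function(i)
      length(unique(y[f != i])) == 2L && sum(f == i) > 0L, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds)) stop("could not build folds with both classes", call. = FALSE)

  base <- setdiff(model_families(), c("ensemble", "mlp"))
  oof <- rep(NA_real_, length(y))
  for (i in seq_len(k)) {
    tr <- folds != i; te <- folds == i
    fit_seed <- derive_seed(seed, paste0("fit", i))
    if (model_family == "ensemble") {
      probs <- sapply(base, function(fam)
        fit_family(fam, x[tr, , drop = FALSE], y[tr], fit_seed)(x[te, , drop = FALSE]))
      oof[te] <- rowMeans(probs)
    } else {
      pred <- fit_family(model_family, x[tr, , drop = FALSE], y[tr], fit_seed)
      oof[te] <- pred(x[te, , drop = FALSE])
    }
  }

  lab <- y == 1L
  hard <- oof >= 0.5
  tp <- sum(hard & lab); tn <- sum(!hard & !lab)
  fp <- sum(hard & !lab); fn <- sum(!hard & lab)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  ci <- auroc_boot_ci(oof, lab, n_boot = n_boot,
                      seed = derive_seed(seed, "boot"))
  out <- data.frame(
    model_name = model_family,
    accuracy = (tp + tn) / length(y),
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    auroc = auroc(oof, lab),
    sensitivity = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    auroc_ci_lower = ci[1], auroc_ci_upper = ci[2],
    stringsAsFactors = FALSE)
  class(out) <- c("eval_report", "data.frame")
  attr(out, "oof") <- data.frame(score = oof, nephrotoxic = lab)
  attr(out, "ci_method") <- sprintf("stratified bootstrap, %d resamples", n_boot)
  out
}

#' Evaluate several model families at once
#'
#' @param features a `feature_table`.
#' @param families character vector of family names (default all).
#' @inheritParams cross_validate
#' @return `eval_report` data.frame, one row per family, sorted by AUROC
#'   descending.
#' @export
evaluate_models <- function(features, families = model_families(), k = 5L,
                            seed = 1L, n_boot = 2000L) {
  rows <- lapply(families, function(fam)
    cross_validate(features, fam, k = k, seed = seed, n_boot = n_boot))
  out <- do.call(rbind, rows)
  out <- out[order(-out$auroc), ]
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", nrow(x), "model(s), positive class = nephrotoxic\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
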