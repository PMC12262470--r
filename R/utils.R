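# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a global seed; keeps all randomness
# flowing from one integer while decorrelating stages. Result stays < 2^31.
derive_seed <- function(seed, stage, run = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 9973L) * 31L + as.integer(run)
}

assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  ok <- is.numeric(x) && all(x >= lo) & all(if (allow_one) x <= 1 else x < 1)
  if (!all(ok)) stop(sprintf("%s must lie in [%s, %s]", name,
                             if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)"),
                     call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      (positive && x < 1) || (!positive && x < 0))
    stop(sprintf("%s must be a %s integer", name,
                 if (positive) "positive" else "nonnegative"), call. = FALSE)
  invisible(as.integer(x))
}

# Vectorized two-sample Welch t-test over the rows of two matrices.
# Returns t, df and two-sided p per row; rows with undefined variance
# structure (e.g. both groups constant and equal) give NA.
row_welch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) stop("insufficient replicates for t-test", call. = FALSE)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(t = tt, df = df, p = p, mean_x = mx, mean_y = my)
}
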