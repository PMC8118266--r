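#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor quantile pt phyper rnorm runif rlnorm setNames
#' @importFrom utils read.delim write.table
NULL

# Stop with a formatted message; all user-facing failures funnel through here.
abort <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# Pearson correlation that returns NA (instead of erroring or warning) when
# either vector is constant; undefined correlations are treated as filter
# failures throughout the pipeline.
safe_cor <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}

#' Bootstrap consensus configuration
#'
#' Settings for the resampling-with-replacement consensus used by the
#' correlation-based filters: a record passes only if its statistic satisfies
#' the threshold in at least `min_pass_frac` of `n_resamples` resamples of the
#' samples. One shared stream of resample index sets per filtering stage makes
#' results reproducible and comparable across records. `n_resamples = 0`
#' disables the consensus (the full-data test alone decides).
#'
#' @param n_resamples Number of resamples with replacement (default 1000 for
#'   the miRNA-target stage; the pair stage conventionally uses 100).
#' @param min_pass_frac Minimum fraction of resamples in which the threshold
#'   must hold, in (0, 1].
#' @param seed Integer seed for the shared resampling stream.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(n_resamples = 1000L, min_pass_frac = 0.99,
                             seed = 1L) {
  if (!is_count(n_resamples)) abort("n_resamples must be a non-negative integer")
  if (!is.numeric(min_pass_frac) || min_pass_frac <= 0 || min_pass_frac > 1)
    abort("min_pass_frac must be in (0, 1]")
  structure(list(n_resamples = as.integer(n_resamples),
                 min_pass_frac = min_pass_frac,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

# Shared resample-index matrix (n_resamples x n_samples), drawn once per stage.
resample_indices <- function(consensus, n_samples) {
  if (consensus$n_resamples == 0L) return(NULL)
  withr_seed <- consensus$seed %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(withr_seed)
  matrix(sample.int(n_samples, consensus$n_resamples * n_samples, replace = TRUE),
         nrow = consensus$n_resamples)
}

# Row-wise Pearson correlation between matched rows of X and Y (same dims).
# Rows with zero variance give NA.
rowwise_cor <- function(X, Y) {
  n <- ncol(X)
  mx <- rowMeans(X); my <- rowMeans(Y)
  cxy <- rowMeans(X * Y) - mx * my
  vx <- rowMeans(X * X) - mx * mx
  vy <- rowMeans(Y * Y) - my * my
  # guard tiny negative values from roundoff
  vx[vx < 0] <- 0; vy[vy < 0] <- 0
  den <- sqrt(vx * vy)
  out <- ifelse(den > 0, cxy / den, NA_real_)
  clip <- which(abs(out) > 1)
  out[clip] <- sign(out[clip])
  out
}

# Consensus pass fractions for matched rows of X and Y: for each resample
# (rows of idx), recompute the row-wise correlation and compare against
# `threshold` with direction `lower` (TRUE: pass if cor < threshold;
# FALSE: pass if cor > threshold). NA correlations (zero-variance resamples)
# count as failures. Returns the pass fraction per row.
consensus_pass_fraction <- function(X, Y, idx, threshold, lower = TRUE) {
  if (is.null(idx)) return(rep(1, nrow(X)))
  B <- nrow(idx)
  pass <- numeric(nrow(X))
  for (b in seq_len(B)) {
    r <- rowwise_cor(X[, idx[b, ], drop = FALSE], Y[, idx[b, ], drop = FALSE])
    ok <- if (lower) !is.na(r) & r < threshold else !is.na(r) & r > threshold
    pass <- pass + ok
  }
  pass / B
}

# Derive a bounded substream seed from a master seed and a stage label.
stage_seed <- function(seed, stage) {
  offs <- c(synth = 11L, mirna_corr = 23L, er_filter = 37L, pair = 53L)
  if (!stage %in% names(offs)) abort("unknown stage '%s'", stage)
  as.integer((as.numeric(seed) * 101 + offs[[stage]]) %% 2147483647)
}
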