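# Internal numeric helpers shared across stages.

# Row-wise means and Bessel-corrected variances over a column subset.
.row_stats <- function(mat, idx) {
  n <- length(idx)
  sub <- mat[, idx, drop = FALSE]
  m <- rowMeans(sub)
  v <- rowSums((sub - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}

# Vectorized Cohen's d over rows of `mat` between column groups `ia` and `ib`.
# Genes with zero pooled SD get NA.
.row_cohens_d <- function(mat, ia, ib) {
  a <- .row_stats(mat, ia)
  b <- .row_stats(mat, ib)
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
  d <- (a$mean - b$mean) / sqrt(sp2)
  d[sp2 <= 0] <- NA_real_
  d
}

# Pearson r and the two-sided t-based p-value, closed form.
# Matches stats::cor.test for complete finite input (oracle-checked in tests).
.pearson_rp <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r)) return(c(r = NA_real_, p = NA_real_))
  r2 <- min(r^2, 1)
  if (1 - r2 < .Machine$double.eps) {
    p <- 0
  } else {
    t <- abs(r) * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  }
  c(r = r, p = p)
}

# Empirical p-value from a permutation null.
# Default is the plain frequency b/B; plus_one gives (b+1)/(B+1).
.empirical_p <- function(n_extreme, B, plus_one = FALSE) {
  if (plus_one) (n_extreme + 1) / (B + 1) else n_extreme / B
}

# Deterministic derivation of per-stage seeds from one pipeline seed.
# Kept below 2^31 so it is a valid R integer seed.
.derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 2654435 + h * 97 + 13) %% 2147483647L)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
  }
}
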