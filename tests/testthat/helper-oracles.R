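# Independent brute-force oracles used to verify the package's statistics.
# These deliberately re-derive each quantity from first principles and never
# share code with the implementation under test.

oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  ssa <- sum((a - sum(a) / na)^2)
  ssb <- sum((b - sum(b) / nb)^2)
  sp <- sqrt((ssa + ssb) / (na + nb - 2))
  (sum(a) / na - sum(b) / nb) / sp
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

# Exact MWU p by enumerating every assignment of the pooled values into the
# two groups (requires no ties).
oracle_mwu_exact <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">"))
  u_obs <- u_of(a, b)
  combos <- combn(length(pool), na)
  us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Exact two-sided Fisher p: sum of hypergeometric probabilities of tables
# (with the observed margins) no more likely than the observed one.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# DTW cost by recursive enumeration over all monotone paths (memoization-free
# for tiny grids, memoized beyond).
oracle_dtw_cost <- function(x, y, memo = FALSE) {
  n <- length(x); m <- length(y)
  cost <- outer(x, y, function(a, b) (a - b)^2)
  if (!memo) {
    rec <- function(i, j) {
      if (i == 1 && j == 1) return(cost[1, 1])
      best <- Inf
      if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
      if (i > 1) best <- min(best, rec(i - 1, j))
      if (j > 1) best <- min(best, rec(i, j - 1))
      best + cost[i, j]
    }
    return(rec(n, m))
  }
  memo_tab <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost[1, 1])
    if (!is.na(memo_tab[i, j])) return(memo_tab[i, j])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    memo_tab[i, j] <<- best + cost[i, j]
    memo_tab[i, j]
  }
  rec(n, m)
}

# Minimal on-disk fixtures -------------------------------------------------

write_tsv_matrix <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_expression_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\ts1\ts2",
               "g1\t1.5\t2.5",
               "g2\t0\t-1.25",
               "g3\t3\t4"), path)
  path
}

tiny_sample_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample_id\tdataset_id\ttissue\tgroup",
               "s1\tC1\tliver\tCR",
               "s2\tC1\tliver\tCR",
               "s3\tC1\tliver\tAL",
               "s4\tC1\tliver\tAL"), path)
  path
}
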