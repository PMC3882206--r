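# Diet-affected gene detection: Welch t, Mann-Whitney U, permutation FDR,
# Fisher enrichment and expression-level-stratified overlap checks.

#' Welch's two-sample t-test (unequal variances)
#'
#' Direct evaluation of the Welch statistic and Welch-Satterthwaite degrees
#' of freedom with the two-sided p-value from the t distribution. The same
#' closed form drives the vectorized permutation machinery, so its agreement
#' with `stats::t.test` is oracle-checked in the test suite.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2; at least
#'   one group must have positive variance.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(values_a, values_b) {
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 2 || n_b < 2) stop("each group needs >= 2 values", call. = FALSE)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va <= 0 && vb <= 0) stop("both variances zero", call. = FALSE)
  se2a <- va / n_a; se2b <- vb / n_b
  t <- (mean(values_a) - mean(values_b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (n_a - 1) + se2b^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# Vectorized Welch p-values over rows between column groups ia, ib.
.row_welch_p <- function(mat, ia, ib) {
  a <- .row_stats(mat, ia); b <- .row_stats(mat, ib)
  se2a <- a$var / a$n; se2b <- b$var / b$n
  denom <- se2a + se2b
  t <- (a$mean - b$mean) / sqrt(denom)
  df <- denom^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[denom <= 0] <- NA_real_
  p
}

#' Mann-Whitney U test
#'
#' Two-sided test via `stats::wilcox.test`: exact enumeration when
#' `n_a + n_b <= 12` and there are no ties, otherwise the midrank normal
#' approximation with tie-corrected variance (no continuity correction).
#' `U` counts pairs where an `a` value exceeds a `b` value (midranks for
#' ties).
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return list with `U`, `p`.
#' @export
mwu <- function(values_a, values_b) {
  if (length(values_a) < 1 || length(values_b) < 1) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && (length(values_a) + length(values_b) <= 12)
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

# Vectorized MWU normal-approximation p-values. Ranks depend only on the data,
# not the labels, so the rank matrix and tie corrections are precomputed once
# and reused across label permutations.
.row_mwu_prepare <- function(mat) {
  ranks <- t(apply(mat, 1, rank))
  n <- ncol(mat)
  tie_term <- apply(mat, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  list(ranks = ranks, n = n, tie_term = tie_term)
}

.row_mwu_p <- function(prep, ia) {
  n_a <- length(ia); n <- prep$n; n_b <- n - n_a
  U <- rowSums(prep$ranks[, ia, drop = FALSE]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  sigma2 <- n_a * n_b / 12 * ((n + 1) - prep$tie_term / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p[sigma2 <= 0] <- NA_real_
  p
}

#' Permutation-FDR detection of differentially expressed genes
#'
#' Observed per-gene p-values (Welch t or MWU) are compared with `B`
#' sample-label permutations. For every candidate cutoff (the sorted distinct
#' observed p-values), the estimated FDR is the permutation summary (median
#' by default) of the permuted significant count divided by the observed
#' significant count; the chosen cutoff is the largest candidate with
#' estimated FDR below `target_fdr` and the affected genes are those at or
#' below it. The permutation paths use vectorized test statistics; genes
#' with undefined statistics (zero variance) are dropped from the curve.
#'
#' @param matrix an [expression_matrix()].
#' @param samples `SampleTable` covering the matrix columns.
#' @param groups the two group labels contrasted.
#' @param test `"welch_t"` or `"mwu"`.
#' @param target_fdr target false discovery rate (default 0.10).
#' @param B number of label permutations (>= 100, default 1000).
#' @param seed RNG seed.
#' @param summary permutation count summary: `"median"` (default) or `"mean"`.
#' @return object of class `FdrCurve`: list with `curve` (data.frame of
#'   `cutoff`, `n_observed`, `perm_count`, `fdr`), `chosen_cutoff` (`NA` when
#'   no cutoff meets the target), `affected`, `p_observed`, `direction`,
#'   `test`, `target_fdr`, `B`.
#' @export
permutation_fdr_genes <- function(matrix, samples, groups = c("CR", "AL"),
                                  test = c("welch_t", "mwu"), target_fdr = 0.10,
                                  B = 1000, seed = 1,
                                  summary = c("median", "mean")) {
  test <- match.arg(test)
  summary <- match.arg(summary)
  if (B < 100) stop("insufficient permutations: B must be >= 100", call. = FALSE)
  .stop_if_not_scalar_prob(target_fdr, "target_fdr")
  ia <- which(colnames(matrix) %in% samples$sample_id[samples$group == groups[1]])
  ib <- which(colnames(matrix) %in% samples$sample_id[samples$group == groups[2]])
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples", call. = FALSE)
  vals <- unclass(matrix)[, c(ia, ib), drop = FALSE]
  n_a <- length(ia); n <- ncol(vals)
  prep <- if (test == "mwu") .row_mwu_prepare(vals)
  p_of <- function(cols_a) {
    if (test == "welch_t") .row_welch_p(vals, cols_a, setdiff(seq_len(n), cols_a))
    else .row_mwu_p(prep, cols_a)
  }
  p_obs <- p_of(seq_len(n_a))
  direction <- sign(rowMeans(vals[, seq_len(n_a), drop = FALSE]) -
                      rowMeans(vals[, (n_a + 1):n, drop = FALSE]))
  ok <- !is.na(p_obs)
  p_use <- p_obs[ok]
  cutoffs <- sort(unique(p_use))
  n_obs_at <- findInterval(cutoffs, sort(p_use))
  perm_counts <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      pp <- p_of(sample.int(n, n_a))
      findInterval(cutoffs, sort(pp[!is.na(pp)]))
    }, numeric(length(cutoffs)))
  })
  if (length(cutoffs) == 1) perm_counts <- base::matrix(perm_counts, nrow = 1)
  summ <- if (summary == "median") apply(perm_counts, 1, stats::median)
          else rowMeans(perm_counts)
  fdr <- summ / n_obs_at
  pass <- which(fdr < target_fdr)
  chosen <- if (length(pass)) cutoffs[max(pass)] else NA_real_
  affected <- if (is.na(chosen)) character(0) else names(p_use)[p_use <= chosen]
  structure(list(curve = data.frame(cutoff = cutoffs, n_observed = n_obs_at,
                                    perm_count = summ, fdr = fdr),
                 chosen_cutoff = chosen, affected = sort(affected),
                 p_observed = p_obs, direction = direction,
                 test = test, target_fdr = target_fdr, B = B, summary = summary),
            class = "FdrCurve")
}

#' @export
print.FdrCurve <- function(x, ...) {
  cat(sprintf("Permutation FDR (%s, B = %d, target %.0f%%): ", x$test, x$B,
              100 * x$target_fdr))
  if (is.na(x$chosen_cutoff)) {
    cat("no cutoff meets the target; 0 affected genes\n")
  } else {
    cat(sprintf("cutoff p <= %.3g, %d affected genes\n",
                x$chosen_cutoff, length(x$affected)))
  }
  invisible(x)
}

#' Fisher's exact enrichment of one gene set in another
#'
#' Builds the 2x2 table of membership in `set_a` vs `set_b` over `universe`
#' and returns the exact two-sided hypergeometric p-value together with the
#' sample odds ratio `(n11 * n22) / (n12 * n21)`.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `odds_ratio`, `p`, `table`.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- base::matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                        sum(!in_a & in_b), sum(!in_a & !in_b)), nrow = 2,
                      dimnames = list(c("in_b", "not_b"), c("in_a", "not_a")))
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  list(odds_ratio = or, p = p, table = tab)
}

#' Expression-level-stratified enrichment
#'
#' Repeats [fisher_enrichment()] inside expression-level strata to check
#' that an overlap between two gene lists is not driven by the
#' expression-level ascertainment bias of differential-expression tests.
#' Strata must partition the universe. A stratum whose 2x2 table has a zero
#' margin is reported untestable.
#'
#' @param affected,reference character vectors of gene ids.
#' @param universe all genes considered.
#' @param strata named list of gene-id vectors partitioning `universe`
#'   (e.g. expression-level quantile bins).
#' @return `data.frame` with one row per stratum: `stratum`, `n`,
#'   `odds_ratio`, `p`, `testable`.
#' @export
stratified_overlap <- function(affected, reference, universe, strata) {
  flat <- unlist(strata, use.names = FALSE)
  if (length(flat) != length(universe) || !setequal(flat, universe) ||
      anyDuplicated(flat)) {
    stop("strata must partition the universe", call. = FALSE)
  }
  rows <- lapply(names(strata), function(nm) {
    uni <- strata[[nm]]
    a <- intersect(affected, uni); b <- intersect(reference, uni)
    margins_ok <- length(uni) > 0 &&
      length(a) > 0 && length(a) < length(uni) &&
      length(b) > 0 && length(b) < length(uni)
    if (!margins_ok) {
      return(data.frame(stratum = nm, n = length(uni), odds_ratio = NA_real_,
                        p = NA_real_, testable = FALSE))
    }
    fe <- fisher_enrichment(a, b, uni)
    data.frame(stratum = nm, n = length(uni), odds_ratio = fe$odds_ratio,
               p = fe$p, testable = TRUE)
  })
  do.call(rbind, rows)
}

#' Expression-level quantile strata
#'
#' Convenience helper splitting genes into equal-count strata by mean
#' expression, for use with [stratified_overlap()].
#'
#' @param matrix an [expression_matrix()].
#' @param n_strata number of strata.
#' @return named list of gene-id vectors.
#' @export
expression_strata <- function(matrix, n_strata = 4) {
  m <- rowMeans(unclass(matrix))
  ord <- order(m)
  bin <- integer(length(m))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_strata))
  split(rownames(matrix), paste0("q", bin))
}
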