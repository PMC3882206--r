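#' Cohen's d with classical pooled variance
#'
#' `d = (mean_a - mean_b) / s_pooled`, with
#' `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)` using
#' Bessel-corrected sample variances. A zero pooled SD yields `NA` so that
#' callers can exclude (and count) such genes.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return Cohen's d (scalar), or `NA` if the pooled SD is zero.
#' @export
cohens_d <- function(values_a, values_b) {
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 2 || n_b < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((n_a - 1) * stats::var(values_a) + (n_b - 1) * stats::var(values_b)) /
    (n_a + n_b - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

#' Per-gene Cohen's d for one labeled contrast
#'
#' Computes Cohen's d for every gene between the samples of `group_a` and
#' `group_b`. Genes with zero pooled SD are excluded and counted in
#' `n_zero_sd`.
#'
#' @param matrix an [expression_matrix()] (or numeric matrix with dimnames).
#' @param samples a `SampleTable` covering the matrix columns.
#' @param group_a,group_b group labels present in `samples$group`.
#' @param label optional contrast label (default `"group_a-vs-group_b"`).
#' @return object of class `ContrastEffect`: list with `label`, `d`
#'   (named numeric), `n_a`, `n_b`, `dataset_id`, `tissue`, `n_zero_sd`.
#' @export
contrast_effects <- function(matrix, samples, group_a, group_b, label = NULL) {
  ia <- which(colnames(matrix) %in% samples$sample_id[samples$group == group_a])
  ib <- which(colnames(matrix) %in% samples$sample_id[samples$group == group_b])
  if (length(ia) == 0) stop("unknown group: ", group_a, call. = FALSE)
  if (length(ib) == 0) stop("unknown group: ", group_b, call. = FALSE)
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples", call. = FALSE)
  d <- .row_cohens_d(unclass(matrix), ia, ib)
  names(d) <- rownames(matrix)
  excluded <- is.na(d)
  structure(list(label = if (is.null(label)) paste0(group_a, "-vs-", group_b) else label,
                 d = d[!excluded], n_a = length(ia), n_b = length(ib),
                 dataset_id = samples$dataset_id[1], tissue = samples$tissue[1],
                 n_zero_sd = sum(excluded)),
            class = "ContrastEffect")
}

#' @export
print.ContrastEffect <- function(x, ...) {
  cat(sprintf("ContrastEffect '%s' (%s, %s): %d genes, n = %d/%d, %d zero-SD excluded\n",
              x$label, x$dataset_id, x$tissue, length(x$d), x$n_a, x$n_b, x$n_zero_sd))
  invisible(x)
}

.effect_vector <- function(x) {
  if (inherits(x, "ContrastEffect")) x$d
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a ContrastEffect or a named numeric vector", call. = FALSE)
}

#' Pearson comparison of two effect-size vectors
#'
#' Correlates the two per-gene effect vectors over their shared genes and
#' tests `r != 0` with the two-sided t-based correlation test.
#'
#' @param x,y `ContrastEffect` objects (or named numeric vectors).
#' @param pair_label optional label such as `"C1::S2"`.
#' @return object of class `ComparisonResult`: list with `pair_label`,
#'   `tissue`, `r`, `p`, `n_genes`.
#' @export
compare_contrasts <- function(x, y, pair_label = NULL) {
  dx <- .effect_vector(x); dy <- .effect_vector(y)
  shared <- intersect(names(dx), names(dy))
  if (length(shared) < 3) stop("need >= 3 shared genes", call. = FALSE)
  ct <- stats::cor.test(dx[shared], dy[shared], method = "pearson")
  if (is.null(pair_label)) {
    pair_label <- paste0(if (inherits(x, "ContrastEffect")) x$label else "x", "::",
                         if (inherits(y, "ContrastEffect")) y$label else "y")
  }
  structure(list(pair_label = pair_label,
                 tissue = if (inherits(x, "ContrastEffect")) x$tissue else NA_character_,
                 r = unname(ct$estimate), p = ct$p.value, n_genes = length(shared)),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("Comparison %s: r = %.3f, p = %.3g over %d shared genes\n",
              x$pair_label, x$r, x$p, x$n_genes))
  invisible(x)
}

#' Equal-count binned scatter of two effect-size vectors
#'
#' Shared genes are binned by equal-count quantiles of `x`; per bin the means
#' of both axes, the variance of `y` and the count are returned (the summary
#' behind effect-size scatter plots).
#'
#' @param x,y `ContrastEffect` objects (or named numeric vectors).
#' @param n_bins number of bins (>= 2, <= number of shared genes).
#' @return `data.frame` with columns `bin`, `n`, `mean_x`, `mean_y`, `var_y`.
#' @export
binned_scatter <- function(x, y, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  dx <- .effect_vector(x); dy <- .effect_vector(y)
  shared <- intersect(names(dx), names(dy))
  if (length(shared) < n_bins) stop("need >= n_bins shared genes", call. = FALSE)
  xv <- dx[shared]; yv <- dy[shared]
  ord <- order(xv)
  bin <- integer(length(xv))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  out <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    mean_x = vapply(seq_len(n_bins), function(b) mean(xv[bin == b]), numeric(1)),
    mean_y = vapply(seq_len(n_bins), function(b) mean(yv[bin == b]), numeric(1)),
    var_y = vapply(seq_len(n_bins), function(b) stats::var(yv[bin == b]), numeric(1)))
  out
}

#' One-sided binomial test for an excess of positive significant comparisons
#'
#' Counts comparisons with `r > 0` and `p < 0.05` and returns the upper-tail
#' exact binomial p-value at success probability `null_success_prob`
#' (default 0.025 = P(r > 0 and two-sided p < 0.05) under independence;
#' use 0.5 for a sign-only analysis).
#'
#' @param comparisons list of `ComparisonResult` objects.
#' @param null_success_prob null per-comparison success probability.
#' @return one-sided p-value.
#' @export
binomial_trend_test <- function(comparisons, null_success_prob = 0.025) {
  .stop_if_not_scalar_prob(null_success_prob, "null_success_prob")
  if (length(comparisons) < 1) stop("need >= 1 comparison", call. = FALSE)
  k <- sum(vapply(comparisons, function(cm) cm$r > 0 && cm$p < 0.05, logical(1)))
  stats::binom.test(k, length(comparisons), p = null_success_prob,
                    alternative = "greater")$p.value
}

# Precompute, per dataset, the value matrix and the column indices of the two
# contrast groups (only those samples take part in label shuffles).
.prepare_meta_dataset <- function(ds) {
  stopifnot(all(c("matrix", "samples", "groups") %in% names(ds)))
  ia <- which(colnames(ds$matrix) %in% ds$samples$sample_id[ds$samples$group == ds$groups[1]])
  ib <- which(colnames(ds$matrix) %in% ds$samples$sample_id[ds$samples$group == ds$groups[2]])
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples", call. = FALSE)
  list(values = unclass(ds$matrix)[, c(ia, ib), drop = FALSE],
       genes = rownames(ds$matrix), n_a = length(ia), n = length(ia) + length(ib))
}

#' Label-permutation meta-test of positively correlated comparisons
#'
#' The observed statistic `C_obs` is the number of dataset pairs whose
#' effect-size vectors correlate positively and significantly (`r > 0`,
#' `p < 0.05`). For each of `B` permutation rounds the two-group labels are
#' shuffled independently within every dataset (group sizes preserved),
#' all effect sizes and pair correlations are recomputed, and the
#' positive-significant count is recorded. Then
#' `p_perm = #{null count >= C_obs} / B` and
#' `fdr_perm = median(null counts) / C_obs` (undefined when `C_obs = 0`).
#' An exact one-sided binomial p-value is attached via
#' [binomial_trend_test()]. Cross-species gene spaces must be mapped to a
#' shared namespace upstream (see [map_orthologs()]); pairs are correlated
#' over shared gene ids.
#'
#' @param datasets list; each element a list with `matrix`, `samples` and
#'   `groups = c(group_a, group_b)`.
#' @param pairs list of length-2 integer vectors indexing `datasets`.
#' @param B number of permutation rounds (default 100000).
#' @param exhaustive enumerate every distinct within-dataset label
#'   assignment instead of sampling (`B` is then the product of per-dataset
#'   assignment counts; only feasible for tiny designs).
#' @param seed RNG seed.
#' @param plus_one report `(b+1)/(B+1)` instead of `b/B`.
#' @param null_success_prob passed to [binomial_trend_test()].
#' @return object of class `MetaResult`: `C_obs`, `n_pairs`, `B`,
#'   `null_counts`, `p_perm`, `fdr_perm`, `p_binomial`, `comparisons`
#'   (data.frame of per-pair `r`, `p`, `n_genes`).
#' @export
permutation_meta_test <- function(datasets, pairs, B = 100000, seed = 1,
                                  exhaustive = FALSE, plus_one = FALSE,
                                  null_success_prob = 0.025) {
  prep <- lapply(datasets, .prepare_meta_dataset)
  pair_idx <- lapply(pairs, function(p) {
    p <- as.integer(p)
    stopifnot(length(p) == 2)
    shared <- intersect(prep[[p[1]]]$genes, prep[[p[2]]]$genes)
    if (length(shared) < 3) stop("pair shares < 3 genes", call. = FALSE)
    list(i = p[1], j = p[2],
         gi = match(shared, prep[[p[1]]]$genes),
         gj = match(shared, prep[[p[2]]]$genes))
  })
  count_positive <- function(effects) {
    rp <- vapply(pair_idx, function(pp) {
      .pearson_rp(effects[[pp$i]][pp$gi], effects[[pp$j]][pp$gj])
    }, numeric(2))
    sum(rp[1, ] > 0 & rp[2, ] < 0.05, na.rm = TRUE)
  }
  real_effects <- lapply(prep, function(d) .row_cohens_d(d$values, seq_len(d$n_a),
                                                         (d$n_a + 1):d$n))
  obs_rp <- t(vapply(pair_idx, function(pp) {
    .pearson_rp(real_effects[[pp$i]][pp$gi], real_effects[[pp$j]][pp$gj])
  }, numeric(2)))
  C_obs <- sum(obs_rp[, 1] > 0 & obs_rp[, 2] < 0.05, na.rm = TRUE)

  null_counts <- if (exhaustive) {
    # every distinct assignment of group-A columns per dataset, crossed
    choices <- lapply(prep, function(d) {
      asplit(utils::combn(d$n, d$n_a), 2)
    })
    counts <- vapply(choices, length, integer(1))
    if (prod(counts) > 1e6) stop("exhaustive enumeration infeasible", call. = FALSE)
    grid <- expand.grid(lapply(counts, seq_len))
    B <- nrow(grid)
    vapply(seq_len(B), function(r) {
      eff <- lapply(seq_along(prep), function(k) {
        ia <- choices[[k]][[grid[r, k]]]
        .row_cohens_d(prep[[k]]$values, ia, setdiff(seq_len(prep[[k]]$n), ia))
      })
      count_positive(eff)
    }, numeric(1))
  } else {
    .with_seed(seed, {
      vapply(seq_len(B), function(b) {
        eff <- lapply(prep, function(d) {
          perm <- sample.int(d$n)
          .row_cohens_d(d$values, perm[seq_len(d$n_a)], perm[(d$n_a + 1):d$n])
        })
        count_positive(eff)
      }, numeric(1))
    })
  }
  p_perm <- .empirical_p(sum(null_counts >= C_obs), B, plus_one)
  fdr_perm <- if (C_obs > 0) stats::median(null_counts) / C_obs else NA_real_
  comparisons <- lapply(seq_along(pair_idx), function(k) {
    structure(list(pair_label = paste0("D", pair_idx[[k]]$i, "::D", pair_idx[[k]]$j),
                   tissue = NA_character_, r = obs_rp[k, 1], p = obs_rp[k, 2],
                   n_genes = length(pair_idx[[k]]$gi)),
              class = "ComparisonResult")
  })
  structure(list(C_obs = C_obs, n_pairs = length(pairs), B = B,
                 null_counts = null_counts, p_perm = p_perm, fdr_perm = fdr_perm,
                 p_binomial = binomial_trend_test(comparisons, null_success_prob),
                 comparisons = data.frame(
                   pair = vapply(comparisons, `[[`, character(1), "pair_label"),
                   r = obs_rp[, 1], p = obs_rp[, 2],
                   n_genes = vapply(pair_idx, function(pp) length(pp$gi), integer(1)))),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("Permutation meta-test: %d of %d comparisons positive-significant\n",
              x$C_obs, x$n_pairs))
  pp <- if (x$p_perm == 0) sprintf("< %g", 1 / x$B) else sprintf("%g", x$p_perm)
  cat(sprintf("  p_perm = %s (B = %d), FDR = %s, binomial p = %.3g\n",
              pp, x$B, ifelse(is.na(x$fdr_perm), "undefined", sprintf("%.3g", x$fdr_perm)),
              x$p_binomial))
  invisible(x)
}
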