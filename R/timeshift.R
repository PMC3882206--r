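# Cross-species age alignment: conception-age scaling, correlation
# filtering, dynamic time warping, and bootstrap corresponding-age queries.

#' Convert postnatal ages to conception ages
#'
#' Adds the species' gestation length (e.g. 280 days for human, 19 for
#' mouse) so that developmental time series of species with very different
#' prenatal spans share a common origin.
#'
#' @param ages postnatal ages in days (>= 0).
#' @param offset_days gestation length in days.
#' @return conception ages in days.
#' @export
to_conception_age <- function(ages, offset_days) {
  if (any(ages < 0)) stop("negative age", call. = FALSE)
  ages + offset_days
}

#' Retain genes whose trajectories agree across species
#'
#' Correlates, per gene, the two trajectories evaluated on equal-length
#' grids of relative positions within each species' age range, and retains
#' genes with Pearson `r` strictly greater than `threshold`. Genes with a
#' constant (degenerate) trajectory in either species are excluded and
#' counted.
#'
#' @param traj_ref,traj_query numeric matrices, genes x grid points (same
#'   number of columns, shared rownames).
#' @param threshold retention threshold on `r` (default 0.5, strict).
#' @return character vector of retained gene ids; attribute `n_degenerate`
#'   counts constant-trajectory exclusions.
#' @export
filter_by_cross_species_correlation <- function(traj_ref, traj_query,
                                                threshold = 0.5) {
  if (ncol(traj_ref) != ncol(traj_query)) {
    stop("trajectories must share the grid length", call. = FALSE)
  }
  genes <- intersect(rownames(traj_ref), rownames(traj_query))
  sa <- apply(traj_ref[genes, , drop = FALSE], 1, stats::sd)
  sb <- apply(traj_query[genes, , drop = FALSE], 1, stats::sd)
  degenerate <- sa < 1e-12 | sb < 1e-12
  r <- rep(NA_real_, length(genes))
  ok <- !degenerate
  r[ok] <- vapply(which(ok), function(i) {
    stats::cor(traj_ref[genes[i], ], traj_query[genes[i], ])
  }, numeric(1))
  retained <- genes[ok & r > threshold]
  structure(retained, n_degenerate = sum(degenerate))
}

#' Dynamic time warping alignment of two expression curves
#'
#' Standard dynamic-programming DTW with the symmetric step pattern
#' (diagonal / vertical / horizontal moves) and squared-difference local
#' cost, aligning a reference-species curve to a query-species curve. Both
#' curves should be standardized (zero mean, unit variance) so that the
#' alignment reflects shape, not level; `standardize = TRUE` (default) does
#' this internally. When age grids are supplied the path is also returned
#' as matched age pairs.
#'
#' @param curve_ref,curve_query numeric vectors of interpolated expression
#'   values on dense (log conception-)age grids.
#' @param grid_ref,grid_query optional age grids matching the two curves.
#' @param standardize standardize the curves internally (default `TRUE`).
#' @param min_grid minimum grid length (default 50; lower it explicitly for
#'   small didactic examples).
#' @return object of class `WarpPath`: list with `cost`, `index_ref`,
#'   `index_query` and (when grids are given) `age_ref`, `age_query`.
#' @export
dtw_align <- function(curve_ref, curve_query, grid_ref = NULL, grid_query = NULL,
                      standardize = TRUE, min_grid = 50) {
  if (length(curve_ref) < min_grid || length(curve_query) < min_grid) {
    stop("grid too sparse: need >= ", min_grid, " points per curve", call. = FALSE)
  }
  std <- function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) stop("constant curve cannot be aligned", call. = FALSE)
    (v - mean(v)) / s
  }
  if (standardize) {
    curve_ref <- std(curve_ref); curve_query <- std(curve_query)
  }
  res <- .dtw_core(as.numeric(curve_ref), as.numeric(curve_query))
  out <- list(cost = res$cost, index_ref = res$index_ref,
              index_query = res$index_query)
  if (!is.null(grid_ref) && !is.null(grid_query)) {
    out$age_ref <- grid_ref[res$index_ref]
    out$age_query <- grid_query[res$index_query]
  }
  structure(out, class = "WarpPath")
}

#' @export
print.WarpPath <- function(x, ...) {
  cat(sprintf("WarpPath: %d steps, cost %.4g\n", length(x$index_ref), x$cost))
  invisible(x)
}

# Per-gene warp function: for each query grid index, the mean matched
# reference log-age; interpolated at an arbitrary query log-age.
.warp_lookup <- function(path, lref, lquery, lq_target) {
  mean_ref <- tapply(lref[path$index_ref], path$index_query, mean)
  lq_grid <- lquery[as.integer(names(mean_ref))]
  stats::approx(lq_grid, as.numeric(mean_ref), xout = lq_target, rule = 2)$y
}

#' Reference-species age corresponding to a query-species age
#'
#' Per shared gene, fits a smoothing spline (df = 3) of expression on log
#' conception age for each species, evaluates both on dense log-age grids
#' spanning the observed ranges, retains genes whose trajectories correlate
#' with `r > min_corr`, aligns each retained gene by DTW, and reads off the
#' reference log-age matched to the query age. The point estimate is the
#' mean across genes on the log conception-age scale; the 95% CI is a
#' percentile bootstrap over genes (sampling with replacement). Ages are
#' reported on the reference species' postnatal scale (days).
#'
#' @param data_ref,data_query per-species datasets: lists with `matrix` and
#'   `samples` (ages in postnatal days).
#' @param query_age query-species postnatal age in days (e.g. 600).
#' @param offset_ref,offset_query gestation lengths in days (defaults
#'   280 / 19).
#' @param min_corr trajectory correlation filter threshold (default 0.5).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param n_grid grid points per species (default 100).
#' @param df spline degrees of freedom (default 3).
#' @param min_genes minimum retained genes for a reportable CI (default 10).
#' @return object of class `TimeShiftEstimate`: `estimate` (postnatal days),
#'   `ci` (2-vector), `per_gene_ages`, `n_genes`, `shift_curve`
#'   (`data.frame` of query log-age vs mean matched reference log-age),
#'   `query_age`, `min_corr`, `n_boot`.
#' @export
corresponding_age <- function(data_ref, data_query, query_age,
                              offset_ref = 280, offset_query = 19,
                              min_corr = 0.5, n_boot = 1000, seed = 1,
                              n_grid = 100, df = 3, min_genes = 10) {
  fit_grid <- function(data, offset) {
    ages <- data$samples$age
    keep <- !is.na(ages)
    lconc <- log(to_conception_age(ages[keep], offset))
    cols <- match(data$samples$sample_id[keep], colnames(data$matrix))
    grid <- seq(min(lconc), max(lconc), length.out = n_grid)
    vals <- unclass(data$matrix)[, cols, drop = FALSE]
    curves <- t(apply(vals, 1, function(v) {
      if (stats::sd(v) < 1e-12) return(rep(v[1], n_grid))
      stats::predict(stats::smooth.spline(lconc, v, df = df, cv = FALSE), grid)$y
    }))
    rownames(curves) <- rownames(data$matrix)
    list(curves = curves, grid = grid)
  }
  ref <- fit_grid(data_ref, offset_ref)
  query <- fit_grid(data_query, offset_query)
  retained <- filter_by_cross_species_correlation(ref$curves, query$curves,
                                                  threshold = min_corr)
  if (length(retained) < min_genes) {
    stop("insufficient genes: only ", length(retained),
         " pass the correlation filter (need >= ", min_genes, ")", call. = FALSE)
  }
  lq_target <- log(to_conception_age(query_age, offset_query))
  if (lq_target < min(query$grid) - 1e-9 || lq_target > max(query$grid) + 1e-9) {
    stop("query age outside the observed query-species range", call. = FALSE)
  }
  per_gene_log <- numeric(length(retained))
  shift_mat <- matrix(NA_real_, length(retained), n_grid)
  for (i in seq_along(retained)) {
    g <- retained[i]
    path <- dtw_align(ref$curves[g, ], query$curves[g, ], min_grid = min(n_grid, 50))
    per_gene_log[i] <- .warp_lookup(path, ref$grid, query$grid, lq_target)
    shift_mat[i, ] <- .warp_lookup(path, ref$grid, query$grid, query$grid)
  }
  names(per_gene_log) <- retained
  estimate_log <- mean(per_gene_log)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(per_gene_log[sample.int(length(per_gene_log), replace = TRUE)])
    }, numeric(1))
  })
  ci_log <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  to_postnatal <- function(l) exp(l) - offset_ref
  structure(list(estimate = to_postnatal(estimate_log),
                 ci = to_postnatal(ci_log),
                 estimate_log_conception = estimate_log,
                 per_gene_ages = to_postnatal(per_gene_log),
                 n_genes = length(retained),
                 shift_curve = data.frame(
                   query_log_age = query$grid,
                   mean_ref_log_age = colMeans(shift_mat),
                   mean_shift = colMeans(shift_mat) - query$grid),
                 query_age = query_age, min_corr = min_corr, n_boot = n_boot,
                 offset_ref = offset_ref, offset_query = offset_query),
            class = "TimeShiftEstimate")
}

#' @export
print.TimeShiftEstimate <- function(x, ...) {
  cat(sprintf("Corresponding reference age for query age %g d (postnatal):\n",
              x$query_age))
  cat(sprintf("  %.1f d (%.2f y), 95%% bootstrap CI [%.1f, %.1f] d, %d genes (r > %g)\n",
              x$estimate, x$estimate / 365.25, x$ci[1], x$ci[2], x$n_genes,
              x$min_corr))
  invisible(x)
}
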