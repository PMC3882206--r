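# Cross-species age-trajectory pattern classification (conserved /
# level-shifted / shape-divergent), k-means modules and module effect tests.

.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# F-test p for nested models given residual sums of squares.
# Degenerate (numerically zero) residuals are resolved by convention:
# no improvement on a perfect fit -> p = 1; perfect full fit with a real
# improvement -> p = 0.
.nested_f_p <- function(rss_reduced, rss_full, q, df2, tol) {
  delta <- rss_reduced - rss_full
  if (df2 <= 0) return(NA_real_)
  if (rss_full <= tol) {
    return(if (delta <= tol) 1 else 0)
  }
  f <- (delta / q) / (rss_full / df2)
  stats::pf(max(f, 0), q, df2, lower.tail = FALSE)
}

#' F-test for age-related expression change
#'
#' Fits polynomial regression models of expression on age (degrees 1 to
#' `max_degree`), grows the degree by forward nested F-tests at
#' `select_alpha`, and returns the F-test p-value of the selected model
#' against the intercept-only model.
#'
#' @param ages numeric ages (any monotone transform thereof).
#' @param values expression values.
#' @param max_degree maximum polynomial degree (default 3).
#' @param select_alpha threshold for growing the degree (default 0.05).
#' @return list with `p` (age p-value) and `degree` (selected degree).
#' @export
age_test <- function(ages, values, max_degree = 3, select_alpha = 0.05) {
  n <- length(ages)
  if (length(values) != n) stop("ages and values must align", call. = FALSE)
  if (n < max_degree + 3) stop("insufficient observations", call. = FALSE)
  rss0 <- sum((values - mean(values))^2)
  tol <- 1e-10 * max(rss0, 1)
  if (rss0 <= tol) return(list(p = 1, degree = 1L))
  P <- stats::poly(ages, max_degree)
  rss <- vapply(seq_len(max_degree), function(d) {
    .rss(cbind(1, P[, seq_len(d), drop = FALSE]), values)
  }, numeric(1))
  degree <- 1L
  while (degree < max_degree) {
    p_step <- .nested_f_p(rss[degree], rss[degree + 1], 1, n - degree - 2, tol)
    if (!is.na(p_step) && p_step < select_alpha) degree <- degree + 1L else break
  }
  p <- .nested_f_p(rss0, rss[degree], degree, n - degree - 1, tol)
  list(p = p, degree = degree)
}

# Pooled two-species ANCOVA F-test. With center = TRUE each species' values
# are first normalized to the common mean, removing constant level
# differences, and only the age-interaction (trajectory-shape) terms are
# tested: a species-level intercept stays in both models because unequal
# age sampling leaves a residual constant after centering.
.pair_ancova_p <- function(ages1, values1, ages2, values2, degree, center) {
  if (center) {
    gm <- mean(c(values1, values2))
    values1 <- values1 - mean(values1) + gm
    values2 <- values2 - mean(values2) + gm
  }
  y <- c(values1, values2)
  if (stats::sd(y) < 1e-12) return(NA_real_)  # untestable after centering
  u <- c(ages1, ages2)
  z <- rep(c(0, 1), c(length(values1), length(values2)))
  P <- stats::poly(u, degree)
  if (center) {
    X_red <- cbind(1, P, z)
    q <- degree
  } else {
    X_red <- cbind(1, P)
    q <- degree + 1
  }
  X_full <- cbind(1, P, z, z * P)
  n <- length(y)
  rss_red <- .rss(X_red, y)
  rss_full <- .rss(X_full, y)
  tol <- 1e-10 * max(sum((y - mean(y))^2), 1)
  .nested_f_p(rss_red, rss_full, q, n - ncol(X_full), tol)
}

# Multi-species age gate: F-test of all age-involving terms (shared
# polynomial plus species interactions) against the species-offsets-only
# model. Exact under the flat null, and powered for genes whose trajectory
# shapes differ across species (where a shared pooled fit can cancel out).
.age_gate_ancova <- function(species_data, degree) {
  y <- unlist(lapply(species_data, `[[`, "values"), use.names = FALSE)
  u <- unlist(lapply(species_data, `[[`, "ages"), use.names = FALSE)
  sp <- factor(rep(names(species_data),
                   vapply(species_data, function(s) length(s$values), integer(1))))
  rss_tot <- sum((y - mean(y))^2)
  tol <- 1e-10 * max(rss_tot, 1)
  if (rss_tot <= tol) return(1)
  S <- stats::model.matrix(~sp)
  P <- stats::poly(u, degree)
  inter <- do.call(cbind, lapply(seq_len(ncol(S) - 1), function(k) S[, k + 1] * P))
  X_red <- S
  X_full <- cbind(S, P, inter)
  q <- degree * nlevels(sp)
  .nested_f_p(.rss(X_red, y), .rss(X_full, y), q, length(y) - ncol(X_full), tol)
}

.species_pairs <- function(species) {
  if (length(species) < 2) stop("need >= 2 species", call. = FALSE)
  cmb <- utils::combn(species, 2)
  stats::setNames(split(cmb, col(cmb)),
                  apply(cmb, 2, paste, collapse = "::"))
}

#' Pairwise ANCOVA test of species trajectory differences
#'
#' For every species pair, compares the pooled polynomial model of
#' expression on (scaled) age with and without species terms (level offset
#' plus age interactions) by F-test. Ages should be comparable across
#' species (e.g. scaled to fraction of the stage window).
#'
#' @param species_data named list; per species a list with `ages` and
#'   `values`.
#' @param degree polynomial degree of the pooled model.
#' @return named numeric vector of p-values, one per species pair
#'   (`"a::b"`).
#' @export
species_difference_test <- function(species_data, degree = 3) {
  pairs <- .species_pairs(names(species_data))
  vapply(pairs, function(pr) {
    a <- species_data[[pr[1]]]; b <- species_data[[pr[2]]]
    .pair_ancova_p(a$ages, a$values, b$ages, b$values, degree, center = FALSE)
  }, numeric(1))
}

#' Pairwise trajectory-shape test after mean normalization
#'
#' Each species' expression vector is normalized to the common mean,
#' removing any constant level difference, before the pairwise ANCOVA;
#' a significant result therefore indicates a difference in trajectory
#' shape, not level. Genes left with zero variance after centering are
#' untestable (`NA`).
#'
#' @inheritParams species_difference_test
#' @return named numeric vector of p-values per species pair.
#' @export
shape_difference_test <- function(species_data, degree = 3) {
  pairs <- .species_pairs(names(species_data))
  vapply(pairs, function(pr) {
    a <- species_data[[pr[1]]]; b <- species_data[[pr[2]]]
    .pair_ancova_p(a$ages, a$values, b$ages, b$values, degree, center = TRUE)
  }, numeric(1))
}

#' Deterministic trajectory pattern label from test p-values
#'
#' Labels (checked in order):
#' `P1` - age-related (`p_age < age_alpha`) with no species difference in
#' any pair (all `p_species > none_alpha`); `P2` - age-related, a species
#' level difference in at least one pair (`min p_species < age_alpha`) and
#' no shape difference in any pair (all `p_shape > none_alpha`); `P3` -
#' age-related with a shape difference in at least one pair
#' (`min p_shape < age_alpha`); otherwise `none`.
#'
#' @param p_age age-test p-value.
#' @param p_species named/plain vector of pairwise species-difference
#'   p-values.
#' @param p_shape vector of pairwise shape-difference p-values.
#' @param age_alpha significance gate (default 0.01).
#' @param none_alpha no-difference gate (default 0.1).
#' @return list with `label` and the summary p-values
#'   (`p_age`, `p_species_min`, `p_shape_min`).
#' @export
classify_pattern <- function(p_age, p_species, p_shape,
                             age_alpha = 0.01, none_alpha = 0.1) {
  stopifnot(all(c(p_age, p_species, p_shape) >= 0, na.rm = TRUE),
            all(c(p_age, p_species, p_shape) <= 1, na.rm = TRUE))
  ps <- p_species[!is.na(p_species)]
  sh <- p_shape[!is.na(p_shape)]
  label <- if (is.na(p_age) || p_age >= age_alpha) {
    "none"
  } else if (length(ps) && all(ps > none_alpha)) {
    "P1"
  } else if (length(ps) && min(ps) < age_alpha &&
             length(sh) && all(sh > none_alpha)) {
    "P2"
  } else if (length(sh) && min(sh) < age_alpha) {
    "P3"
  } else {
    "none"
  }
  list(label = label, p_age = p_age,
       p_species_min = if (length(ps)) min(ps) else NA_real_,
       p_shape_min = if (length(sh)) min(sh) else NA_real_)
}

#' Classify every gene's cross-species age pattern
#'
#' The age gate is a pooled multi-species ANCOVA F-test of all
#' age-involving terms (shared polynomial plus species interactions)
#' against a species-offsets-only model, so genes whose trajectories
#' diverge across species still pass the gate. Pairwise species and shape
#' tests then feed [classify_pattern()]. Ages are scaled to the fraction of
#' each species' stage window so species with different maturation rates
#' are comparable.
#'
#' @param datasets named list per species: `matrix` plus `samples`
#'   (with `age`).
#' @param config [species_stage_config()].
#' @param stage `"development"` (default) or `"aging"`.
#' @param max_degree maximum polynomial degree.
#' @param age_alpha,none_alpha classification gates (defaults 0.01 / 0.1).
#' @return `data.frame` of class `PatternCall` with one row per shared gene:
#'   `gene_id`, `p_age`, `p_species_min`, `p_shape_min`, `degree`, `label`.
#' @export
classify_age_patterns <- function(datasets, config = species_stage_config(),
                                  stage = "development", max_degree = 3,
                                  age_alpha = 0.01, none_alpha = 0.1) {
  species <- names(datasets)
  scaled <- lapply(species, function(sp) {
    iv <- config[[sp]][[stage]]
    ages <- datasets[[sp]]$samples$age
    keep <- !is.na(ages) & ages >= iv[1] & ages <= iv[2]
    ids <- datasets[[sp]]$samples$sample_id[keep]
    list(u = (ages[keep] - iv[1]) / diff(iv),
         cols = match(ids, colnames(datasets[[sp]]$matrix)))
  })
  names(scaled) <- species
  genes <- Reduce(intersect, lapply(datasets, function(d) rownames(d$matrix)))
  rows <- lapply(genes, function(g) {
    per_species <- lapply(species, function(sp) {
      list(ages = scaled[[sp]]$u,
           values = unclass(datasets[[sp]]$matrix)[g, scaled[[sp]]$cols])
    })
    names(per_species) <- species
    p_age <- .age_gate_ancova(per_species, degree = max_degree)
    # pairwise tests use the full polynomial family: species-specific shape
    # differences can live in terms a parsimonious pooled fit does not need
    p_sp <- species_difference_test(per_species, degree = max_degree)
    p_sh <- shape_difference_test(per_species, degree = max_degree)
    cl <- classify_pattern(p_age, p_sp, p_sh, age_alpha, none_alpha)
    data.frame(gene_id = g, p_age = cl$p_age, p_species_min = cl$p_species_min,
               p_shape_min = cl$p_shape_min, degree = max_degree,
               label = cl$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PatternCall", "data.frame")
  out
}

#' Interpolated multi-species expression profiles
#'
#' Per gene, fits each species' trajectory in the stage window and
#' concatenates the interpolated values at the species' 10-point stage
#' grids; the usual input for module clustering.
#'
#' @inheritParams classify_age_patterns
#' @param df,method passed to [fit_trajectory()].
#' @return numeric matrix, genes x (10 * n_species).
#' @export
trajectory_profiles <- function(datasets, config = species_stage_config(),
                                stage = "development", df = 3,
                                method = "smoothing") {
  species <- names(datasets)
  human_lifespan <- config[["human"]]$aging[2]
  mats <- lapply(species, function(sp) {
    d <- datasets[[sp]]
    iv <- config[[sp]][[stage]]
    keep <- !is.na(d$samples$age) & d$samples$age >= iv[1] & d$samples$age <= iv[2]
    ages <- d$samples$age[keep]
    cols <- match(d$samples$sample_id[keep], colnames(d$matrix))
    grid <- stage_grid(config, sp, stage)$ages
    offset <- .log_age_offset(config[[sp]]$aging[2] / human_lifespan)
    t(apply(unclass(d$matrix)[, cols, drop = FALSE], 1, function(v) {
      fit <- fit_trajectory(ages, v, timescale = .stage_timescale(stage),
                            df = df, method = method, log_offset = offset)
      stats::predict(fit, pmin(pmax(grid, min(ages)), max(ages)))
    }))
  })
  genes <- Reduce(intersect, lapply(mats, rownames))
  do.call(cbind, lapply(mats, function(m) m[genes, , drop = FALSE]))
}

#' k-means modules of expression profiles
#'
#' Each gene's profile is standardized to zero mean and unit variance, then
#' clustered with k-means (best of `n_restarts` random starts by total
#' within-cluster sum of squares). Deterministic for a fixed seed.
#'
#' @param profiles numeric matrix, genes x features (e.g.
#'   [trajectory_profiles()]).
#' @param k number of modules (default 8).
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 50).
#' @return object of class `ModuleAssignment`: list with `k`, `module`
#'   (named integer vector), `sizes`, `tot_withinss`.
#' @export
cluster_modules <- function(profiles, k = 8, seed = 1, n_restarts = 50) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of genes", call. = FALSE)
  s <- apply(profiles, 1, stats::sd)
  std <- (profiles - rowMeans(profiles)) / ifelse(s > 0, s, 1)
  km <- .with_seed(seed, stats::kmeans(std, centers = k, nstart = n_restarts,
                                       iter.max = 100))
  structure(list(k = k, module = stats::setNames(km$cluster, rownames(profiles)),
                 sizes = as.integer(km$size), tot_withinss = km$tot.withinss),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat(sprintf("ModuleAssignment: %d genes in %d modules (sizes: %s)\n",
              length(x$module), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Permutation test of a module's mean effect size
#'
#' The statistic is the mean effect size of the module's genes. In
#' `"gene-permutation"` mode the null draws random same-size gene sets from
#' the effect vector; in `"label-null"` mode the caller supplies an ensemble
#' of label-permuted effect vectors (rows = permutations). The two-sided
#' p-value is the fraction of null statistics at least as far from the null
#' center as the observed one.
#'
#' @param module_genes character vector of gene ids (non-empty, present in
#'   the effect vector).
#' @param effect `ContrastEffect` or named numeric vector.
#' @param B permutations for gene-permutation mode (default 1000).
#' @param seed RNG seed.
#' @param mode `"gene-permutation"` or `"label-null"`.
#' @param null_effects permutations x genes matrix of label-permuted effect
#'   vectors (required for `"label-null"`).
#' @param plus_one report `(b+1)/(B+1)`.
#' @return list with `p`, `observed`, `null_mean`, `B`.
#' @export
module_effect_test <- function(module_genes, effect, B = 1000, seed = 1,
                               mode = c("gene-permutation", "label-null"),
                               null_effects = NULL, plus_one = FALSE) {
  mode <- match.arg(mode)
  d <- .effect_vector(effect)
  if (length(module_genes) == 0) stop("empty module", call. = FALSE)
  if (!all(module_genes %in% names(d))) {
    stop("module contains genes absent from the effect vector", call. = FALSE)
  }
  obs <- mean(d[module_genes])
  m <- length(module_genes)
  null_stats <- if (mode == "gene-permutation") {
    .with_seed(seed, vapply(seq_len(B), function(b) {
      mean(d[sample.int(length(d), m)])
    }, numeric(1)))
  } else {
    if (is.null(null_effects)) stop("null_effects required for label-null mode", call. = FALSE)
    idx <- match(module_genes, colnames(null_effects))
    if (anyNA(idx)) stop("module genes missing from null_effects columns", call. = FALSE)
    rowMeans(null_effects[, idx, drop = FALSE])
  }
  center <- mean(null_stats)
  n_extreme <- sum(abs(null_stats - center) >= abs(obs - center) - 1e-12)
  list(p = .empirical_p(n_extreme, length(null_stats), plus_one),
       observed = obs, null_mean = center, B = length(null_stats))
}
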