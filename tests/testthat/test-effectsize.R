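test_that("cohens_d matches hand-worked values and is antisymmetric", {
  expect_equal(cohens_d(c(0, 2), c(0, 2)), 0)
  expect_equal(cohens_d(c(0, 1, 2), c(2, 3, 4)), -2)
  expect_equal(cohens_d(c(2, 3, 4), c(0, 1, 2)), 2)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("cohens_d agrees with the direct-formula oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.1, 5))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -3, 3))
    expect_equal(cohens_d(a, b), oracle_cohens_d(a, b), tolerance = 1e-12)
  }
})

test_that("contrast_effects computes per-gene d and excludes zero-variance genes", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[, 3:4] <- m[, 1:2]  # groups are identical copies
  m[1, ] <- 5           # flat gene: zero pooled SD
  st <- as_sample_table(data.frame(sample_id = paste0("s", 1:4), dataset_id = "D",
                                   tissue = "liver", group = rep(c("a", "b"), each = 2)))
  eff <- contrast_effects(expression_matrix(m), st, "a", "b")
  expect_true(all(eff$d == 0))
  expect_equal(eff$n_zero_sd, 1)
  expect_false("g1" %in% names(eff$d))
  expect_error(contrast_effects(expression_matrix(m), st, "a", "nope"),
               "unknown group")
})

test_that("compare_contrasts reproduces hand-computable correlations", {
  x <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_equal(compare_contrasts(x, x)$r, 1)
  expect_equal(compare_contrasts(x, -x)$r, -1)
  y <- setNames(c(1, 3, 2, 4), paste0("g", 1:4))
  cm <- compare_contrasts(x, y)
  expect_equal(cm$r, 0.8)
  expect_equal(cm$n_genes, 4)
  expect_error(compare_contrasts(x[1:2], y[1:2]), "3 shared genes")
})

test_that("fast Pearson path matches cor.test and the formula oracle", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    rp <- crosstx:::.pearson_rp(x, y)
    ct <- cor.test(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(rp[["r"]], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(rp[["p"]], ct$p.value, tolerance = 1e-12)
    expect_equal(rp[["p"]], orc$p, tolerance = 1e-12)
  }
})

test_that("binned scatter equals a naive group-by computation", {
  set.seed(8)
  ids <- paste0("g", 1:100)
  x <- setNames(rnorm(100), ids)
  y <- setNames(x + rnorm(100, sd = 0.5), ids)
  bs <- binned_scatter(x, y, n_bins = 10)
  ord <- names(sort(x))
  for (b in 1:10) {
    members <- ord[((b - 1) * 10 + 1):(b * 10)]
    expect_equal(bs$mean_x[b], mean(x[members]))
    expect_equal(bs$mean_y[b], mean(y[members]))
    expect_equal(bs$var_y[b], var(y[members]))
  }
  # one gene per bin: bin means are the raw values
  one <- binned_scatter(x[1:10], y[1:10], n_bins = 10)
  expect_equal(one$mean_x, sort(unname(x[1:10])))
  expect_true(all(one$n == 1))
  # monotone construction gives monotone bin means
  u <- setNames(runif(200), paste0("u", 1:200))
  mono <- binned_scatter(u, u, 10)
  expect_true(all(diff(mono$mean_y) > 0))
  expect_error(binned_scatter(x, y, 1), ">= 2")
})

test_that("binomial trend test equals the exact tail sum", {
  mk <- function(r, p) structure(list(r = r, p = p), class = "ComparisonResult")
  none <- list(mk(-0.5, 0.01), mk(0.3, 0.5))
  expect_equal(binomial_trend_test(none), 1)
  some <- list(mk(0.5, 0.01), mk(0.6, 0.001), mk(0.2, 0.04), mk(-0.1, 0.9))
  pi0 <- 0.025
  expected <- sum(dbinom(3:4, 4, pi0))
  expect_equal(binomial_trend_test(some, pi0), expected, tolerance = 1e-12)
  expect_equal(binomial_trend_test(some, 1), 1)
  expect_error(binomial_trend_test(list()), ">= 1")
})

test_that("meta-test p equals the exhaustive label-shuffle fraction on tiny designs", {
  set.seed(55)
  mk <- function(seed) {
    s <- simulate_two_group(12, n_a = 2, n_b = 2, frac_affected = 0.5, d = 3,
                            seed = seed)
    list(matrix = s$matrix, samples = s$samples, groups = c("CR", "AL"))
  }
  ds <- list(mk(1), mk(2))
  got <- permutation_meta_test(ds, list(c(1, 2)), exhaustive = TRUE)

  # independent oracle: enumerate the 6 x 6 assignments directly
  count_for <- function(ia1, ia2) {
    d1 <- apply(unclass(ds[[1]]$matrix), 1, function(v)
      oracle_cohens_d(v[ia1], v[-ia1]))
    d2 <- apply(unclass(ds[[2]]$matrix), 1, function(v)
      oracle_cohens_d(v[ia2], v[-ia2]))
    ok <- is.finite(d1) & is.finite(d2)
    ct <- cor.test(d1[ok], d2[ok])
    (ct$estimate > 0) && (ct$p.value < 0.05)
  }
  combos <- combn(4, 2)
  counts <- c()
  for (i in 1:6) for (j in 1:6) {
    counts <- c(counts, count_for(combos[, i], combos[, j]))
  }
  c_obs <- count_for(1:2, 1:2)
  expect_equal(got$B, 36)
  expect_equal(got$p_perm, sum(counts >= c_obs) / 36, tolerance = 1e-12)
})

test_that("meta-test handles C_obs = 0 and is bit-reproducible under a seed", {
  mk <- function(seed) {
    s <- simulate_two_group(30, n_a = 3, n_b = 3, frac_affected = 0, seed = seed)
    list(matrix = s$matrix, samples = s$samples, groups = c("CR", "AL"))
  }
  ds <- list(mk(11), mk(12), mk(13), mk(14))
  pairs <- list(c(1, 2), c(3, 4))
  r1 <- permutation_meta_test(ds, pairs, B = 150, seed = 7)
  r2 <- permutation_meta_test(ds, pairs, B = 150, seed = 7)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$p_perm, r2$p_perm)
  if (r1$C_obs == 0) {
    expect_equal(r1$p_perm, 1)
    expect_true(is.na(r1$fdr_perm))
  }
})

test_that("meta-test detects a planted cross-dataset effect correlation", {
  prs <- lapply(1:12, function(k) {
    crosstx:::.simulate_effect_pair(150, 0.8, 5, 5, seed = 40 + k, pair_id = k)
  })
  ds <- unlist(lapply(prs, function(p) list(
    list(matrix = p$diet$matrix, samples = p$diet$samples, groups = c("CR", "AL")),
    list(matrix = p$species$matrix, samples = p$species$samples,
         groups = c("human", "chimpanzee")))), recursive = FALSE)
  meta <- permutation_meta_test(ds, lapply(1:12, function(k) c(2 * k - 1, 2 * k)),
                                B = 1000, seed = 3)
  expect_lte(meta$p_perm, 0.01)
  expect_lt(meta$fdr_perm, 0.5)
})
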