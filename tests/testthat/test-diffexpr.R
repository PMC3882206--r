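test_that("welch_t reproduces the hand-worked statistic and its symmetries", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(w$df, 50 / 17, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- welch_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)
  expect_error(welch_t(c(1, 1), c(2, 2)), "variances zero")
})

test_that("welch_t matches stats::t.test on random instances", {
  set.seed(61)
  for (i in 1:100) {
    a <- rnorm(sample(3:15, 1), sd = runif(1, 0.2, 3))
    b <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    w <- welch_t(a, b)
    tt <- t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("mwu exact path matches brute-force enumeration for small samples", {
  res <- mwu(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  set.seed(71)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(mwu(a, b)$p, oracle_mwu_exact(a, b), tolerance = 1e-12)
  }
})

test_that("mwu handles ties and is invariant to monotone transforms", {
  expect_equal(mwu(c(1, 2, 3), c(1, 2, 3))$p, 1)
  a <- c(0.3, 1.1, 2.2, 4.5); b <- c(0.8, 1.9, 3.1)
  r1 <- mwu(a, b)
  r2 <- mwu(exp(a), exp(b))
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p)
  expect_error(mwu(numeric(0), 1), "empty group")
})

test_that("permutation FDR stays near-empty under the null and recovers planted effects", {
  null_sim <- simulate_two_group(300, n_a = 8, n_b = 7, frac_affected = 0, seed = 81)
  f0 <- permutation_fdr_genes(null_sim$matrix, null_sim$samples, B = 200, seed = 1)
  expect_lte(length(f0$affected), 3)  # <= 1% of genes

  sim <- simulate_two_group(400, n_a = 10, n_b = 10, frac_affected = 0.2, d = 3,
                            seed = 82)
  f1 <- permutation_fdr_genes(sim$matrix, sim$samples, B = 300, seed = 2)
  expect_gte(mean(sim$truth$affected %in% f1$affected), 0.9)
  expect_lte(mean(!(f1$affected %in% sim$truth$affected)), 0.2)
  # curve invariants
  expect_true(all(diff(f1$curve$n_observed) >= 0))
  expect_true(all(f1$curve$fdr >= 0))
  expect_error(permutation_fdr_genes(sim$matrix, sim$samples, B = 50),
               "insufficient permutations")
})

test_that("welch and MWU affected lists agree on high-SNR data", {
  sim <- simulate_two_group(300, n_a = 10, n_b = 10, frac_affected = 0.3, d = 4,
                            seed = 83)
  fw <- permutation_fdr_genes(sim$matrix, sim$samples, test = "welch_t",
                              B = 200, seed = 3)
  fm <- permutation_fdr_genes(sim$matrix, sim$samples, test = "mwu",
                              B = 200, seed = 3)
  overlap <- length(intersect(fw$affected, fm$affected)) /
    max(length(fw$affected), length(fm$affected))
  expect_gte(overlap, 0.9)
})

test_that("fisher enrichment reproduces hand-worked odds ratios and enumeration p", {
  uni <- sprintf("g%03d", 1:100)
  a <- uni[1:20]               # 10 overlap
  b <- uni[11:30]
  fe <- fisher_enrichment(a, b, uni)
  expect_equal(unname(fe$table[1, 1]), 10)
  expect_equal(fe$odds_ratio, (10 * 70) / (10 * 10))
  expect_equal(fe$p, oracle_fisher_p(fe$table), tolerance = 1e-12)

  prop <- fisher_enrichment(uni[1:20], uni[c(1:4, 21:36)], uni)
  expect_equal(prop$odds_ratio, 1)

  set.seed(91)
  for (i in 1:100) {
    n_uni <- sample(12:30, 1)
    u <- sprintf("u%02d", seq_len(n_uni))
    fa <- sample(u, sample(2:(n_uni - 2), 1))
    fb <- sample(u, sample(2:(n_uni - 2), 1))
    fe <- fisher_enrichment(fa, fb, u)
    expect_equal(fe$p, oracle_fisher_p(fe$table), tolerance = 1e-12)
  }
  expect_error(fisher_enrichment("a", "b", character(0)), "empty universe")
})

test_that("stratified overlap flags degenerate strata and matches per-stratum Fisher", {
  uni <- sprintf("g%03d", 1:80)
  strata <- list(lo = uni[1:40], hi = uni[41:80])
  aff <- c(uni[1:10], uni[41:44])
  ref <- c(uni[5:20], uni[41:50])
  so <- stratified_overlap(aff, ref, uni, strata)
  expect_equal(nrow(so), 2)
  lo <- fisher_enrichment(intersect(aff, strata$lo), intersect(ref, strata$lo),
                          strata$lo)
  expect_equal(so$p[so$stratum == "lo"], lo$p)
  expect_true(all(so$testable))

  empty <- stratified_overlap(uni[1:10], ref, uni,
                              list(a = uni[1:40], b = uni[41:80]))
  expect_false(empty$testable[empty$stratum == "b"])
  expect_error(stratified_overlap(aff, ref, uni, list(a = uni[1:10])),
               "partition")
})

test_that("reference = affected gives maximal enrichment in populated strata", {
  uni <- sprintf("g%03d", 1:60)
  aff <- uni[1:12]
  strata <- expression_strata(
    expression_matrix(matrix(seq_len(60), 60, 2,
                             dimnames = list(uni, c("s1", "s2")))), 2)
  so <- stratified_overlap(aff, aff, uni, strata)
  tb <- so[so$testable, ]
  expect_true(all(is.infinite(tb$odds_ratio)))
  expect_true(all(tb$p < 0.01))
})
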