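test_that("age test flags trends, ignores constants, and enforces sample minimums", {
  ages <- runif(30)
  flat <- age_test(ages, rep(2, 30))
  expect_gte(flat$p, 0.5)

  set.seed(12)
  a <- sort(runif(30))
  y <- 3 * a + rnorm(30, sd = 0.3)  # SNR ~ 10
  expect_lt(age_test(a, y)$p, 1e-6)
  expect_error(age_test(runif(4), rnorm(4)), "insufficient observations")
})

test_that("age test F statistic matches a direct residual-sum-of-squares oracle", {
  set.seed(13)
  a <- runif(25)
  y <- 1 + 2 * a + rnorm(25, sd = 0.5)
  res <- age_test(a, y, max_degree = 1)
  rss0 <- sum((y - mean(y))^2)
  fit <- lm(y ~ a)
  rss1 <- sum(residuals(fit)^2)
  f <- ((rss0 - rss1) / 1) / (rss1 / (25 - 2))
  expect_equal(res$p, pf(f, 1, 23, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("species and shape tests behave on identical, offset and reshaped inputs", {
  set.seed(14)
  u <- sort(runif(20))
  base <- 2 * u - u^2
  identical_pair <- list(a = list(ages = u, values = base),
                         b = list(ages = u, values = base))
  expect_gte(species_difference_test(identical_pair, degree = 2)[[1]], 0.999)

  noisy_offset <- list(a = list(ages = u, values = base + rnorm(20, sd = 0.2)),
                       b = list(ages = u, values = base + 2 + rnorm(20, sd = 0.2)))
  expect_lt(species_difference_test(noisy_offset, degree = 2)[[1]], 1e-4)
  # pure offsets leave no shape difference after centering
  expect_gt(shape_difference_test(noisy_offset, degree = 2)[[1]], 0.05)

  offset_only <- list(a = list(ages = u, values = base),
                      b = list(ages = u, values = base - 1.5))
  expect_equal(shape_difference_test(offset_only, degree = 2)[[1]], 1)

  reshaped <- list(a = list(ages = u, values = 3 * u + rnorm(20, sd = 0.1)),
                   b = list(ages = u, values = 3 * u^2 + rnorm(20, sd = 0.1)))
  expect_lt(shape_difference_test(reshaped, degree = 2)[[1]], 1e-4)

  expect_error(species_difference_test(list(a = list(ages = u, values = base))),
               ">= 2 species")
  degen <- list(a = list(ages = u, values = rep(1, 20)),
                b = list(ages = u, values = rep(4, 20)))
  expect_true(is.na(shape_difference_test(degen, degree = 2)[[1]]))
})

test_that("pattern labels follow the threshold table", {
  lab <- function(...) classify_pattern(...)$label
  expect_equal(lab(0.005, c(0.5, 0.6, 0.7), c(0.5, 0.5, 0.5)), "P1")
  expect_equal(lab(0.005, c(0.001, 0.5, 0.5), c(0.5, 0.5, 0.5)), "P2")
  expect_equal(lab(0.005, c(0.001, 0.5, 0.5), c(0.005, 0.5, 0.5)), "P3")
  expect_equal(lab(0.05, c(0.001, 0.001, 0.001), c(0.001, 0.5, 0.5)), "none")
  expect_equal(lab(0.005, c(0.05, 0.5, 0.5), c(0.5, 0.5, 0.5)), "none")
})

test_that("adding a constant species offset converts P1 to P2, never P3", {
  sim <- simulate_age_series(c(P1 = 5), noise_sd = 0, n_individuals = 12, seed = 19)
  shifted <- sim$datasets
  shifted$chimpanzee$matrix <- expression_matrix(
    unclass(shifted$chimpanzee$matrix) + 2)
  calls <- classify_age_patterns(shifted)
  expect_true(all(calls$label == "P2"))
  expect_true(all(calls$p_shape_min > 0.1))
})

test_that("classification recovers planted patterns on moderately noisy data", {
  sim <- simulate_age_series(c(P1 = 20, P2 = 20, P3 = 20, flat = 20),
                             n_individuals = 15, noise_sd = 0.5, seed = 20)
  calls <- classify_age_patterns(sim$datasets)
  truth <- sim$truth$pattern[calls$gene_id]
  sel <- truth %in% c("P1", "P2", "P3")
  expect_gte(mean(calls$label[sel] == truth[sel]), 0.75)
  expect_gte(mean(calls$label[truth == "flat"] == "none"), 0.9)
})

test_that("k-means modules recover planted structure and validate k", {
  set.seed(23)
  up <- matrix(rep(1:10, 30), 30, 10, byrow = TRUE) + rnorm(300, sd = 0.1)
  down <- matrix(rep(10:1, 30), 30, 10, byrow = TRUE) + rnorm(300, sd = 0.1)
  profiles <- rbind(up, down)
  rownames(profiles) <- sprintf("g%02d", 1:60)
  mod <- cluster_modules(profiles, k = 2, seed = 5)
  groups <- split(names(mod$module), mod$module)
  expect_setequal(vapply(groups, length, integer(1)), c(30L, 30L))
  expect_true(all(groups[[1]] %in% rownames(profiles)[1:30]) ||
                all(groups[[1]] %in% rownames(profiles)[31:60]))

  one <- cluster_modules(profiles, k = 1, seed = 5)
  expect_equal(unique(unname(one$module)), 1L)
  expect_error(cluster_modules(profiles, k = 100), "exceeds")
  # deterministic under a fixed seed
  expect_identical(cluster_modules(profiles, k = 2, seed = 9)$module,
                   cluster_modules(profiles, k = 2, seed = 9)$module)
})

test_that("module effect test is trivial on the full set and detects shifted modules", {
  ids <- sprintf("g%03d", 1:500)
  set.seed(29)
  d <- setNames(rnorm(500), ids)
  all_p <- module_effect_test(ids, d, B = 200, seed = 1)
  expect_equal(all_p$p, 1)

  d2 <- d
  d2[1:50] <- d2[1:50] + 2
  shifted <- module_effect_test(ids[1:50], d2, B = 1000, seed = 2)
  expect_lte(shifted$p, 0.002)
  expect_error(module_effect_test(character(0), d), "empty module")
  expect_error(module_effect_test("missing", d), "absent")
})

test_that("label-null mode uses the supplied permuted ensemble", {
  ids <- sprintf("g%02d", 1:40)
  d <- setNames(c(rep(2, 10), rep(0, 30)), ids)
  null_eff <- matrix(rnorm(200 * 40, sd = 0.3), 200, 40,
                     dimnames = list(NULL, ids))
  res <- module_effect_test(ids[1:10], d, mode = "label-null",
                            null_effects = null_eff)
  expect_lte(res$p, 0.01)
  expect_equal(res$B, 200)
})
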