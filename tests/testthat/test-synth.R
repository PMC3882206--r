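test_that("generators are deterministic given a seed and respond to seed changes", {
  a <- simulate_two_group(50, seed = 5)
  b <- simulate_two_group(50, seed = 5)
  expect_identical(a, b)
  c <- simulate_two_group(50, seed = 6)
  expect_false(identical(unclass(a$matrix)[, ], unclass(c$matrix)[, ]))

  w1 <- simulate_warped_pair(log(20), 1, n_genes = 10, seed = 3)
  w2 <- simulate_warped_pair(log(20), 1, n_genes = 10, seed = 3)
  expect_identical(unclass(w1$ref$matrix)[, ], unclass(w2$ref$matrix)[, ])

  s1 <- simulate_age_series(c(P1 = 3, flat = 2), seed = 9)
  s2 <- simulate_age_series(c(P1 = 3, flat = 2), seed = 9)
  expect_identical(unclass(s1$datasets$human$matrix)[, ],
                   unclass(s2$datasets$human$matrix)[, ])
})

test_that("two-group generator plants the requested effect sizes", {
  none <- simulate_two_group(300, frac_affected = 0, seed = 2)
  expect_length(none$truth$affected, 0)
  e0 <- contrast_effects(none$matrix, none$samples, "CR", "AL")
  # null d_hat has sd ~ sqrt(1/8 + 1/7) = 0.52, so median |d| ~ 0.35
  expect_lt(median(abs(e0$d)), 0.5)

  sim <- simulate_two_group(2000, n_a = 10, n_b = 10, frac_affected = 0.5,
                            d = 2, seed = 4)
  eff <- contrast_effects(sim$matrix, sim$samples, "CR", "AL")
  # Cohen's d has the Hedges small-sample inflation E[d_hat] = d / J with
  # J = 1 - 3 / (4 df - 1); correct for it before checking the planted value
  J <- 1 - 3 / (4 * 18 - 1)
  expect_lt(abs(mean(eff$d[sim$truth$affected]) * J - 2), 0.1)
  expect_lt(abs(mean(eff$d[setdiff(names(eff$d), sim$truth$affected)])), 0.1)

  expect_error(simulate_two_group(10, n_a = 1), ">= 2")
  expect_error(simulate_two_group(10, frac_affected = 1.5), "probability")
})

test_that("correlated contrast pairs achieve the requested correlation", {
  perfect <- simulate_correlated_contrasts(200, 1, seed = 1)
  expect_equal(cor(perfect$x, perfect$y), 1, tolerance = 1e-12)
  anti <- simulate_correlated_contrasts(200, -1, seed = 1)
  expect_equal(cor(anti$x, anti$y), -1, tolerance = 1e-12)
  null <- simulate_correlated_contrasts(10000, 0, seed = 2)
  expect_lt(abs(cor(null$x, null$y)), 0.05)
  expect_error(simulate_correlated_contrasts(10, 1.2), "rho")
})

test_that("age-series truth labels satisfy their defining constraints", {
  sim <- simulate_age_series(c(P1 = 4, P2 = 4, P3 = 4, flat = 4),
                             noise_sd = 0, seed = 13)
  tr <- sim$truth
  for (g in names(tr$pattern)) {
    cf <- tr$coefficients[[g]]
    off <- tr$offsets[g, ]
    if (tr$pattern[g] == "P1") {
      expect_true(all(vapply(cf, identical, logical(1), cf[[1]])))
      expect_true(all(off == 0))
    } else if (tr$pattern[g] == "P2") {
      expect_true(all(vapply(cf, identical, logical(1), cf[[1]])))
      expect_gt(max(abs(off)), 0)
    } else if (tr$pattern[g] == "P3") {
      expect_false(identical(cf[[1]], cf[[2]]) && identical(cf[[1]], cf[[3]]))
    }
  }
})

test_that("noiseless P1 genes lie on one shared curve after stage scaling", {
  sim <- simulate_age_series(c(P1 = 3), noise_sd = 0, seed = 17)
  cfg <- species_stage_config()
  for (g in names(sim$truth$pattern)) {
    cf <- sim$truth$coefficients[[g]][[1]]
    # subtracting the shared trajectory must leave one common constant
    # (the gene's baseline) in every species
    consts <- unlist(lapply(names(sim$datasets), function(sp) {
      d <- sim$datasets[[sp]]
      u <- d$samples$age / cfg[[sp]]$development[2]
      unclass(d$matrix)[g, ] - drop(outer(u, 1:3, `^`) %*% cf)
    }))
    expect_lt(diff(range(consts)), 1e-9)
  }
})

test_that("warped-pair generator honors the identity and scaling warps", {
  ident <- simulate_warped_pair(0, 1, n_genes = 20, noise_sd = 0, seed = 5,
                                offset_ref = 19, offset_query = 19,
                                ages_query = round(exp(seq(log(2), log(904),
                                                           length.out = 15))))
  # identity warp + equal offsets: query expression at age t equals the
  # trajectory at the same conception age
  tq <- ident$query$samples$age
  expect_equal(ident$truth$warp(tq), tq, tolerance = 1e-9)

  dbl <- simulate_warped_pair(log(2), 1, n_genes = 5, noise_sd = 0, seed = 5,
                              offset_ref = 0, offset_query = 0,
                              ages_query = c(2, 5, 10, 25, 60, 120, 300, 900))
  expect_equal(dbl$truth$warp(10), 20)
  expect_error(simulate_warped_pair(0, -1, n_genes = 5), "monotone")
})

test_that("generator outputs satisfy their type invariants", {
  for (seed in 1:5) {
    sim <- simulate_two_group(30, seed = seed)
    expect_true(all(is.finite(unclass(sim$matrix))))
    expect_false(anyDuplicated(rownames(sim$matrix)) > 0)
    expect_setequal(sim$samples$sample_id, colnames(sim$matrix))

    fx <- simulate_probe_fixture(n_transcripts = 6, seed = seed)
    expect_true(all(fx$probes$intensities > 0))
    expect_true(all(fx$background$gc >= 0))

    ws <- simulate_warped_pair(log(25), 1.05, n_genes = 8, seed = seed)
    ages <- ws$query$samples$age
    expect_true(all(diff(ws$truth$warp(sort(ages))) > 0))  # monotone warp
  }
})
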