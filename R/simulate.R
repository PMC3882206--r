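# Synthetic-data generators with known ground truth for every pipeline stage.

#' Simulate a two-group expression dataset with planted effects
#'
#' Gene-by-sample log2-scale values for a two-group design (default sizes
#' mirror a typical diet experiment: 8 treated vs 7 control). A fraction of
#' genes carries a true standardized mean difference of `d`: the group-A mean
#' is shifted by `d * noise_sd`, so the injected Cohen's d is exactly `d`.
#'
#' @param n_genes number of genes.
#' @param n_a,n_b samples per group (>= 2).
#' @param frac_affected fraction of genes with a true effect, in `[0, 1]`.
#' @param d true standardized effect size for affected genes.
#' @param noise_sd residual standard deviation (log2 units).
#' @param seed RNG seed; outputs are bit-reproducible given the seed.
#' @param groups labels for the two groups.
#' @param dataset_id,tissue metadata written into the sample table.
#' @return list with `matrix` ([expression_matrix()]), `samples`
#'   (`SampleTable`) and `truth` (affected gene ids, `d`, sizes, `noise_sd`).
#' @export
simulate_two_group <- function(n_genes, n_a = 8, n_b = 7, frac_affected = 0.1,
                               d = 1, noise_sd = 1, seed = 1,
                               groups = c("CR", "AL"), dataset_id = "synthetic",
                               tissue = "cerebral cortex") {
  .stop_if_not_scalar_prob(frac_affected, "frac_affected")
  if (n_a < 2 || n_b < 2) stop("each group needs >= 2 samples", call. = FALSE)
  if (!is.finite(d)) stop("'d' must be finite", call. = FALSE)
  .with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    n_aff <- round(frac_affected * n_genes)
    affected <- if (n_aff > 0) sort(sample(gene_ids, n_aff)) else character(0)
    base <- stats::rnorm(n_genes, mean = 8, sd = 2)
    n <- n_a + n_b
    vals <- base + matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    vals[match(affected, gene_ids), seq_len(n_a)] <-
      vals[match(affected, gene_ids), seq_len(n_a), drop = FALSE] + d * noise_sd
    sample_ids <- sprintf("%s_s%02d", dataset_id, seq_len(n))
    dimnames(vals) <- list(gene_ids, sample_ids)
    samples <- as_sample_table(data.frame(
      sample_id = sample_ids, dataset_id = dataset_id, tissue = tissue,
      group = rep(groups, c(n_a, n_b)), stringsAsFactors = FALSE))
    list(matrix = expression_matrix(vals),
         samples = samples,
         truth = list(affected = affected, d = d, n_a = n_a, n_b = n_b,
                      noise_sd = noise_sd, groups = groups))
  })
}

#' Simulate a pair of per-gene effect vectors with known correlation
#'
#' Draws `n_genes` pairs from a bivariate standard normal with correlation
#' `rho`.
#'
#' @param n_genes number of genes.
#' @param rho target Pearson correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return list with numeric vectors `x`, `y` (named by gene id) and `rho`.
#' @export
simulate_correlated_contrasts <- function(n_genes, rho, seed = 1) {
  if (!is.finite(rho) || abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  .with_seed(seed, {
    z1 <- stats::rnorm(n_genes)
    z2 <- stats::rnorm(n_genes)
    x <- z1
    y <- rho * z1 + sqrt(1 - rho^2) * z2
    ids <- sprintf("g%05d", seq_len(n_genes))
    names(x) <- names(y) <- ids
    list(x = x, y = y, rho = rho)
  })
}

# Random polynomial on [0,1] rescaled to a given amplitude (range of values).
.random_shape <- function(amplitude, degree = 3) {
  u <- seq(0, 1, length.out = 101)
  repeat {
    coefs <- stats::rnorm(degree)
    span <- diff(range(outer(u, seq_len(degree), `^`) %*% coefs))
    if (span > 1e-6) break # essentially never loops; guards a degenerate draw
  }
  coefs * (amplitude / span)
}

.eval_shape <- function(coefs, u) {
  drop(outer(u, seq_along(coefs), `^`) %*% coefs)
}

#' Simulate three-species age-series data with planted trajectory patterns
#'
#' Genes follow one of four ground-truth labels on stage-scaled age
#' (fraction of the species' stage window): `P1` identical trajectory and
#' level in all species; `P2` identical trajectory, species level offsets;
#' `P3` species-specific trajectory shapes (a shared age component plus a
#' per-species perturbation of equal magnitude); `flat` constant expression.
#' Ages are drawn stratified-uniform over each species' stage interval.
#'
#' @param n_per_pattern named integer vector with entries among
#'   `P1`, `P2`, `P3`, `flat`.
#' @param config [species_stage_config()].
#' @param species species simulated (must be in `config`).
#' @param stage `"development"` or `"aging"`.
#' @param n_individuals individuals per species (>= 8).
#' @param noise_sd residual standard deviation (log2 units).
#' @param amplitude trajectory range over the stage window (log2 units).
#' @param offset_size absolute species level offset for `P2` genes.
#' @param seed RNG seed.
#' @return list with `datasets` (per species: `matrix`, `samples`) and
#'   `truth` (per-gene `pattern`, trajectory coefficients, offsets).
#' @export
simulate_age_series <- function(n_per_pattern = c(P1 = 25, P2 = 25, P3 = 25, flat = 25),
                                config = species_stage_config(),
                                species = c("human", "chimpanzee", "macaque"),
                                stage = "development", n_individuals = 15,
                                noise_sd = 0.5, amplitude = 2,
                                offset_size = 1, seed = 1) {
  stopifnot(all(names(n_per_pattern) %in% c("P1", "P2", "P3", "flat")))
  if (n_individuals < 8) stop("need >= 8 individuals per species", call. = FALSE)
  intervals <- lapply(species, function(sp) {
    iv <- config[[sp]][[stage]]
    if (is.null(iv) || any(is.na(iv)) || iv[2] <= iv[1]) {
      stop("empty stage interval for species '", sp, "'", call. = FALSE)
    }
    iv
  })
  names(intervals) <- species
  .with_seed(seed, {
    labels <- rep(names(n_per_pattern), n_per_pattern)
    n_genes <- length(labels)
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, 8, 1)

    # per-gene trajectory coefficients and per-species offsets
    coefs <- vector("list", n_genes)
    offsets <- matrix(0, n_genes, length(species), dimnames = list(gene_ids, species))
    for (i in seq_len(n_genes)) {
      lab <- labels[i]
      if (lab == "flat") {
        coefs[[i]] <- rep(list(numeric(3)), length(species))
      } else if (lab == "P3") {
        # species shapes = shared age component + species perturbation;
        # redraw until every species pair differs by at least a quarter of
        # the amplitude (RMS after mean-centering): random scaled cubics are
        # often near-parallel, and a "divergent shape" label is only
        # meaningful when the shapes actually diverge
        shared <- .random_shape(amplitude)
        ugrid <- seq(0, 1, length.out = 50)
        repeat {
          cand <- lapply(species, function(sp) shared + .random_shape(amplitude))
          curves <- lapply(cand, function(cf) {
            v <- .eval_shape(cf, ugrid); v - mean(v)
          })
          dmin <- min(apply(utils::combn(length(cand), 2), 2, function(pr) {
            sqrt(mean((curves[[pr[1]]] - curves[[pr[2]]])^2))
          }))
          if (dmin >= amplitude / 4) break
        }
        coefs[[i]] <- cand
      } else {
        one <- .random_shape(amplitude)
        coefs[[i]] <- rep(list(one), length(species))
      }
      if (lab == "P2") {
        off <- sample(c(0, offset_size, -offset_size))
        offsets[i, ] <- off
      }
    }

    # stratified-uniform ages, per-species values
    datasets <- list()
    for (k in seq_along(species)) {
      sp <- species[k]
      iv <- intervals[[sp]]
      u <- (seq_len(n_individuals) - stats::runif(n_individuals)) / n_individuals
      ages <- iv[1] + u * diff(iv)
      scaled <- (ages - iv[1]) / diff(iv)
      vals <- matrix(NA_real_, n_genes, n_individuals)
      for (i in seq_len(n_genes)) {
        vals[i, ] <- base[i] + .eval_shape(coefs[[i]][[k]], scaled) + offsets[i, k]
      }
      vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                            n_genes, n_individuals)
      sample_ids <- sprintf("%s_%02d", sp, seq_len(n_individuals))
      dimnames(vals) <- list(gene_ids, sample_ids)
      samples <- as_sample_table(data.frame(
        sample_id = sample_ids, dataset_id = paste0("ageseries_", sp),
        tissue = "cerebral cortex", group = sp, age = ages,
        stringsAsFactors = FALSE))
      datasets[[sp]] <- list(matrix = expression_matrix(vals), samples = samples)
    }
    truth <- list(pattern = stats::setNames(labels, gene_ids),
                  coefficients = stats::setNames(coefs, gene_ids),
                  offsets = offsets, noise_sd = noise_sd,
                  amplitude = amplitude, stage = stage, species = species)
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate a pair of age-series datasets related by a known monotone warp
#'
#' The query species' expression at postnatal age t equals the reference
#' species' trajectory evaluated at the warped age
#' `log t_ref = a + b * log t_query` (conception-age scale), plus noise.
#' When `ages_ref` is omitted, reference ages are placed log-uniformly so
#' that their conception-age range equals the warp image of the query range
#' (both series then span the same biological window).
#'
#' @param a,b log-linear warp coefficients, `b > 0`.
#' @param n_genes number of genes.
#' @param ages_query postnatal query-species ages in days.
#' @param ages_ref optional postnatal reference-species ages in days.
#' @param noise_sd residual standard deviation (log2 units).
#' @param offset_ref,offset_query gestation lengths in days (defaults:
#'   human 280, mouse 19).
#' @param amplitude trajectory range (log2 units).
#' @param seed RNG seed.
#' @return list with `ref` and `query` datasets (`matrix`, `samples`) and
#'   `truth` (warp coefficients and `warp(t_query_postnatal)` function
#'   returning reference postnatal age).
#' @export
simulate_warped_pair <- function(a, b, n_genes = 200,
                                 ages_query = round(exp(seq(log(2), log(904), length.out = 12))),
                                 ages_ref = NULL, noise_sd = 0.1,
                                 offset_ref = 280, offset_query = 19,
                                 amplitude = 2, seed = 1) {
  if (!is.finite(b) || b <= 0) stop("warp must be monotone: b > 0", call. = FALSE)
  if (any(ages_query < 0)) stop("negative age", call. = FALSE)
  lq <- log(ages_query + offset_query)
  warp_log <- function(l) a + b * l
  if (is.null(ages_ref)) {
    lr <- seq(warp_log(min(lq)), warp_log(max(lq)), length.out = 23)
    ages_ref <- exp(lr) - offset_ref
    if (any(ages_ref < 0)) {
      stop("warp maps query ages before the reference species' birth; ",
           "increase a/b or supply ages_ref explicitly", call. = FALSE)
    }
  } else {
    if (any(ages_ref < 0)) stop("negative age", call. = FALSE)
    lr <- log(ages_ref + offset_ref)
  }
  .with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, 8, 1)
    # trajectories parameterized on the reference log conception-age axis,
    # standardized to [0,1] over the reference range
    rng <- range(lr)
    to_u <- function(l) (l - rng[1]) / diff(rng)
    coefs <- lapply(seq_len(n_genes), function(i) .random_shape(amplitude))
    make <- function(lvec) {
      u <- pmin(pmax(to_u(lvec), 0), 1)
      t(vapply(seq_len(n_genes),
               function(i) base[i] + .eval_shape(coefs[[i]], u),
               numeric(length(u))))
    }
    ref_vals <- make(lr) + matrix(stats::rnorm(n_genes * length(lr), sd = noise_sd),
                                  n_genes, length(lr))
    query_vals <- make(warp_log(lq)) +
      matrix(stats::rnorm(n_genes * length(lq), sd = noise_sd), n_genes, length(lq))
    mk <- function(vals, ages, sp, ds) {
      ids <- sprintf("%s_%02d", sp, seq_along(ages))
      dimnames(vals) <- list(gene_ids, ids)
      list(matrix = expression_matrix(vals),
           samples = as_sample_table(data.frame(
             sample_id = ids, dataset_id = ds, tissue = "cerebral cortex",
             group = sp, age = ages, stringsAsFactors = FALSE)))
    }
    truth <- list(a = a, b = b, offset_ref = offset_ref, offset_query = offset_query,
                  warp = function(t_query) exp(a + b * log(t_query + offset_query)) - offset_ref,
                  coefficients = coefs, noise_sd = noise_sd)
    list(ref = mk(ref_vals, ages_ref, "ref", "warp_ref"),
         query = mk(query_vals, ages_query, "query", "warp_query"),
         truth = truth)
  })
}

#' Simulate a probe/background fixture with known detectable transcripts
#'
#' Background (anti-genomic) probes populate a handful of GC bins; a chosen
#' fraction of transcripts has every probe intensity strictly above the
#' pooled 95th-percentile background threshold of its GC bin, the rest
#' strictly below, so the detectable set is recovered exactly.
#'
#' @param n_transcripts number of transcripts.
#' @param probes_per_transcript probes per transcript.
#' @param n_background background probes per GC bin (>= 20).
#' @param detect_fraction fraction of detectable transcripts.
#' @param n_samples samples (arrays).
#' @param quantile background quantile the fixture is constructed against.
#' @param seed RNG seed.
#' @return list with `probes`, `background` ([probe_table()]s) and
#'   `truth` (detectable transcript ids).
#' @export
simulate_probe_fixture <- function(n_transcripts = 20, probes_per_transcript = 12,
                                   n_background = 30, detect_fraction = 0.5,
                                   n_samples = 4, quantile = 0.95, seed = 1) {
  .stop_if_not_scalar_prob(detect_fraction, "detect_fraction")
  if (n_transcripts < 1 || probes_per_transcript < 1) stop("invalid sizes", call. = FALSE)
  if (n_background < 20) stop("need >= 20 background probes per GC bin", call. = FALSE)
  .with_seed(seed, {
    gc_bins <- 10:15
    bg_gc <- rep(gc_bins, each = n_background)
    bg_scale <- 2^(bg_gc / 3)  # hybridization background grows with GC
    bg_int <- matrix(stats::rlnorm(length(bg_gc) * n_samples, sdlog = 0.4),
                     length(bg_gc), n_samples) * bg_scale
    background <- probe_table(sprintf("bg%04d", seq_along(bg_gc)), bg_gc, bg_int)
    thr <- vapply(gc_bins, function(g) {
      stats::quantile(as.vector(bg_int[bg_gc == g, , drop = FALSE]),
                      probs = quantile, names = FALSE, type = 7)
    }, numeric(1))
    tx_ids <- sprintf("tx%03d", seq_len(n_transcripts))
    n_det <- round(detect_fraction * n_transcripts)
    detectable <- if (n_det > 0) sort(sample(tx_ids, n_det)) else character(0)
    n_probes <- n_transcripts * probes_per_transcript
    probe_gc <- sample(gc_bins, n_probes, replace = TRUE)
    probe_tx <- rep(tx_ids, each = probes_per_transcript)
    hi <- probe_tx %in% detectable
    bin_thr <- thr[match(probe_gc, gc_bins)]
    center <- ifelse(hi, bin_thr * stats::runif(n_probes, 1.6, 3),
                     bin_thr * stats::runif(n_probes, 0.2, 0.7))
    jitter <- matrix(exp(stats::rnorm(n_probes * n_samples, sd = 0.05)),
                     n_probes, n_samples)
    probes <- probe_table(sprintf("p%05d", seq_len(n_probes)), probe_gc,
                          center * jitter, transcript_id = probe_tx)
    list(probes = probes, background = background,
         truth = list(detectable = detectable, thresholds = stats::setNames(thr, gc_bins)))
  })
}
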