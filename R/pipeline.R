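# Pipeline orchestration: YAML configuration, seeded stage execution,
# provenance manifest.

.default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "preprocess", "effects", "compare", "cr_genes",
               "patterns", "modules", "pathways", "timeshift"),
    thresholds = list(age_alpha = 0.01, none_alpha = 0.1, fdr = 0.10,
                      min_genes = 5, min_corr = 0.5),
    permutations = list(B_meta = 100000, B_genes = 1000, B_module = 1000,
                        n_boot = 1000),
    synthetic = list(n_genes = 300, n_pairs = 4, rho = 0.5, n_a = 5, n_b = 5,
                     frac_affected = 0.2, d = 2, n_individuals = 15,
                     n_per_pattern = 10, n_sets = 10, query_age = 600,
                     warp_a = log(20), warp_b = 1),
    datasets = list(),
    pairs = list(),
    stage_windows = NULL
  )
}

.check_range <- function(cfg) {
  th <- cfg$thresholds
  for (nm in c("age_alpha", "none_alpha", "fdr")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop("range error: thresholds$", nm, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (th$min_genes < 0) stop("range error: thresholds$min_genes", call. = FALSE)
  if (th$min_corr < -1 || th$min_corr > 1) stop("range error: thresholds$min_corr", call. = FALSE)
  for (nm in names(cfg$permutations)) {
    v <- cfg$permutations[[nm]]
    if (!is.numeric(v) || v < 1) stop("range error: permutations$", nm, call. = FALSE)
  }
  invisible(cfg)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults (permutation counts
#' B_meta = 100000, B_genes = B_module = n_boot = 1000; gates 0.01 / 0.1;
#' FDR 0.10; min_genes 5; min_corr 0.5), rejects unknown keys, checks value
#' ranges, and verifies that every referenced dataset path exists.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized list of class `PipelineConfig`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a YAML file or a list", call. = FALSE)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (section in c("thresholds", "permutations", "synthetic")) {
    extra <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(extra)) {
      stop("unknown config key: ", section, "$", extra[1], call. = FALSE)
    }
    defaults[[section]][names(config[[section]])] <- config[[section]]
  }
  for (key in setdiff(names(config), c("thresholds", "permutations", "synthetic"))) {
    defaults[[key]] <- config[[key]]
  }
  cfg <- defaults
  .check_range(cfg)
  for (ds in cfg$datasets) {
    for (p in unlist(ds[grepl("^path", names(ds))])) {
      if (!file.exists(p)) stop("validation error: missing file '", p, "'", call. = FALSE)
    }
  }
  cfg$stage_windows <- if (is.null(cfg$stage_windows)) species_stage_config()
                       else species_stage_config(cfg$stage_windows)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

# Paired two-group datasets whose true per-gene effects are correlated rho
# across the pair (one "diet-like", one "species-like" dataset).
.simulate_effect_pair <- function(n_genes, rho, n_a, n_b, d_sd = 1,
                                  noise_sd = 1, seed = 1, pair_id = 1) {
  cc <- simulate_correlated_contrasts(n_genes, rho, seed = seed)
  make <- function(delta, ds, groups, sd_seed) {
    sim <- simulate_two_group(n_genes, n_a = n_a, n_b = n_b, frac_affected = 0,
                              noise_sd = noise_sd, seed = sd_seed,
                              groups = groups, dataset_id = ds)
    vals <- unclass(sim$matrix)
    vals[, seq_len(n_a)] <- vals[, seq_len(n_a)] + delta * d_sd * noise_sd
    sim$matrix <- expression_matrix(vals)
    sim
  }
  list(diet = make(cc$x, sprintf("C%d", pair_id), c("CR", "AL"),
                   .derive_seed(seed, paste0("diet", pair_id))),
       species = make(cc$y, sprintf("S%d", pair_id), c("human", "chimpanzee"),
                      .derive_seed(seed, paste0("species", pair_id))),
       truth = cc)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order (simulate ->
#' preprocess -> effects -> compare -> cr_genes -> patterns -> modules ->
#' pathways -> timeshift), writing each stage's outputs (TSV/JSON) into
#' `out_dir` together with a provenance manifest (per stage: derived seed,
#' outputs, md5 hashes). A single global seed expands deterministically into
#' per-stage seeds, so reruns with the same config are bit-identical. Any
#' stage failure halts the run with a stage-labeled error.
#'
#' With an empty `datasets` registry the run is fully synthetic, driven by
#' the `synthetic` config section; user datasets (paths to expression/sample
#' TSVs plus contrast groups) replace the simulated ones for the effects,
#' compare and cr_genes stages.
#'
#' @param config a [validate_config()] result, YAML path, or list.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly), also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("crosstx_run_")) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  state <- new.env(parent = emptyenv())
  syn <- cfg$synthetic
  th <- cfg$thresholds
  B <- cfg$permutations

  record <- function(stage, seed, outputs) {
    manifest[[stage]] <<- list(
      stage = stage, seed = seed, outputs = basename(outputs),
      md5 = unname(tools::md5sum(outputs)))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    seed <- .derive_seed(cfg$seed, stage)
    outputs <- tryCatch(fun(seed),
                        error = function(e) {
                          stop("stage '", stage, "' failed: ", conditionMessage(e),
                               call. = FALSE)
                        })
    record(stage, seed, outputs)
  }

  run_stage("simulate", function(seed) {
    outs <- character(0)
    if (length(cfg$datasets) == 0) {
      state$pairs <- lapply(seq_len(syn$n_pairs), function(k) {
        .simulate_effect_pair(syn$n_genes, syn$rho, syn$n_a, syn$n_b,
                              seed = .derive_seed(seed, paste0("pair", k)),
                              pair_id = k)
      })
      for (k in seq_along(state$pairs)) {
        for (side in c("diet", "species")) {
          f <- file.path(out_dir, sprintf("sim_%s_%d.tsv", side, k))
          write_expression_matrix(state$pairs[[k]][[side]]$matrix, f)
          outs <- c(outs, f)
        }
      }
    } else {
      state$user <- lapply(cfg$datasets, function(ds) {
        list(matrix = read_expression_matrix(ds$path_matrix),
             samples = read_sample_table(ds$path_samples),
             groups = c(ds$group_a, ds$group_b))
      })
    }
    state$cr <- simulate_two_group(syn$n_genes, n_a = 8, n_b = 7,
                                   frac_affected = syn$frac_affected, d = syn$d,
                                   seed = .derive_seed(seed, "cr"))
    state$ageseries <- simulate_age_series(
      n_per_pattern = stats::setNames(rep(syn$n_per_pattern, 4),
                                      c("P1", "P2", "P3", "flat")),
      config = cfg$stage_windows, n_individuals = syn$n_individuals,
      seed = .derive_seed(seed, "ageseries"))
    state$warp <- simulate_warped_pair(syn$warp_a, syn$warp_b,
                                       n_genes = max(60, syn$n_genes %/% 4),
                                       seed = .derive_seed(seed, "warp"))
    state$probe <- simulate_probe_fixture(seed = .derive_seed(seed, "probe"))
    # random gene sets over the two-group universe for the pathway screen
    ids <- rownames(state$cr$matrix)
    state$sets <- .with_seed(.derive_seed(seed, "sets"), {
      stats::setNames(lapply(seq_len(syn$n_sets), function(i) {
        sample(ids, sample(8:30, 1))
      }), sprintf("SET%02d", seq_len(syn$n_sets)))
    })
    gmt <- file.path(out_dir, "sim_sets.gmt")
    writeLines(vapply(names(state$sets), function(nm) {
      paste(c(nm, "synthetic", state$sets[[nm]]), collapse = "\t")
    }, character(1)), gmt)
    truth_file <- .write_json(list(cr_affected = state$cr$truth$affected,
                                   patterns = as.list(state$ageseries$truth$pattern),
                                   warp = list(a = syn$warp_a, b = syn$warp_b)),
                              file.path(out_dir, "sim_truth.json"))
    c(outs, gmt, truth_file)
  })

  run_stage("preprocess", function(seed) {
    mask <- detect_probes(state$probe$probes, state$probe$background)
    detectable <- detectable_transcripts(mask, state$probe$probes, min_detected = 7)
    norm <- log2_quantile_normalize(state$probe$probes$intensities)
    f1 <- file.path(out_dir, "detectable_transcripts.txt")
    writeLines(detectable, f1)
    f2 <- file.path(out_dir, "normalized_probes.tsv")
    write_expression_matrix(norm, f2)
    c(f1, f2)
  })

  get_datasets <- function() {
    if (!is.null(state$user)) return(state$user)
    unlist(lapply(state$pairs, function(p) {
      list(list(matrix = p$diet$matrix, samples = p$diet$samples,
                groups = p$diet$truth$groups),
           list(matrix = p$species$matrix, samples = p$species$samples,
                groups = p$species$truth$groups))
    }), recursive = FALSE)
  }

  run_stage("effects", function(seed) {
    ds <- get_datasets()
    state$effects <- lapply(ds, function(d) {
      contrast_effects(d$matrix, d$samples, d$groups[1], d$groups[2])
    })
    f <- file.path(out_dir, "effects.tsv")
    tab <- do.call(rbind, lapply(state$effects, function(e) {
      data.frame(dataset = e$dataset_id, contrast = e$label,
                 gene_id = names(e$d), d = unname(e$d))
    }))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("compare", function(seed) {
    ds <- get_datasets()
    pair_idx <- if (length(cfg$pairs)) cfg$pairs
                else lapply(seq_len(length(ds) %/% 2), function(k) c(2 * k - 1, 2 * k))
    meta <- permutation_meta_test(ds, pair_idx, B = B$B_meta, seed = seed)
    f1 <- file.path(out_dir, "comparisons.tsv")
    utils::write.table(meta$comparisons, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- .write_json(list(C_obs = meta$C_obs, n_pairs = meta$n_pairs,
                           B = meta$B, p_perm = meta$p_perm,
                           fdr_perm = meta$fdr_perm,
                           p_binomial = meta$p_binomial),
                      file.path(out_dir, "meta_test.json"))
    state$meta <- meta
    c(f1, f2)
  })

  run_stage("cr_genes", function(seed) {
    fdr <- permutation_fdr_genes(state$cr$matrix, state$cr$samples,
                                 groups = state$cr$truth$groups,
                                 target_fdr = th$fdr, B = B$B_genes, seed = seed)
    state$cr_result <- fdr
    f1 <- file.path(out_dir, "cr_genes.tsv")
    utils::write.table(data.frame(gene_id = names(fdr$p_observed),
                                  p = unname(fdr$p_observed),
                                  direction = unname(fdr$direction),
                                  affected = names(fdr$p_observed) %in% fdr$affected),
                       f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- .write_json(list(chosen_cutoff = fdr$chosen_cutoff,
                           n_affected = length(fdr$affected),
                           target_fdr = fdr$target_fdr, B = fdr$B),
                      file.path(out_dir, "cr_fdr.json"))
    c(f1, f2)
  })

  run_stage("patterns", function(seed) {
    calls <- classify_age_patterns(state$ageseries$datasets,
                                   config = cfg$stage_windows,
                                   age_alpha = th$age_alpha,
                                   none_alpha = th$none_alpha)
    state$patterns <- calls
    f <- file.path(out_dir, "pattern_calls.tsv")
    utils::write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("modules", function(seed) {
    p2 <- state$patterns$gene_id[state$patterns$label == "P2"]
    genes <- if (length(p2) >= 16) p2 else state$patterns$gene_id
    profiles <- trajectory_profiles(state$ageseries$datasets,
                                    config = cfg$stage_windows)
    profiles <- profiles[intersect(rownames(profiles), genes), , drop = FALSE]
    k <- min(8, max(2, nrow(profiles) %/% 5))
    mod <- cluster_modules(profiles, k = k, seed = seed)
    eff <- contrast_effects(state$cr$matrix, state$cr$samples,
                            state$cr$truth$groups[1], state$cr$truth$groups[2])
    shared <- intersect(names(mod$module), names(eff$d))
    tests <- lapply(seq_len(k), function(m) {
      g <- intersect(names(mod$module)[mod$module == m], shared)
      if (length(g) == 0) return(list(module = m, n = 0, p = NA))
      mt <- module_effect_test(g, eff, B = B$B_module,
                               seed = .derive_seed(seed, paste0("module", m)))
      list(module = m, n = length(g), observed = mt$observed, p = mt$p)
    })
    f <- .write_json(list(k = k, sizes = mod$sizes, tests = tests),
                     file.path(out_dir, "modules.json"))
    f
  })

  run_stage("pathways", function(seed) {
    eff_cr <- contrast_effects(state$cr$matrix, state$cr$samples,
                               state$cr$truth$groups[1], state$cr$truth$groups[2])
    ds <- get_datasets()
    eff_sp <- state$effects[[2]]
    screen <- suppressWarnings(
      pathway_correlation_screen(eff_cr, eff_sp, state$sets,
                                 min_genes = th$min_genes))
    f <- file.path(out_dir, "pathway_screen.tsv")
    utils::write.table(screen, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("timeshift", function(seed) {
    est <- corresponding_age(state$warp$ref, state$warp$query,
                             query_age = syn$query_age,
                             min_corr = th$min_corr, n_boot = B$n_boot,
                             seed = seed)
    f <- .write_json(list(query_age = est$query_age, estimate = est$estimate,
                          ci = est$ci, n_genes = est$n_genes),
                     file.path(out_dir, "timeshift.json"))
    f
  })

  manifest_file <- file.path(out_dir, "manifest.json")
  .write_json(unname(manifest), manifest_file)
  invisible(structure(list(out_dir = out_dir, manifest = manifest),
                      class = "PipelineRun"))
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  for (st in x$manifest) {
    cat(sprintf("  %-10s seed %-11d outputs: %s\n", st$stage, st$seed,
                paste(st$outputs, collapse = ", ")))
  }
  invisible(x)
}
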