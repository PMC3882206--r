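# Age-trajectory fitting and interpolation over species stage windows.

# Age-scale transform used for development-stage fits: log(age + offset),
# offset = 1 week on the human scale, scaled per species by lifespan ratio.
.log_age_offset <- function(lifespan_ratio = 1) (7 / 365.25) * lifespan_ratio

.transform_age <- function(ages, timescale, log_offset) {
  switch(timescale,
         "linear-age" = ages,
         "log-age" = log(ages + log_offset),
         stop("unknown timescale: ", timescale, call. = FALSE))
}

#' Fit a smooth trajectory of expression over age
#'
#' Default method is a cubic smoothing spline (`stats::smooth.spline`) with
#' target effective degrees of freedom `df` (3 by convention) on the chosen
#' age scale; development-stage data use log-transformed age, aging-stage
#' data linear age. `method = "polynomial"` instead fits an ordinary cubic
#' polynomial (exactly `df` non-intercept degrees of freedom), which
#' reproduces a noiseless polynomial of degree <= `df` exactly. Queries
#' outside the observed age range are rejected.
#'
#' @param ages observed ages (years), >= `df + 2` distinct values.
#' @param values expression values (log2 scale), same length.
#' @param timescale `"log-age"` or `"linear-age"`.
#' @param df target degrees of freedom for the smoother (default 3).
#' @param method `"smoothing"` (penalized spline) or `"polynomial"`.
#' @param log_offset offset added to age before the log transform
#'   (default: one human week; scale by lifespan ratio across species).
#' @return object of class `TrajectoryFit`; query it with `predict()`.
#' @export
fit_trajectory <- function(ages, values, timescale = c("log-age", "linear-age"),
                           df = 3, method = c("smoothing", "polynomial"),
                           log_offset = .log_age_offset()) {
  timescale <- match.arg(timescale)
  method <- match.arg(method)
  if (length(ages) != length(values)) stop("ages and values must align", call. = FALSE)
  if (length(unique(ages)) < df + 2) {
    stop("insufficient distinct ages: need >= df + 2", call. = FALSE)
  }
  t <- .transform_age(ages, timescale, log_offset)
  constant <- stats::sd(values) < 1e-12
  fit <- if (constant) {
    list(kind = "constant", value = mean(values))
  } else if (method == "polynomial") {
    X <- outer(t, seq_len(df), `^`)
    list(kind = "polynomial", coef = stats::lm.fit(cbind(1, X), values)$coefficients)
  } else {
    ss <- stats::smooth.spline(t, values, df = df, cv = FALSE)
    list(kind = "smoothing", spline = ss, edf = ss$df)
  }
  structure(list(fit = fit, timescale = timescale, df = df, method = method,
                 log_offset = log_offset, age_range = range(ages)),
            class = "TrajectoryFit")
}

#' Interpolate a fitted trajectory at new ages
#'
#' @param object a [fit_trajectory()] result.
#' @param ages query ages (years) within the observed range.
#' @param ... unused.
#' @return numeric vector of interpolated expression values.
#' @export
predict.TrajectoryFit <- function(object, ages, ...) {
  rng <- object$age_range
  if (any(ages < rng[1] - 1e-9 | ages > rng[2] + 1e-9)) {
    stop("extrapolation: query age outside the observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  t <- .transform_age(ages, object$timescale, object$log_offset)
  f <- object$fit
  switch(f$kind,
         constant = rep(f$value, length(ages)),
         polynomial = drop(cbind(1, outer(t, seq_len(object$df), `^`)) %*% f$coef),
         smoothing = stats::predict(f$spline, t)$y)
}

#' @export
print.TrajectoryFit <- function(x, ...) {
  cat(sprintf("TrajectoryFit (%s, %s): ages %.3g-%.3g, target df %g\n",
              x$fit$kind, x$timescale, x$age_range[1], x$age_range[2], x$df))
  invisible(x)
}

#' Ten query ages spanning a species stage window
#'
#' The stage interval is divided into 10 equal subintervals; by default the
#' query ages are the subinterval midpoints (which avoids evaluating at age 0
#' on the log scale). `rule = "endpoint"` instead returns an
#' endpoint-inclusive equally spaced grid.
#'
#' @param config [species_stage_config()].
#' @param species species name present in the config.
#' @param stage `"development"` or `"aging"`.
#' @param rule `"midpoint"` (default) or `"endpoint"`.
#' @return object of class `StageGrid`: list with `species`, `stage`, `ages`.
#' @export
stage_grid <- function(config, species, stage, rule = c("midpoint", "endpoint")) {
  rule <- match.arg(rule)
  if (!species %in% names(config)) stop("unknown species: ", species, call. = FALSE)
  iv <- config[[species]][[stage]]
  if (is.null(iv)) stop("unknown stage: ", stage, call. = FALSE)
  if (any(is.na(iv)) || iv[2] <= iv[1]) stop("degenerate stage interval", call. = FALSE)
  ages <- if (rule == "midpoint") {
    iv[1] + (2 * seq_len(10) - 1) / 20 * diff(iv)
  } else {
    seq(iv[1], iv[2], length.out = 10)
  }
  structure(list(species = species, stage = stage, ages = ages, rule = rule),
            class = "StageGrid")
}

.stage_timescale <- function(stage) {
  if (stage == "development") "log-age" else "linear-age"
}

#' Cross-species effect sizes from interpolated age trajectories
#'
#' For every shared gene, each species' trajectory is fitted on the stage's
#' time scale (log age for development, linear age for aging) from the
#' samples inside the stage window, interpolated at that species' 10-point
#' stage grid, and the two 10-point vectors are compared with [cohens_d()]
#' (n = 10 per species). Interpolation removes inter-individual variation
#' while retaining variation across age.
#'
#' @param data_a,data_b per-species datasets: lists with `matrix` and
#'   `samples` (sample table with `age`).
#' @param species_a,species_b species names in `config`.
#' @param stage `"development"` or `"aging"`.
#' @param config [species_stage_config()].
#' @param df smoother degrees of freedom (default 3).
#' @param method trajectory fitting method, see [fit_trajectory()].
#' @param rule stage-grid placement rule, see [stage_grid()].
#' @return a `ContrastEffect` (label `"species_a-vs-species_b"`).
#' @export
stage_effect <- function(data_a, data_b, species_a, species_b, stage,
                         config = species_stage_config(), df = 3,
                         method = "smoothing", rule = "midpoint") {
  timescale <- .stage_timescale(stage)
  human_lifespan <- config[["human"]]$aging[2]
  one <- function(data, species) {
    iv <- config[[species]][[stage]]
    samples <- data$samples
    keep <- !is.na(samples$age) & samples$age >= iv[1] & samples$age <= iv[2]
    if (sum(keep) < df + 2) {
      stop("species '", species, "' has < df + 2 samples in the ", stage,
           " window", call. = FALSE)
    }
    ids <- samples$sample_id[keep]
    ages <- samples$age[keep]
    offset <- .log_age_offset(config[[species]]$aging[2] / human_lifespan)
    grid <- stage_grid(config, species, stage, rule)$ages
    vals <- unclass(data$matrix)[, match(ids, colnames(data$matrix)), drop = FALSE]
    interp <- t(apply(vals, 1, function(v) {
      fit <- fit_trajectory(ages, v, timescale = timescale, df = df,
                            method = method, log_offset = offset)
      stats::predict(fit, pmin(pmax(grid, min(ages)), max(ages)))
    }))
    rownames(interp) <- rownames(data$matrix)
    interp
  }
  ia <- one(data_a, species_a)
  ib <- one(data_b, species_b)
  shared <- intersect(rownames(ia), rownames(ib))
  if (length(shared) < 1) stop("no shared genes", call. = FALSE)
  both <- cbind(ia[shared, , drop = FALSE], ib[shared, , drop = FALSE])
  d <- .row_cohens_d(both, 1:10, 11:20)
  names(d) <- shared
  excluded <- is.na(d)
  structure(list(label = paste0(species_a, "-vs-", species_b),
                 d = d[!excluded], n_a = 10, n_b = 10,
                 dataset_id = paste(data_a$samples$dataset_id[1],
                                    data_b$samples$dataset_id[1], sep = "+"),
                 tissue = data_a$samples$tissue[1],
                 n_zero_sd = sum(excluded)),
            class = "ContrastEffect")
}
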