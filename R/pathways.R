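#' Gene-set correlation screen between two effect-size vectors
#'
#' For every gene set with more than `min_genes` usable genes (members
#' present in both effect vectors; switch to nominal set size with
#' `count = "nominal"`), correlates the two per-gene effect sizes across the
#' member genes (Pearson, two-sided t-based p) and applies Bonferroni
#' correction over the number of sets tested. The strict "more than"
#' filter means a set with exactly `min_genes` usable genes is not tested.
#'
#' @param x,y `ContrastEffect` objects or named numeric effect vectors
#'   sharing a gene universe (map orthologs upstream).
#' @param sets a [read_gene_sets()] collection (or named list of gene ids).
#' @param min_genes sets need strictly more than this many genes (default 5).
#' @param alpha significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @param count count `"usable"` genes (default) or `"nominal"` set size
#'   for the `min_genes` filter.
#' @return `data.frame` of class `PathwayScreenResult`, sorted by adjusted
#'   p: `set`, `n_genes`, `r`, `p`, `p_adjusted`, `significant`. Zero rows
#'   (with a warning) when no set qualifies.
#' @export
pathway_correlation_screen <- function(x, y, sets, min_genes = 5, alpha = 0.05,
                                       count = c("usable", "nominal")) {
  count <- match.arg(count)
  dx <- .effect_vector(x); dy <- .effect_vector(y)
  universe <- intersect(names(dx), names(dy))
  usable <- lapply(sets, function(g) intersect(unique(g), universe))
  n_filter <- if (count == "usable") lengths(usable) else lengths(sets)
  keep <- n_filter > min_genes & lengths(usable) >= 3
  if (!any(keep)) {
    warning("no gene set passes the size filter", call. = FALSE)
    out <- data.frame(set = character(0), n_genes = integer(0), r = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0))
    class(out) <- c("PathwayScreenResult", "data.frame")
    return(out)
  }
  tested <- sort(names(sets)[keep])
  n_tested <- length(tested)
  rows <- lapply(tested, function(nm) {
    g <- usable[[nm]]
    rp <- .pearson_rp(dx[g], dy[g])
    data.frame(set = nm, n_genes = length(g), r = rp[["r"]], p = rp[["p"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * n_tested)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PathwayScreenResult", "data.frame")
  out
}
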