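#' Construct a probe intensity table
#'
#' Linear-scale probe intensities with GC content, used by the detectability
#' filter. `transcript_id` is `NULL` for background (anti-genomic) probes.
#'
#' @param probe_id character vector of unique probe ids.
#' @param gc integer G+C base count per probe (>= 0).
#' @param intensities numeric matrix, probes x samples, strictly positive.
#' @param transcript_id optional transcript id per probe.
#' @return list of class `ProbeTable` (or `BackgroundTable` if no
#'   `transcript_id`).
#' @export
probe_table <- function(probe_id, gc, intensities, transcript_id = NULL) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("duplicate probe id", call. = FALSE)
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(probe_id) || length(gc) != length(probe_id)) {
    stop("probe_id, gc and intensity rows must align", call. = FALSE)
  }
  if (any(gc < 0)) stop("gc_content must be >= 0", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("intensities must be finite and > 0", call. = FALSE)
  }
  rownames(intensities) <- probe_id
  out <- list(probe_id = probe_id, gc = as.integer(gc), intensities = intensities,
              transcript_id = if (!is.null(transcript_id)) as.character(transcript_id))
  class(out) <- c(if (is.null(transcript_id)) "BackgroundTable" else "ProbeTable", "list")
  out
}

#' Read a probe (or background) table from TSV
#'
#' Columns: `probe_id`, `transcript_id` (omitted for background tables),
#' `gc`, then one column per sample.
#'
#' @param path file path.
#' @param background if `TRUE`, no `transcript_id` column is expected.
#' @return a [probe_table()].
#' @export
read_probe_table <- function(path, background = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  meta <- if (background) c("probe_id", "gc") else c("probe_id", "transcript_id", "gc")
  missing <- setdiff(meta, names(df))
  if (length(missing)) stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  ints <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  probe_table(df$probe_id, df$gc, ints,
              transcript_id = if (!background) df$transcript_id)
}

#' Detectability call per probe against GC-matched background
#'
#' A probe is called detected when its intensity exceeds (strictly) the
#' `quantile` quantile of the pooled intensities of background probes with
#' the same GC content. By default the probe's mean intensity across samples
#' is compared once per probe; with `per_sample = TRUE` a logical matrix of
#' per-sample calls is returned instead. Quantiles use the linear
#' interpolation rule (`stats::quantile`, type 7). Background bins with
#' fewer than `min_background` probes are unusable.
#'
#' @param probes [probe_table()] with transcript ids.
#' @param background [probe_table()] of anti-genomic probes.
#' @param quantile background quantile defining the detection threshold.
#' @param per_sample compare each sample's intensity separately.
#' @param min_background minimum background probes per GC bin (default 20).
#' @return logical vector named by probe id (or probes x samples matrix when
#'   `per_sample = TRUE`).
#' @export
detect_probes <- function(probes, background, quantile = 0.95,
                          per_sample = FALSE, min_background = 20L) {
  .stop_if_not_scalar_prob(quantile, "quantile")
  need <- unique(probes$gc)
  thresholds <- vapply(need, function(g) {
    rows <- background$gc == g
    if (!any(rows)) stop("no background probes for GC bin ", g, call. = FALSE)
    if (sum(rows) < min_background) {
      stop("GC bin ", g, " unusable: fewer than ", min_background,
           " background probes", call. = FALSE)
    }
    stats::quantile(as.vector(background$intensities[rows, , drop = FALSE]),
                    probs = quantile, names = FALSE, type = 7)
  }, numeric(1))
  thr <- thresholds[match(probes$gc, need)]
  if (per_sample) {
    out <- probes$intensities > thr
    rownames(out) <- probes$probe_id
    return(out)
  }
  out <- rowMeans(probes$intensities) > thr
  names(out) <- probes$probe_id
  out
}

#' Transcripts with more than `min_detected` detected probes
#'
#' The inclusion rule is strict: a transcript needs strictly more than
#' `min_detected` detected probes (10 for the human exon array convention,
#' 7 for the mouse gene array convention).
#'
#' @param mask logical vector of per-probe detection calls, named by probe id.
#' @param probes [probe_table()] supplying the probe-to-transcript mapping.
#' @param min_detected integer >= 1.
#' @return sorted character vector of detectable transcript ids.
#' @export
detectable_transcripts <- function(mask, probes, min_detected) {
  stopifnot(min_detected >= 1)
  if (length(mask) == 0 || !any(mask)) return(character(0))
  mask <- mask[probes$probe_id]
  counts <- tapply(as.integer(mask), probes$transcript_id, sum)
  sort(names(counts)[counts > min_detected])
}

#' Log2 transform and quantile normalize a linear-intensity matrix
#'
#' Each column's sorted values are replaced by the across-column mean of the
#' sorted log2 values; ties within a column receive the mean of the reference
#' values over the tied rank span (delegated to
#' \code{limma::normalizeQuantiles(ties = TRUE)}). The operation is
#' idempotent and makes the value multiset identical in every column.
#'
#' @param x numeric matrix of strictly positive linear intensities.
#' @param namespace namespace tag for the returned matrix.
#' @return an [expression_matrix()] on the log2 scale.
#' @export
log2_quantile_normalize <- function(x, namespace = "gene") {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x <= 0)) stop("non-positive value", call. = FALSE)
  out <- limma::normalizeQuantiles(log2(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (is.null(rownames(out))) rownames(out) <- paste0("g", seq_len(nrow(out)))
  if (is.null(colnames(out))) colnames(out) <- paste0("s", seq_len(ncol(out)))
  expression_matrix(out, namespace = namespace)
}
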