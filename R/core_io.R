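#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns, log2 scale) carrying unique row and column identifiers and a
#' `namespace` attribute naming the gene-ID system. All values must be finite;
#' stages that cannot handle missing values rely on this invariant.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (default: `colnames(values)`).
#' @param namespace tag naming the gene-ID system (e.g. `"ensembl_human"`).
#' @return a numeric matrix of class `ExpressionMatrix` with a
#'   `namespace` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              namespace = "gene") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || length(gene_ids) != nrow(values)) {
    stop("gene_ids must match the number of rows", call. = FALSE)
  }
  if (is.null(sample_ids) || length(sample_ids) != ncol(values)) {
    stop("sample_ids must match the number of columns", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene id", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample id", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite expression values", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "namespace") <- namespace
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (namespace: %s)\n",
              nrow(x), ncol(x), attr(x, "namespace")))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0) "\t" else if (n_com > 0) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects one header row of sample ids and a first column of gene ids.
#' The delimiter is auto-detected (tab or comma). Duplicate gene ids and
#' non-numeric cells are errors, never silently repaired.
#'
#' @param path file path.
#' @param genes_in_rows if `FALSE` the file is transposed on read.
#' @param namespace gene-ID namespace tag attached to the result.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, genes_in_rows = TRUE, namespace = "gene") {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header: need gene-id column plus samples", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene id: ", ids[duplicated(ids)][1], call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) | trimws(vals) == ""
  if (any(bad)) {
    stop("non-numeric value at gene '", ids[which(bad, arr.ind = TRUE)[1, 1]], "'",
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (!genes_in_rows) num <- t(num)
  expression_matrix(num, namespace = namespace)
}

#' Write an expression matrix as TSV with full double precision
#'
#' Values are formatted with `%.17g` so that a read/write round trip is
#' bit-exact for finite doubles.
#'
#' @param x expression matrix (or plain numeric matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", unclass(x)[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

.known_tissues <- c("cerebral cortex", "heart", "liver", "other")

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `dataset_id`, `tissue`, `group`; `age`
#' (years) is optional. Unknown tissue labels are mapped to `"other"` with a
#' warning; duplicate sample ids and negative ages are errors.
#'
#' @param path delimited text file (tab or comma).
#' @return a `data.frame` of class `SampleTable`.
#' @export
read_sample_table <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  as_sample_table(df)
}

#' Validate a sample metadata data.frame
#' @param df data.frame with columns `sample_id`, `dataset_id`, `tissue`,
#'   `group` and optionally `age`.
#' @return the validated `data.frame`, tissue normalized, class `SampleTable`.
#' @export
as_sample_table <- function(df) {
  required <- c("sample_id", "dataset_id", "tissue", "group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  }
  unknown <- !(df$tissue %in% .known_tissues)
  if (any(unknown)) {
    warning("unknown tissue label(s) mapped to 'other': ",
            paste(unique(df$tissue[unknown]), collapse = ", "), call. = FALSE)
    df$tissue[unknown] <- "other"
  }
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    if (any(!is.na(df$age) & df$age < 0)) stop("negative age", call. = FALSE)
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Members are de-duplicated within a set; empty sets are dropped with a
#' warning; a line with fewer than 3 fields is an error.
#'
#' @param path GMT file path.
#' @param namespace gene-ID namespace tag.
#' @return a named list of character vectors of class `GeneSetCollection`,
#'   with attributes `namespace` and `descriptions`.
#' @export
read_gene_sets <- function(path, namespace = "gene") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("unreadable GMT line (fewer than 3 fields): line ", which(short)[1], call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) stop("duplicate gene-set name", call. = FALSE)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    members <- trimws(f[-(1:2)])
    unique(members[nzchar(members)])
  })
  names(sets) <- names_
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping empty gene set(s): ", paste(names_[empty], collapse = ", "),
            call. = FALSE)
    sets <- sets[!empty]; desc <- desc[!empty]
  }
  structure(sets, namespace = namespace, descriptions = desc,
            class = c("GeneSetCollection", "list"))
}

#' Read a two-column ortholog map
#'
#' TSV with columns source id, target id; an optional header line
#' `source<TAB>target` is recognised. The map must be strictly one-to-one.
#'
#' @param path file path.
#' @return `data.frame` with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- identical(tolower(first), c("source", "target"))
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          col.names = c("source", "target"),
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  validate_ortholog_map(df)
}

validate_ortholog_map <- function(map) {
  if (!all(c("source", "target") %in% names(map))) {
    stop("ortholog map needs 'source' and 'target' columns", call. = FALSE)
  }
  if (anyDuplicated(map$source)) stop("ortholog map not one-to-one: duplicated source id", call. = FALSE)
  if (anyDuplicated(map$target)) stop("ortholog map not one-to-one: duplicated target id", call. = FALSE)
  map
}

#' Map an expression matrix through a one-to-one ortholog table
#'
#' Rows without a mapping are dropped (and counted in the attached report);
#' remaining rows are renamed to target ids and sorted target-id
#' lexicographically (C locale).
#'
#' @param matrix an [expression_matrix()].
#' @param map `data.frame` with `source`/`target` columns (one-to-one).
#' @param target_namespace namespace tag for the renamed result.
#' @return an `ExpressionMatrix` in the target namespace; attribute
#'   `mapping_report` holds `n_dropped` and `n_mapped`.
#' @export
map_orthologs <- function(matrix, map, target_namespace = "target") {
  map <- validate_ortholog_map(map)
  idx <- match(rownames(matrix), map$source)
  keep <- !is.na(idx)
  n_dropped <- sum(!keep)
  out <- unclass(matrix)[keep, , drop = FALSE]
  rownames(out) <- map$target[idx[keep]]
  ord <- order(rownames(out), method = "radix")
  out <- out[ord, , drop = FALSE]
  res <- expression_matrix(out, namespace = target_namespace)
  attr(res, "mapping_report") <- list(n_dropped = n_dropped, n_mapped = sum(keep))
  res
}

#' Species stage windows and conception offsets
#'
#' Developmental and aging intervals in years per species, plus gestation
#' length in days used to convert postnatal to conception age. Defaults are
#' the primate windows used throughout: development 0-20 y (human), 0-12 y
#' (chimpanzee), 0-6 y (macaque); aging 20-98 / 12-54 / 6-27 y; gestation
#' 280 d (human) and 19 d (mouse). Development must end where aging begins.
#'
#' @param windows optional named list per species with elements
#'   `development = c(start, end)`, `aging = c(start, end)` and
#'   `conception_offset_days` (may be `NA`).
#' @return a list of class `SpeciesStageConfig`.
#' @export
species_stage_config <- function(windows = NULL) {
  default <- list(
    human      = list(development = c(0, 20), aging = c(20, 98), conception_offset_days = 280),
    chimpanzee = list(development = c(0, 12), aging = c(12, 54), conception_offset_days = NA_real_),
    macaque    = list(development = c(0, 6),  aging = c(6, 27),  conception_offset_days = NA_real_),
    mouse      = list(development = c(0, 0.16), aging = c(0.16, 2.5), conception_offset_days = 19)
  )
  cfg <- if (is.null(windows)) default else windows
  for (sp in names(cfg)) {
    w <- cfg[[sp]]
    if (is.null(w$conception_offset_days)) cfg[[sp]]$conception_offset_days <- NA_real_
    dev <- w$development; ag <- w$aging
    if (is.null(dev) || is.null(ag)) next
    if (dev[2] <= dev[1] || ag[2] <= ag[1]) {
      stop("empty stage interval for species '", sp, "'", call. = FALSE)
    }
    if (!isTRUE(all.equal(dev[2], ag[1]))) {
      stop("development must end where aging begins for species '", sp, "'", call. = FALSE)
    }
  }
  structure(cfg, class = c("SpeciesStageConfig", "list"))
}
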