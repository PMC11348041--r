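# Tissue x gene expression matrices in three dialects, and the
# low/medium/high expression filters applied to them.

#' Supported expression dataset dialects
#'
#' @details
#' * `rna_tpm`: RNA-seq abundance in transcripts per million (TPM).
#' * `protein_ppb`: quantitative proteomics abundance in parts per billion.
#' * `protein_semiquant`: semi-quantitative proteomics with ordinal levels
#'   1 (low), 2 (medium), 3 (high).
#' @export
expression_dialects <- c("rna_tpm", "protein_ppb", "protein_semiquant")

#' Filter stringency levels, ordered none < low < medium < high
#' @export
filter_levels <- c("none", "low", "medium", "high")

#' Default expression filter thresholds for a dialect
#'
#' A gene survives a filter level only when its expression value is
#' strictly greater than the level's threshold. Defaults are 0.5/1/5 TPM
#' for RNA-seq and 500/1000/1500 ppb for quantitative proteomics.
#' Semi-quantitative data use their ordinal levels directly and take no
#' numeric thresholds.
#'
#' @param dialect one of [expression_dialects]
#' @return named list with elements `low`, `medium`, `high` (or `NULL` for
#'   the semi-quantitative dialect)
#' @export
default_thresholds <- function(dialect) {
  dialect <- match.arg(dialect, expression_dialects)
  switch(dialect,
    rna_tpm = list(low = 0.5, medium = 1, high = 5),
    protein_ppb = list(low = 500, medium = 1000, high = 1500),
    protein_semiquant = NULL
  )
}

validate_thresholds <- function(thresholds) {
  if (is.null(thresholds)) return(invisible(NULL))
  stopifnot(all(c("low", "medium", "high") %in% names(thresholds)))
  if (!(thresholds$low < thresholds$medium && thresholds$medium < thresholds$high)) {
    rlang::abort("thresholds must satisfy low < medium < high",
                 class = "tissuetox_threshold_error")
  }
  invisible(NULL)
}

#' Construct an expression dataset
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   tissues in columns (colnames = tissue names). `NA` marks a cell that
#'   was not measured, which is distinct from an expression value of 0.
#'   For the semi-quantitative dialect all measured values must be in
#'   \{1, 2, 3\}.
#' @param dialect one of [expression_dialects]
#' @param dataset_id free-text dataset label
#' @param gene_names optional named character vector of display names
#' @param thresholds filter thresholds; defaults per dialect
#' @return an `expression_dataset` object
#' @export
expression_dataset <- function(values, dialect, dataset_id = "unnamed",
                               gene_names = NULL, thresholds = NULL) {
  dialect <- match.arg(dialect, expression_dialects)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    rlang::abort("duplicate gene ids in expression matrix",
                 class = "tissuetox_load_error")
  }
  if (anyDuplicated(colnames(values))) {
    rlang::abort("duplicate tissue names in expression matrix",
                 class = "tissuetox_load_error")
  }
  measured <- values[!is.na(values)]
  if (dialect == "protein_semiquant") {
    if (!all(measured %in% c(1, 2, 3))) {
      rlang::abort("semi-quantitative values must be 1, 2 or 3",
                   class = "tissuetox_load_error")
    }
  } else if (any(measured < 0)) {
    rlang::abort("expression values must be non-negative",
                 class = "tissuetox_load_error")
  }
  if (is.null(thresholds)) thresholds <- default_thresholds(dialect)
  validate_thresholds(thresholds)
  structure(
    list(
      dataset_id = dataset_id,
      dialect = dialect,
      tissues = colnames(values),
      genes = rownames(values),
      gene_names = gene_names,
      values = values,
      thresholds = thresholds
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %s (%s): %d genes x %d tissues\n",
    x$dataset_id, x$dialect, length(x$genes), length(x$tissues)
  ))
  invisible(x)
}

#' Number of genes in an expression dataset
#' @param dataset an `expression_dataset`
#' @export
gene_count <- function(dataset) length(dataset$genes)

semiquant_words <- c(low = 1, medium = 2, high = 3)

#' Load a tissue x gene expression matrix from TSV
#'
#' Expected layout: a header row, first column `GeneID`, an optional
#' second column `GeneName`, and one column per tissue. Empty cells mean
#' "not measured" and are kept distinct from 0. Semi-quantitative cells
#' may be the words low/medium/high (any case) or the digits 1/2/3.
#'
#' @param path TSV file (plain or gzip)
#' @param dialect one of [expression_dialects]
#' @param dataset_id label; defaults to the file name
#' @param thresholds optional threshold override
#' @return an [expression_dataset()]
#' @export
load_expression_matrix <- function(path, dialect, dataset_id = NULL,
                                   thresholds = NULL) {
  dialect <- match.arg(dialect, expression_dialects)
  if (is.null(dataset_id)) dataset_id <- tools::file_path_sans_ext(basename(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 2) {
    rlang::abort(sprintf("malformed header in %s: need a gene id column and >= 1 tissue column", path),
                 class = "tissuetox_load_error")
  }
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids)) {
    rlang::abort(sprintf("duplicate gene id '%s' in %s", gene_ids[duplicated(gene_ids)][1], path),
                 class = "tissuetox_load_error")
  }
  has_name_col <- tolower(names(raw)[2]) %in% c("genename", "gene_name", "name")
  gene_names <- NULL
  if (has_name_col) gene_names <- stats::setNames(raw[[2]], gene_ids)
  tissue_cols <- names(raw)[(if (has_name_col) 3L else 2L):ncol(raw)]
  if (length(tissue_cols) == 0) {
    rlang::abort(sprintf("malformed header in %s: no tissue columns", path),
                 class = "tissuetox_load_error")
  }

  parse_cell <- function(cell, gene, tissue) {
    if (is.na(cell) || cell == "") return(NA_real_)
    if (dialect == "protein_semiquant") {
      word <- tolower(trimws(cell))
      if (word %in% names(semiquant_words)) return(unname(semiquant_words[word]))
      if (word %in% c("1", "2", "3")) return(as.numeric(word))
      rlang::abort(sprintf("unknown expression level '%s' at gene %s, tissue %s",
                           cell, gene, tissue),
                   class = "tissuetox_load_error")
    }
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      rlang::abort(sprintf("non-numeric expression value '%s' at gene %s, tissue %s",
                           cell, gene, tissue),
                   class = "tissuetox_load_error")
    }
    if (v < 0) {
      rlang::abort(sprintf("negative expression value %s at gene %s, tissue %s",
                           cell, gene, tissue),
                   class = "tissuetox_load_error")
    }
    v
  }

  values <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(tissue_cols),
                   dimnames = list(gene_ids, tissue_cols))
  for (j in seq_along(tissue_cols)) {
    col <- raw[[tissue_cols[j]]]
    for (i in seq_along(gene_ids)) {
      values[i, j] <- parse_cell(col[i], gene_ids[i], tissue_cols[j])
    }
  }
  expression_dataset(values, dialect, dataset_id = dataset_id,
                     gene_names = gene_names, thresholds = thresholds)
}

#' Write an expression dataset back to TSV
#'
#' Inverse of [load_expression_matrix()]: reloading the written file
#' reproduces identical filter decisions.
#'
#' @param dataset an `expression_dataset`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(dataset, path) {
  df <- tibble::as_tibble(dataset$values, rownames = "GeneID")
  if (!is.null(dataset$gene_names)) {
    df <- tibble::add_column(df, GeneName = unname(dataset$gene_names[df$GeneID]),
                             .after = "GeneID")
  }
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Does an expression value survive a filter level?
#'
#' Boundary semantics are exclusive for the numeric dialects: a value
#' exactly equal to the level's threshold does NOT pass (a 0.5 TPM gene
#' is a low-expression gene under the default RNA-seq thresholds). For
#' semi-quantitative data the `low` filter retains ordinal levels
#' \{2, 3\} and the `medium` and `high` filters both retain level \{3\}.
#' `level = "none"` passes every measured value. Unmeasured values (`NA`)
#' never pass any level other than `none` under the default
#' missing-value policy; see [genes_passing_filter()].
#'
#' @param value numeric vector of expression values (`NA` = not measured)
#' @param level one of [filter_levels]
#' @param thresholds list with `low`/`medium`/`high` (numeric dialects)
#' @param dialect one of [expression_dialects]
#' @return logical vector
#' @export
passes_filter <- function(value, level, thresholds = NULL,
                          dialect = "rna_tpm") {
  level <- match.arg(level, filter_levels)
  dialect <- match.arg(dialect, expression_dialects)
  measured <- !is.na(value)
  if (level == "none") return(measured)
  if (dialect == "protein_semiquant") {
    cutoff <- if (level == "low") 2 else 3
    return(measured & !is.na(value) & value >= cutoff)
  }
  if (is.null(thresholds)) thresholds <- default_thresholds(dialect)
  validate_thresholds(thresholds)
  measured & value > thresholds[[level]]
}

assert_tissue <- function(dataset, tissue) {
  if (!tissue %in% dataset$tissues) {
    rlang::abort(sprintf("unknown tissue '%s'; available tissues: %s",
                         tissue, paste(dataset$tissues, collapse = ", ")),
                 class = "tissuetox_tissue_error")
  }
  invisible(NULL)
}

#' Genes surviving an expression filter in one tissue
#'
#' @param dataset an `expression_dataset`
#' @param tissue tissue name present in the dataset
#' @param level one of [filter_levels]; `"none"` returns all genes
#'   measured in the tissue
#' @param thresholds optional threshold override (defaults to the
#'   dataset's own)
#' @return character vector of gene ids
#' @export
genes_passing_filter <- function(dataset, tissue, level,
                                 thresholds = NULL) {
  assert_tissue(dataset, tissue)
  if (is.null(thresholds)) thresholds <- dataset$thresholds
  col <- dataset$values[, tissue]
  keep <- passes_filter(col, level, thresholds, dataset$dialect)
  dataset$genes[keep]
}

#' Per-tissue summary of log-transformed expression values
#'
#' Computes min, quartiles and max of `log10(value + pseudocount)` per
#' tissue over measured values. The pseudocount (default 0.01) avoids an
#' invalid logarithm of zero; it affects only this summary, never the
#' filters, which operate on raw values.
#'
#' @param dataset a numeric-dialect `expression_dataset`
#' @param pseudocount small positive number added before the log
#' @return tibble with columns tissue, n, min, q1, median, q3, max
#' @export
log_summary <- function(dataset, pseudocount = 0.01) {
  if (dataset$dialect == "protein_semiquant") {
    rlang::abort("log_summary is not defined for semi-quantitative data",
                 class = "tissuetox_dialect_error")
  }
  purrr::map_dfr(dataset$tissues, function(ts) {
    v <- dataset$values[, ts]
    v <- log10(v[!is.na(v)] + pseudocount)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(tissue = ts, n = length(v), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  })
}

#' Percentile of measured expression values at or below a threshold
#'
#' Returns `100 * (# measured values <= threshold) / (# measured values)`
#' for one tissue, i.e. the percentage of genes a strictly-greater-than
#' filter at that threshold would remove.
#'
#' @param dataset a numeric-dialect `expression_dataset`
#' @param tissue tissue name
#' @param threshold numeric threshold on the raw scale
#' @return a number in `[0, 100]`
#' @export
threshold_percentile <- function(dataset, tissue, threshold) {
  if (dataset$dialect == "protein_semiquant") {
    rlang::abort("threshold_percentile is not defined for semi-quantitative data",
                 class = "tissuetox_dialect_error")
  }
  assert_tissue(dataset, tissue)
  v <- dataset$values[, tissue]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  100 * sum(v <= threshold) / length(v)
}
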