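# Chemical-protein interaction tables (STITCH-style TSV with a
# combined confidence score scaled 0-1000).

#' Construct an interaction table
#'
#' @param records tibble/data frame with columns `chemical`, `protein`,
#'   `score` (integer 0-1000). Duplicate (chemical, protein) pairs are
#'   collapsed keeping the maximum score.
#' @return an `interaction_table` object
#' @export
interaction_table <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("chemical", "protein", "score") %in% names(records)))
  if (any(is.na(records$score)) || any(records$score < 0 | records$score > 1000)) {
    rlang::abort("interaction scores must be integers in [0, 1000]",
                 class = "tissuetox_load_error")
  }
  records <- records |>
    dplyr::group_by(.data$chemical, .data$protein) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$chemical, .data$protein)
  structure(list(records = records), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d interactions, %d chemicals, %d proteins\n",
              nrow(x$records), dplyr::n_distinct(x$records$chemical),
              dplyr::n_distinct(x$records$protein)))
  invisible(x)
}

#' Load a chemical-protein interaction TSV
#'
#' Expects columns `chemical`, `protein` and `combined_score` (or
#' `score`); extra columns are ignored. Gzip input is accepted. An
#' optional two-column id-mapping file (`protein<TAB>gene`) translates
#' protein identifiers into the gene namespace used by the annotation
#' and expression tables when the two differ.
#'
#' @param path TSV path
#' @param id_map optional path to a `protein<TAB>gene` TSV
#' @return an [interaction_table()]
#' @export
load_interactions <- function(path, id_map = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  score_col <- intersect(c("combined_score", "score"), names(raw))[1]
  if (!all(c("chemical", "protein") %in% names(raw)) || is.na(score_col)) {
    rlang::abort(sprintf(
      "missing column(s) in %s: need chemical, protein, combined_score", path),
      class = "tissuetox_load_error")
  }
  score <- suppressWarnings(as.numeric(raw[[score_col]]))
  bad <- which(is.na(score) | score != round(score))
  if (length(bad) > 0) {
    rlang::abort(sprintf("non-integer score '%s' at row %d of %s",
                         raw[[score_col]][bad[1]], bad[1], path),
                 class = "tissuetox_load_error")
  }
  records <- tibble::tibble(chemical = raw$chemical, protein = raw$protein,
                            score = as.integer(score))
  if (!is.null(id_map)) {
    mp <- readr::read_tsv(id_map, col_names = c("protein", "gene"),
                          col_types = "cc", progress = FALSE)
    records <- records |>
      dplyr::left_join(mp, by = "protein") |>
      dplyr::mutate(protein = dplyr::coalesce(.data$gene, .data$protein)) |>
      dplyr::select(-"gene")
  }
  interaction_table(records)
}

#' Proteins interacting with a chemical at a confidence threshold
#'
#' @param table an [interaction_table()]
#' @param chemical chemical id
#' @param min_score minimum combined score (inclusive); 700 is the
#'   conventional "high confidence" cut-off on the 0-1000 scale
#' @return character vector of protein ids; empty (with a warning) for
#'   an unknown chemical
#' @export
interacting_proteins <- function(table, chemical, min_score = 700) {
  stopifnot(nzchar(chemical))
  rec <- table$records[table$records$chemical == chemical, ]
  if (nrow(rec) == 0) {
    rlang::warn(sprintf("chemical '%s' not found in interaction table", chemical))
    return(character(0))
  }
  sort(rec$protein[rec$score >= min_score])
}

#' Interacting proteins surviving a tissue expression filter
#'
#' The augmented method's protein set: interacting proteins intersected
#' with the genes passing the expression filter in the chosen tissue.
#' `level = "none"` returns the conventional protein set unchanged.
#' Proteins absent from the expression dataset (or unmeasured in the
#' tissue) are dropped by default; `missing_gene_policy = "keep"`
#' retains them instead.
#'
#' @inheritParams interacting_proteins
#' @param dataset an [expression_dataset()]
#' @param tissue tissue name in `dataset`
#' @param level one of [filter_levels]
#' @param missing_gene_policy `"drop"` (default) or `"keep"` for
#'   proteins without a measured expression value in the tissue
#' @return character vector of protein ids
#' @export
filtered_interacting_proteins <- function(table, chemical, min_score = 700,
                                          dataset, tissue, level,
                                          missing_gene_policy = c("drop", "keep")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  proteins <- interacting_proteins(table, chemical, min_score)
  level <- match.arg(level, filter_levels)
  if (level == "none") return(proteins)
  passing <- genes_passing_filter(dataset, tissue, level)
  kept <- intersect(proteins, passing)
  if (missing_gene_policy == "keep") {
    measured <- dataset$genes[!is.na(dataset$values[, tissue])]
    kept <- union(kept, setdiff(proteins, measured))
  }
  sort(kept)
}
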