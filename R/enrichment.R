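# Per-term over-representation testing: one-sided hypergeometric upper
# tail with Benjamini-Hochberg adjustment across the tested term family.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts annotated genes in a draw of `n` genes
#' from a universe of `N` genes of which `K` are annotated to the term.
#' Evaluated on the log scale via [stats::phyper()] for numerical
#' stability.
#'
#' @param k observed count of annotated genes in the target set
#' @param K annotated genes in the universe
#' @param n target-set size
#' @param N universe size
#' @return p-value in `[0, 1]`
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  ok <- k >= 0 && K >= 0 && n >= 0 && N >= 0 &&
    k <= min(K, n) && n <= N && K <= N &&
    all(c(k, K, n, N) == round(c(k, K, n, N)))
  if (!ok) {
    rlang::abort(sprintf(
      "invalid hypergeometric arguments (k=%s, K=%s, n=%s, N=%s): need 0 <= k <= min(K, n), n <= N, K <= N",
      k, K, n, N), class = "tissuetox_domain_error")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: rank p-values ascending, scale by `m / rank`,
#' enforce monotonicity from the largest rank downwards, cap at 1, and
#' return in the original order. Thin wrapper over
#' `stats::p.adjust(method = "BH")` with domain checks.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]", class = "tissuetox_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Disease-term over-representation analysis of a gene set
#'
#' For every ontology term with at least one target gene annotated
#' (after propagation), tests whether the target set contains more
#' annotated genes than expected when drawing `n` genes from the
#' universe. The universe defaults to all genes carrying at least one
#' propagated annotation; target genes outside the universe are
#' intersected away with a warning. BH adjustment spans all terms
#' tested in this one call.
#'
#' @param target_genes character vector of gene ids
#' @param annotations an `annotation_map` from
#'   [propagate_annotations()]
#' @param universe optional character vector restricting the background
#'   (e.g. to tissue-filtered genes); intersected with annotated genes
#' @param alpha significance level used to label results (default 0.05)
#' @param term_names optional named character vector of term names
#' @return tibble with one row per tested term: term, name, k, n, K, N,
#'   gene_ratio, background_ratio, p_value, adjusted_p, significant,
#'   genes (list column, sorted, length k), ordered by adjusted_p then
#'   term id
#' @export
enrich <- function(target_genes, annotations, universe = NULL, alpha = 0.05,
                   term_names = NULL) {
  annotated_genes <- names(annotations$propagated)
  universe <- if (is.null(universe)) annotated_genes else intersect(universe, annotated_genes)
  target_genes <- unique(target_genes)
  stray <- setdiff(target_genes, universe)
  if (length(stray) > 0) {
    rlang::warn(sprintf("%d target gene(s) outside the universe were dropped", length(stray)))
  }
  target <- intersect(target_genes, universe)
  empty <- tibble::tibble(
    term = character(0), name = character(0), k = integer(0), n = integer(0),
    K = integer(0), N = integer(0), gene_ratio = numeric(0),
    background_ratio = numeric(0), p_value = numeric(0),
    adjusted_p = numeric(0), significant = logical(0), genes = list()
  )
  if (length(target) == 0) {
    rlang::warn("empty target gene set: nothing to test")
    return(empty)
  }
  prop <- annotations$propagated[universe]
  term2genes <- split(
    rep(names(prop), lengths(prop)),
    unlist(prop, use.names = FALSE)
  )
  N <- length(universe)
  n <- length(target)
  rows <- purrr::map_dfr(names(term2genes), function(tm) {
    genes_tm <- term2genes[[tm]]
    hit <- intersect(target, genes_tm)
    k <- length(hit)
    if (k == 0) return(NULL)
    K <- length(genes_tm)
    tibble::tibble(term = tm, k = k, n = n, K = K, N = N,
                   p_value = hypergeom_upper_tail(k, K, n, N),
                   genes = list(sort(hit)))
  })
  if (nrow(rows) == 0) return(empty)
  rows$adjusted_p <- bh_adjust(rows$p_value)
  rows |>
    dplyr::mutate(
      name = if (is.null(term_names)) .data$term else unname(term_names[.data$term]),
      gene_ratio = .data$k / .data$n,
      background_ratio = .data$K / .data$N,
      significant = .data$adjusted_p < alpha
    ) |>
    dplyr::arrange(.data$adjusted_p, .data$term) |>
    dplyr::select("term", "name", "k", "n", "K", "N", "gene_ratio",
                  "background_ratio", "p_value", "adjusted_p",
                  "significant", "genes")
}

#' Infer diseases affected by a chemical
#'
#' The full three-step inference: (1) collect the chemical's
#' interacting proteins at the confidence threshold, in augmented mode
#' additionally removing proteins with relatively low expression in the
#' chosen tissue; (2) hypergeometric over-representation test per
#' disease term with BH correction; (3) report terms with adjusted
#' p-value below `alpha` as the inferred diseases.
#'
#' @param chemical chemical id
#' @param interactions an [interaction_table()]
#' @param annotations an `annotation_map`
#' @param graph an [ontology_graph()] (for term names)
#' @param mode `"conventional"` or `"augmented"`
#' @param min_score STITCH-style confidence threshold (default 700)
#' @param alpha adjusted-p significance cut-off (default 0.05)
#' @param dataset,tissue,level augmented mode only: the expression
#'   dataset, tissue and filter level
#' @param background `"filtered"` (default; in augmented mode the
#'   universe is tissue-filtered like the target set) or
#'   `"unfiltered"` (global annotated universe in both modes)
#' @param missing_gene_policy passed to
#'   [filtered_interacting_proteins()]
#' @return an `inference_report`: list with the run parameters, the
#'   full `results` table, the `enriched` subset (adjusted_p < alpha),
#'   `tested_count`, and `empty_protein_set` flag
#' @export
infer_diseases <- function(chemical, interactions, annotations, graph,
                           mode = c("conventional", "augmented"),
                           min_score = 700, alpha = 0.05,
                           dataset = NULL, tissue = NULL, level = NULL,
                           background = c("filtered", "unfiltered"),
                           missing_gene_policy = "drop") {
  mode <- match.arg(mode)
  background <- match.arg(background)
  if (mode == "augmented" &&
      (is.null(dataset) || is.null(tissue) || is.null(level))) {
    rlang::abort("augmented mode requires dataset, tissue and level",
                 class = "tissuetox_config_error")
  }
  proteins <- if (mode == "conventional") {
    interacting_proteins(interactions, chemical, min_score)
  } else {
    filtered_interacting_proteins(interactions, chemical, min_score,
                                  dataset, tissue, level,
                                  missing_gene_policy = missing_gene_policy)
  }
  universe <- NULL
  if (mode == "augmented" && background == "filtered" && level != "none") {
    universe <- genes_passing_filter(dataset, tissue, level)
    if (missing_gene_policy == "keep") {
      measured <- dataset$genes[!is.na(dataset$values[, tissue])]
      universe <- union(universe, setdiff(names(annotations$propagated), measured))
    }
  }
  results <- if (length(proteins) == 0) {
    enrich(character(0), annotations, universe = universe, alpha = alpha,
           term_names = graph$names) |> suppressWarnings()
  } else {
    enrich(proteins, annotations, universe = universe, alpha = alpha,
           term_names = graph$names)
  }
  structure(
    list(
      chemical = chemical, mode = mode, min_score = min_score, alpha = alpha,
      dataset_id = if (mode == "augmented") dataset$dataset_id else NA_character_,
      tissue = if (mode == "augmented") tissue else NA_character_,
      level = if (mode == "augmented") level else NA_character_,
      background = background,
      missing_gene_policy = missing_gene_policy,
      protein_set = proteins,
      empty_protein_set = length(proteins) == 0,
      results = results,
      enriched = results[results$significant, ],
      tested_count = nrow(results)
    ),
    class = "inference_report"
  )
}

#' @export
print.inference_report <- function(x, ...) {
  cat(sprintf("<inference_report> %s [%s]%s: %d proteins, %d terms tested, %d enriched (alpha=%g)\n",
              x$chemical, x$mode,
              if (x$mode == "augmented")
                sprintf(" %s/%s/%s", x$dataset_id, x$tissue, x$level) else "",
              length(x$protein_set), x$tested_count, nrow(x$enriched), x$alpha))
  invisible(x)
}

#' Write an inference report as TSV (+ JSON provenance)
#'
#' The TSV holds one row per enriched term with the gene list
#' semicolon-joined; the JSON sidecar records all run parameters and
#' the full tested table.
#'
#' @param report an `inference_report`
#' @param path_tsv TSV output path
#' @param path_json optional JSON output path
#' @return `path_tsv`, invisibly
#' @export
write_inference_report <- function(report, path_tsv, path_json = NULL) {
  flat <- report$enriched |>
    dplyr::mutate(genes = vapply(.data$genes, paste, character(1), collapse = ";")) |>
    dplyr::select(-"significant")
  readr::write_tsv(flat, path_tsv, progress = FALSE)
  if (!is.null(path_json)) {
    payload <- report
    payload$results <- payload$results |>
      dplyr::mutate(genes = vapply(.data$genes, paste, character(1), collapse = ";"))
    payload$enriched <- payload$enriched |>
      dplyr::mutate(genes = vapply(.data$genes, paste, character(1), collapse = ";"))
    jsonlite::write_json(unclass(payload), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path_tsv)
}
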