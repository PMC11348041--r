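# Benchmarking inferred chemical-disease associations against a curated
# reference: discovery rate |x n y| / |y| (recall-like) and enrichment
# rate |x n y| / |x| (precision-like), per tissue and filter level.

undefined_rate <- function(which) {
  rlang::warn(sprintf("%s is undefined for an empty reference set", which),
              class = "tissuetox_undefined_rate")
  NA_real_
}

#' Discovery rate of inferred associations
#'
#' `|x n y| / |y|`: the fraction of curated associations the inference
#' recovered. Undefined (returns `NA` with a warning) when the curated
#' set `y` is empty. Inputs are treated as sets: ordering and
#' duplicates are irrelevant.
#'
#' @param x inferred associations (character vector of keys)
#' @param y curated associations (character vector of keys)
#' @return a number in `[0, 1]`, or `NA` if undefined
#' @export
discovery_rate <- function(x, y) {
  y <- unique(y)
  if (length(y) == 0) return(undefined_rate("discovery rate"))
  length(intersect(unique(x), y)) / length(y)
}

#' Enrichment rate of inferred associations
#'
#' `|x n y| / |x|`: the fraction of inferred associations that are
#' curated. Undefined (returns `NA` with a warning) when the inferred
#' set `x` is empty.
#'
#' @inheritParams discovery_rate
#' @return a number in `[0, 1]`, or `NA` if undefined
#' @export
enrichment_rate <- function(x, y) {
  x <- unique(x)
  if (length(x) == 0) return(undefined_rate("enrichment rate"))
  length(intersect(x, unique(y))) / length(x)
}

#' Fraction of enriched terms relevant to a tissue
#'
#' @param enriched_terms character vector of enriched term ids
#' @param tissue_term_set character vector of tissue-relevant term ids
#' @return fraction in `[0, 1]`, or `NA` (with warning) when no term is
#'   enriched
#' @export
tissue_relevant_fraction <- function(enriched_terms, tissue_term_set) {
  enriched_terms <- unique(enriched_terms)
  if (length(enriched_terms) == 0) {
    return(undefined_rate("tissue-relevant fraction"))
  }
  length(intersect(enriched_terms, tissue_term_set)) / length(enriched_terms)
}

#' Top-k tissues by associated disease count
#'
#' Orders tissues by descending disease count, breaking ties
#' lexicographically by tissue name, and returns the first `k`.
#'
#' @param disease_counts named numeric vector, tissue -> count
#' @param k number of tissues to return (default 5)
#' @return character vector of `k` tissue names
#' @export
top_k_tissues <- function(disease_counts, k = 5) {
  stopifnot(!is.null(names(disease_counts)))
  if (k > length(disease_counts)) {
    rlang::abort(sprintf("k = %d exceeds the %d available tissues",
                         k, length(disease_counts)),
                 class = "tissuetox_domain_error")
  }
  ord <- order(-disease_counts, names(disease_counts))
  names(disease_counts)[ord][seq_len(k)]
}

assoc_key <- function(chemical, term) paste(chemical, term, sep = "|")

# Enriched term sets per chemical for one inference configuration.
enriched_terms_by_chemical <- function(chemicals, interactions, annotations,
                                       graph, mode, min_score, alpha,
                                       dataset = NULL, tissue = NULL,
                                       level = NULL, background = "filtered",
                                       missing_gene_policy = "drop") {
  out <- lapply(chemicals, function(ch) {
    rep <- suppressWarnings(infer_diseases(
      ch, interactions, annotations, graph, mode = mode,
      min_score = min_score, alpha = alpha,
      dataset = dataset, tissue = tissue, level = level,
      background = background, missing_gene_policy = missing_gene_policy
    ))
    rep$enriched$term
  })
  stats::setNames(out, chemicals)
}

rate_pair <- function(x, y) {
  c(discovery = suppressWarnings(discovery_rate(x, y)),
    enrichment = suppressWarnings(enrichment_rate(x, y)))
}

#' Benchmark disease inference per chemical (averaged rates)
#'
#' For every combination of expression dataset, tissue and filter
#' level, runs conventional and augmented inference for each chemical,
#' restricts both the inferred and curated association sets to the
#' tissue-relevant disease terms, computes per-chemical discovery and
#' enrichment rates, and averages over the chemicals for which each
#' rate is defined (chemicals with an empty inferred or curated
#' tissue-relevant set are excluded from the respective average, and
#' counted).
#'
#' @param chemicals character vector of chemical ids to evaluate
#' @param interactions an [interaction_table()]
#' @param annotations an `annotation_map`
#' @param graph an [ontology_graph()]
#' @param curated tibble with columns `chemical`, `term`
#' @param datasets named list of [expression_dataset()] objects
#' @param tissue_sets named list, tissue name -> character vector of
#'   tissue-relevant term ids (see [tissue_terms()])
#' @param levels filter levels to evaluate (default low/medium/high)
#' @param min_score,alpha,background,missing_gene_policy inference
#'   parameters, see [infer_diseases()]
#' @param improvement `"absolute"` (percentage points, default) or
#'   `"relative"` (percent of the conventional value)
#' @return tidy tibble: dataset, tissue, level, metric, conventional,
#'   augmented, improvement, n_conventional, n_augmented,
#'   n_excluded_conventional, n_excluded_augmented
#' @export
evaluate_disease_inference <- function(chemicals, interactions, annotations,
                                       graph, curated, datasets, tissue_sets,
                                       levels = c("low", "medium", "high"),
                                       min_score = 700, alpha = 0.05,
                                       background = "filtered",
                                       missing_gene_policy = "drop",
                                       improvement = c("absolute", "relative")) {
  improvement <- match.arg(improvement)
  curated_by_chem <- split(curated$term, curated$chemical)
  conv <- enriched_terms_by_chemical(chemicals, interactions, annotations,
                                     graph, "conventional", min_score, alpha)
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (ts in intersect(names(tissue_sets), ds$tissues)) {
      tset <- tissue_sets[[ts]]
      conv_rates <- vapply(chemicals, function(ch) {
        rate_pair(intersect(conv[[ch]], tset),
                  intersect(curated_by_chem[[ch]], tset))
      }, numeric(2))
      for (lv in levels) {
        aug <- enriched_terms_by_chemical(
          chemicals, interactions, annotations, graph, "augmented",
          min_score, alpha, dataset = ds, tissue = ts, level = lv,
          background = background, missing_gene_policy = missing_gene_policy
        )
        aug_rates <- vapply(chemicals, function(ch) {
          rate_pair(intersect(aug[[ch]], tset),
                    intersect(curated_by_chem[[ch]], tset))
        }, numeric(2))
        for (metric in c("discovery", "enrichment")) {
          cv <- conv_rates[metric, ]; av <- aug_rates[metric, ]
          cmean <- mean(cv, na.rm = TRUE); amean <- mean(av, na.rm = TRUE)
          imp <- if (improvement == "absolute") {
            100 * (amean - cmean)
          } else {
            100 * (amean - cmean) / cmean
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = ds_name, tissue = ts, level = lv,
            metric = paste0(metric, "_rate"),
            conventional = cmean, augmented = amean, improvement = imp,
            n_conventional = sum(!is.na(cv)), n_augmented = sum(!is.na(av)),
            n_excluded_conventional = sum(is.na(cv)),
            n_excluded_augmented = sum(is.na(av))
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    rlang::warn("no evaluable (dataset, tissue) combination")
    return(tibble::tibble())
  }
  dplyr::bind_rows(rows)
}

#' Benchmark chemical identification per tissue (pooled rates)
#'
#' Same evaluation grid as [evaluate_disease_inference()], but instead
#' of averaging per-chemical rates, pools the inferred and curated
#' (chemical, term) association pairs across all chemicals within a
#' tissue and computes one discovery and one enrichment rate on the
#' pooled sets -- the view that asks whether chemicals linked to a
#' tissue's diseases can be picked out.
#'
#' @inheritParams evaluate_disease_inference
#' @return tidy tibble: dataset, tissue, level, metric, conventional,
#'   augmented, improvement, n_pooled_x, n_pooled_y
#' @export
evaluate_chemical_identification <- function(chemicals, interactions,
                                             annotations, graph, curated,
                                             datasets, tissue_sets,
                                             levels = c("low", "medium", "high"),
                                             min_score = 700, alpha = 0.05,
                                             background = "filtered",
                                             missing_gene_policy = "drop",
                                             improvement = c("absolute", "relative")) {
  improvement <- match.arg(improvement)
  curated_by_chem <- split(curated$term, curated$chemical)
  conv <- enriched_terms_by_chemical(chemicals, interactions, annotations,
                                     graph, "conventional", min_score, alpha)
  pooled <- function(sets_by_chem, tset) {
    unlist(lapply(chemicals, function(ch) {
      terms <- intersect(sets_by_chem[[ch]], tset)
      if (length(terms) == 0) return(character(0))
      assoc_key(ch, terms)
    }), use.names = FALSE)
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (ts in intersect(names(tissue_sets), ds$tissues)) {
      tset <- tissue_sets[[ts]]
      y <- pooled(curated_by_chem, tset)
      x_conv <- pooled(conv, tset)
      conv_rates <- rate_pair(x_conv, y)
      for (lv in levels) {
        aug <- enriched_terms_by_chemical(
          chemicals, interactions, annotations, graph, "augmented",
          min_score, alpha, dataset = ds, tissue = ts, level = lv,
          background = background, missing_gene_policy = missing_gene_policy
        )
        x_aug <- pooled(aug, tset)
        aug_rates <- rate_pair(x_aug, y)
        for (metric in c("discovery", "enrichment")) {
          cmean <- conv_rates[[metric]]; amean <- aug_rates[[metric]]
          imp <- if (improvement == "absolute") {
            100 * (amean - cmean)
          } else {
            100 * (amean - cmean) / cmean
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = ds_name, tissue = ts, level = lv,
            metric = paste0(metric, "_rate"),
            conventional = cmean, augmented = amean, improvement = imp,
            n_pooled_x = length(unique(x_aug)), n_pooled_y = length(unique(y))
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    rlang::warn("no evaluable (dataset, tissue) combination")
    return(tibble::tibble())
  }
  dplyr::bind_rows(rows)
}

#' Load a curated chemical-disease association TSV
#'
#' Two columns, `chemical<TAB>term`; a header row is tolerated.
#'
#' @param path TSV path
#' @return tibble with columns `chemical`, `term`
#' @export
load_curated_associations <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chemical", "term"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) > 0 && tolower(raw$term[1]) %in% c("term", "doid", "disease")) {
    raw <- raw[-1, ]
  }
  if (nrow(raw) == 0) rlang::warn("curated association table is empty")
  dplyr::distinct(raw)
}
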