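# Seed-reproducible synthetic input bundles: ontology, annotations,
# chemical-protein interactions, expression matrices and curated truth,
# with a planted tissue-specific chemical-disease signal.
#
# Planting mechanism: for each planted (chemical, term, tissue) triple
# the chemical interacts with genes annotated to the planted term that
# are highly expressed in the tissue, and with decoy genes annotated to
# OTHER tissue-relevant terms but forced below the low-expression
# threshold in that tissue. A low filter therefore removes the decoys,
# sharpening the planted term's enrichment signal while the curated
# association stays recoverable by both methods.

fixture_tissue_pool <- c("kidney", "brain", "liver", "heart",
                         "lung", "skin", "blood", "breast")

#' Configuration for the synthetic data generator
#'
#' Defaults define the standard benchmark conditions used throughout
#' the package: 500 genes, 50 ontology terms, 4 tissues, 10 chemicals,
#' one planted (chemical, term, tissue) triple per chemical with
#' chemicals cycling through the tissues. Background expression is
#' log-normal per gene x tissue (meanlog `log(0.5)`, sdlog 2, putting
#' the median at the 0.5 TPM low threshold and the upper quartile near
#' 2 TPM); tissue-specific genes get an elevated log-normal (meanlog
#' `log(50)`) placing them above the 5 TPM high threshold.
#'
#' @param seed integer RNG seed; the single pseudo-random stream of the
#'   bundle
#' @param n_genes,n_chemicals,n_terms,n_tissues bundle dimensions
#' @param ontology_depth maximum depth of the random ontology DAG
#' @param n_extra_edges extra is_a edges beyond the random tree
#' @param frac_tissue_specific fraction of background genes given a
#'   tissue-specific high expression profile; 0 also disables signal
#'   planting (a pure-noise bundle)
#' @param n_signal_genes genes carrying the planted term per tissue
#' @param n_decoy_terms,n_decoy_genes_per_term decoy structure per
#'   tissue
#' @param noise_interaction_rate per-gene probability of a random
#'   chemical-gene interaction
#' @param missing_rate fraction of unplanted expression cells left
#'   unmeasured
#' @param meanlog,sdlog,specific_meanlog,specific_sdlog log-normal
#'   expression parameters (background and tissue-specific)
#' @param dialect expression dialect of the generated dataset
#' @param planted optional tibble (chemical, term, tissue) overriding
#'   the default planting; validated against the bundle dimensions
#' @return a `fixture_config` list
#' @export
fixture_config <- function(seed = 1,
                           n_genes = 500, n_chemicals = 10,
                           n_terms = 50, n_tissues = 4,
                           ontology_depth = 4, n_extra_edges = 5,
                           frac_tissue_specific = 0.1,
                           n_signal_genes = 8,
                           n_decoy_terms = 4,
                           n_decoy_genes_per_term = 6,
                           noise_interaction_rate = 0.02,
                           missing_rate = 0.01,
                           meanlog = log(0.5), sdlog = 2,
                           specific_meanlog = log(50), specific_sdlog = 0.5,
                           dialect = "rna_tpm",
                           planted = NULL) {
  stopifnot(n_tissues <= length(fixture_tissue_pool),
            frac_tissue_specific >= 0, frac_tissue_specific <= 1,
            noise_interaction_rate >= 0, noise_interaction_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  dialect <- match.arg(dialect, expression_dialects)
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_chemicals = n_chemicals, n_terms = n_terms,
              n_tissues = n_tissues, ontology_depth = ontology_depth,
              n_extra_edges = n_extra_edges,
              frac_tissue_specific = frac_tissue_specific,
              n_signal_genes = n_signal_genes,
              n_decoy_terms = n_decoy_terms,
              n_decoy_genes_per_term = n_decoy_genes_per_term,
              noise_interaction_rate = noise_interaction_rate,
              missing_rate = missing_rate,
              meanlog = meanlog, sdlog = sdlog,
              specific_meanlog = specific_meanlog,
              specific_sdlog = specific_sdlog,
              dialect = dialect, planted = planted)
  class(cfg) <- "fixture_config"
  cfg
}

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Random is_a DAG: a depth-bounded random tree over term ids plus a few
# extra child -> earlier-node edges (index order keeps it acyclic).
random_ontology <- function(n_terms, depth, n_extra, tissues, tissue_leaf_sets) {
  ids <- sprintf("DOID:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  node_depth <- integer(n_terms)
  parents[[1]] <- character(0)
  node_depth[1] <- 0L
  for (i in 2:n_terms) {
    eligible <- which(node_depth[seq_len(i - 1)] < depth)
    p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
    parents[[i]] <- ids[p]
    node_depth[i] <- node_depth[p] + 1L
  }
  if (n_extra > 0 && n_terms > 3) {
    for (j in seq_len(n_extra)) {
      child <- sample(3:n_terms, 1)
      extra <- sample(seq_len(child - 1), 1)
      parents[[child]] <- union(parents[[child]], ids[extra])
    }
  }
  nm <- stats::setNames(sprintf("synthetic condition %d", seq_len(n_terms)), ids)
  # tissue-relevant leaves carry the tissue keyword in their names so
  # keyword search recovers them
  for (ts in names(tissue_leaf_sets)) {
    leaves <- tissue_leaf_sets[[ts]]
    nm[leaves] <- sprintf("synthetic %s disorder %d", ts, seq_along(leaves))
  }
  ontology_graph(ids, nm, parents)
}

#' Generate a synthetic input bundle
#'
#' Builds an internally consistent set of inputs -- ontology,
#' gene-term annotations, chemical-protein interactions, one expression
#' dataset and curated chemical-disease truth -- with the planted
#' tissue-specific signal described in [fixture_config()]. The same
#' seed always yields an identical bundle.
#'
#' @param config a [fixture_config()]
#' @return a `fixture_bundle`: list with `config`, `graph`,
#'   `annotations`, `interactions`, `datasets` (named list),
#'   `curated` (tibble chemical/term), `planted` (tibble
#'   chemical/term/tissue) and `tissue_sets`
#' @export
generate_bundle <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_fixture_seed(config$seed, {
    tissues <- fixture_tissue_pool[seq_len(config$n_tissues)]
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    chemicals <- sprintf("CHEM%03d", seq_len(config$n_chemicals))
    plant <- config$frac_tissue_specific > 0

    # -- ontology: reserve leaf positions for tissue-relevant terms.
    # Terms in the last third of the index order are leaves of the
    # random tree construction only by chance, so instead keep a block
    # of dedicated leaf ids appended after tree construction.
    n_relevant <- config$n_tissues * (1 + config$n_decoy_terms)
    n_tree <- config$n_terms - n_relevant
    if (n_tree < 3) {
      rlang::abort("n_terms too small for the requested tissue structure",
                   class = "tissuetox_config_error")
    }
    ids_all <- sprintf("DOID:%07d", seq_len(config$n_terms))
    leaf_ids <- ids_all[(n_tree + 1):config$n_terms]
    tissue_leaf_sets <- split(leaf_ids,
                              rep(tissues, each = 1 + config$n_decoy_terms))
    graph <- local({
      base <- random_ontology(n_tree, config$ontology_depth,
                              config$n_extra_edges, tissues,
                              tissue_leaf_sets = list())
      parents <- base$parents
      nm <- base$names
      internal <- base$terms
      for (lid in leaf_ids) {
        parents[[lid]] <- sample(internal, 1)
        nm[lid] <- lid
      }
      for (ts in names(tissue_leaf_sets)) {
        leaves <- tissue_leaf_sets[[ts]]
        nm[leaves] <- sprintf("synthetic %s disorder %d", ts, seq_along(leaves))
      }
      ontology_graph(ids_all, nm, parents)
    })

    # -- planted structure per tissue
    planted_term <- vapply(tissues, function(ts) tissue_leaf_sets[[ts]][1],
                           character(1))
    decoy_terms <- lapply(tissues, function(ts) tissue_leaf_sets[[ts]][-1])
    names(decoy_terms) <- tissues

    gene_pool <- genes
    take <- function(n) {
      picked <- gene_pool[seq_len(n)]
      gene_pool <<- gene_pool[-seq_len(n)]
      picked
    }
    signal_genes <- decoy_genes <- stats::setNames(vector("list", length(tissues)), tissues)
    if (plant) {
      for (ts in tissues) {
        signal_genes[[ts]] <- take(config$n_signal_genes)
        decoy_genes[[ts]] <- stats::setNames(
          lapply(decoy_terms[[ts]], function(d) take(config$n_decoy_genes_per_term)),
          decoy_terms[[ts]])
      }
    }

    # -- direct annotations: every gene gets one random term (30% get a
    # second), then planted genes are tied to their tissue terms
    direct <- lapply(genes, function(g) {
      k <- 1 + stats::rbinom(1, 1, 0.3)
      sample(graph$terms, k)
    })
    names(direct) <- genes
    if (plant) {
      for (ts in tissues) {
        for (g in signal_genes[[ts]]) {
          direct[[g]] <- union(direct[[g]], planted_term[[ts]])
        }
        for (d in names(decoy_genes[[ts]])) {
          for (g in decoy_genes[[ts]][[d]]) direct[[g]] <- union(direct[[g]], d)
        }
      }
    }
    annotations <- propagate_annotations(graph, direct)

    # -- expression: background log-normal; a frac_tissue_specific slice
    # of unplanted genes is high in one random tissue; signal genes high
    # in their tissue; decoy genes forced below the low threshold there.
    latent <- matrix(
      stats::rlnorm(config$n_genes * length(tissues),
                    meanlog = config$meanlog, sdlog = config$sdlog),
      nrow = config$n_genes, dimnames = list(genes, tissues))
    planted_gene_ids <- unique(c(unlist(signal_genes),
                                 unlist(decoy_genes, use.names = FALSE)))
    free_genes <- setdiff(genes, planted_gene_ids)
    n_spec <- round(config$frac_tissue_specific * length(free_genes))
    if (n_spec > 0) {
      spec <- sample(free_genes, n_spec)
      spec_tissue <- sample(tissues, n_spec, replace = TRUE)
      latent[cbind(spec, spec_tissue)] <-
        stats::rlnorm(n_spec, config$specific_meanlog, config$specific_sdlog)
    }
    if (plant) {
      for (ts in tissues) {
        sg <- signal_genes[[ts]]
        latent[sg, ts] <- stats::rlnorm(length(sg), config$specific_meanlog,
                                        config$specific_sdlog)
        dg <- unlist(decoy_genes[[ts]], use.names = FALSE)
        latent[dg, ts] <- stats::runif(length(dg), 0, 0.4)
      }
    }
    if (config$missing_rate > 0 && length(free_genes) > 0) {
      cells <- which(matrix(genes %in% free_genes, config$n_genes,
                            length(tissues)))
      drop <- sample(cells, round(config$missing_rate * length(cells)))
      latent[drop] <- NA_real_
    }
    values <- switch(config$dialect,
      rna_tpm = latent,
      protein_ppb = latent * 1000,
      protein_semiquant = {
        v <- latent
        v[!is.na(latent) & latent <= 0.5] <- 1
        v[!is.na(latent) & latent > 0.5 & latent <= 5] <- 2
        v[!is.na(latent) & latent > 5] <- 3
        v
      })
    ds_id <- switch(config$dialect, rna_tpm = "SYN-RNA-1",
                    protein_ppb = "SYN-PROT-1", protein_semiquant = "SYN-PROT-SQ-1")
    dataset <- expression_dataset(values, config$dialect, dataset_id = ds_id)

    # -- planted triples: chemicals cycle through the tissues
    planted_tbl <- if (!is.null(config$planted)) {
      tibble::as_tibble(config$planted)
    } else if (plant) {
      ts_of <- tissues[((seq_len(config$n_chemicals) - 1) %% length(tissues)) + 1]
      tibble::tibble(chemical = chemicals, term = unname(planted_term[ts_of]),
                     tissue = ts_of)
    } else {
      tibble::tibble(chemical = character(0), term = character(0),
                     tissue = character(0))
    }
    if (nrow(planted_tbl) > 0) {
      bad <- setdiff(planted_tbl$term, graph$terms)
      if (length(bad) > 0 || !all(planted_tbl$chemical %in% chemicals) ||
          !all(planted_tbl$tissue %in% tissues)) {
        rlang::abort("planted triples reference unknown chemicals/terms/tissues",
                     class = "tissuetox_config_error")
      }
    }

    # -- interactions: planted signal + decoys at high confidence, plus
    # uniform background noise with uniform scores
    rows <- list()
    for (i in seq_len(nrow(planted_tbl))) {
      ch <- planted_tbl$chemical[i]; ts <- planted_tbl$tissue[i]
      targets <- c(signal_genes[[ts]],
                   unlist(decoy_genes[[ts]], use.names = FALSE))
      if (length(targets) > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chemical = ch, protein = targets, score = 900L)
      }
    }
    for (ch in chemicals) {
      hit <- genes[stats::runif(config$n_genes) < config$noise_interaction_rate]
      if (length(hit) > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chemical = ch, protein = hit,
          score = sample(150:999, length(hit), replace = TRUE))
      }
    }
    interactions <- interaction_table(dplyr::bind_rows(rows))

    # -- curated truth: the planted associations; for a pure-noise
    # bundle, random chemical-term pairs so rates remain computable
    curated <- if (nrow(planted_tbl) > 0) {
      dplyr::distinct(planted_tbl[, c("chemical", "term")])
    } else {
      tibble::tibble(chemical = chemicals,
                     term = sample(leaf_ids, config$n_chemicals, replace = TRUE))
    }

    tissue_sets <- stats::setNames(
      lapply(tissues, function(ts) tissue_terms(graph, ts)), tissues)

    structure(
      list(config = config, graph = graph, annotations = annotations,
           interactions = interactions,
           datasets = stats::setNames(list(dataset), ds_id),
           curated = curated, planted = planted_tbl,
           tissue_sets = tissue_sets, tissues = tissues,
           chemicals = chemicals),
      class = "fixture_bundle")
  })
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> seed %d: %d genes, %d chemicals, %d terms, %d tissues, %d planted triples\n",
    x$config$seed, x$config$n_genes, x$config$n_chemicals,
    x$config$n_terms, length(x$tissues), nrow(x$planted)))
  invisible(x)
}

#' Write a bundle to disk in the external input formats
#'
#' Emits `interactions.tsv`, `annotations.tsv`, `ontology.obo`, one
#' expression TSV plus metadata YAML per dataset, `curated.tsv`,
#' `planted.tsv` and a `manifest.yaml` recording the configuration,
#' seed and per-file MD5 checksums. Loading the files back with the
#' package's loaders reproduces the in-memory bundle.
#'
#' @param bundle a `fixture_bundle`
#' @param dir output directory (created if needed)
#' @return path of the written manifest, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(
    dplyr::rename(bundle$interactions$records, combined_score = "score"),
    p("interactions.tsv"), progress = FALSE)
  write_annotations(bundle$annotations, p("annotations.tsv"))
  write_obo(bundle$graph, p("ontology.obo"))
  for (ds in bundle$datasets) {
    write_expression_matrix(ds, p(paste0("expression_", ds$dataset_id, ".tsv")))
    yaml::write_yaml(list(dataset_id = ds$dataset_id, dialect = ds$dialect,
                          thresholds = ds$thresholds),
                     p(paste0("expression_", ds$dataset_id, ".meta.yaml")))
  }
  readr::write_tsv(bundle$curated, p("curated.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(bundle$planted, p("planted.tsv"), progress = FALSE)
  files <- setdiff(list.files(dir), "manifest.yaml")
  manifest <- list(
    seed = bundle$config$seed,
    config = lapply(unclass(bundle$config)[setdiff(names(unclass(bundle$config)), "planted")],
                    function(x) if (is.numeric(x)) unclass(x) else x),
    checksums = as.list(tools::md5sum(file.path(dir, files))) |>
      stats::setNames(files)
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(p("manifest.yaml"))
}

#' Load a bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory
#' @return a list with `graph`, `annotations`, `interactions`,
#'   `datasets`, `curated`, `planted`, `tissue_sets` and the manifest
#' @export
load_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- yaml::read_yaml(p("manifest.yaml"))
  graph <- load_obo(p("ontology.obo"))
  annotations <- load_annotations(p("annotations.tsv"), graph)
  interactions <- load_interactions(p("interactions.tsv"))
  meta_files <- list.files(dir, pattern = "\\.meta\\.yaml$", full.names = TRUE)
  datasets <- list()
  for (mf in meta_files) {
    meta <- yaml::read_yaml(mf)
    ds <- load_expression_matrix(sub("\\.meta\\.yaml$", ".tsv", mf),
                                 dialect = meta$dialect,
                                 dataset_id = meta$dataset_id,
                                 thresholds = meta$thresholds)
    datasets[[meta$dataset_id]] <- ds
  }
  curated <- load_curated_associations(p("curated.tsv"))
  planted <- if (file.exists(p("planted.tsv"))) {
    readr::read_tsv(p("planted.tsv"), col_types = "ccc", progress = FALSE)
  } else NULL
  tissues <- unique(unlist(lapply(datasets, function(d) d$tissues)))
  tissue_sets <- stats::setNames(
    lapply(tissues, function(ts) tissue_terms(graph, ts)), tissues)
  list(manifest = manifest, graph = graph, annotations = annotations,
       interactions = interactions, datasets = datasets, curated = curated,
       planted = planted, tissue_sets = tissue_sets, tissues = tissues)
}
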