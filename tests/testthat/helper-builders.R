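# Small in-code builders shared across the test files.

# 3-gene x 2-tissue TPM matrix with one unmeasured cell
tiny_expression <- function(dialect = "rna_tpm") {
  m <- matrix(c(0.2, 0.7, 6.0,
                1.5, NA, 0.1),
              nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("kidney", "brain")))
  if (dialect == "protein_ppb") m <- m * 1000
  expression_dataset(m, dialect, dataset_id = "TINY")
}

# writes a TSV from a named list of row vectors and returns the path
write_tsv_fixture <- function(header, rows) {
  path <- tempfile(fileext = ".tsv")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# linear chain DOID:1 is_a DOID:2 is_a ... is_a DOID:n (last is root)
chain_graph <- function(n) {
  ids <- paste0("DOID:", seq_len(n))
  parents <- c(lapply(seq_len(n - 1), function(i) ids[i + 1]), list(character(0)))
  names(parents) <- ids
  ontology_graph(ids, stats::setNames(paste("term", seq_len(n)), ids), parents)
}

# two-level graph: root R; T annotates genes[annotated]; every gene
# also annotated to the root so they all sit in the universe
two_term_annotations <- function(universe, term_genes) {
  ids <- c("DOID:R", "DOID:T")
  parents <- list("DOID:R" = character(0), "DOID:T" = "DOID:R")
  graph <- ontology_graph(ids, stats::setNames(c("root", "leaf"), ids), parents)
  direct <- lapply(universe, function(g) {
    if (g %in% term_genes) c("DOID:R", "DOID:T") else "DOID:R"
  })
  names(direct) <- universe
  list(graph = graph, annotations = propagate_annotations(graph, direct))
}

# random expression matrix + interaction table for property tests
random_filter_fixture <- function(n_genes = 40, n_tissues = 3) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  tissues <- paste0("tissue", seq_len(n_tissues))
  m <- matrix(stats::rlnorm(n_genes * n_tissues, log(0.8), 1.5),
              nrow = n_genes, dimnames = list(genes, tissues))
  m[sample(length(m), round(0.05 * length(m)))] <- NA
  ds <- expression_dataset(m, "rna_tpm", dataset_id = "RND")
  chem <- "chemX"
  partners <- sample(genes, 25)
  it <- interaction_table(tibble::tibble(
    chemical = chem, protein = partners,
    score = sample(0:1000, 25, replace = TRUE)))
  list(dataset = ds, interactions = it, chemical = chem, genes = genes)
}
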