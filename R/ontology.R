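# Disease Ontology handling: OBO parsing, is_a ancestor closure,
# annotation propagation, tissue keyword search, hierarchy extraction.
# Only is_a edges are used; other relationship types are ignored.

#' Construct an ontology graph
#'
#' @param ids character vector of term ids
#' @param names named character vector, term id -> name
#' @param parents named list, term id -> character vector of is_a parents
#' @param synonyms named list, term id -> character vector of synonyms
#' @param obsolete character vector of obsolete term ids (excluded from
#'   `terms`)
#' @return an `ontology_graph` object
#' @export
ontology_graph <- function(ids, names, parents, synonyms = list(),
                           obsolete = character(0)) {
  ids <- setdiff(ids, obsolete)
  parents <- parents[intersect(names(parents), ids)]
  parents <- lapply(parents, intersect, ids)
  missing <- setdiff(ids, names(parents))
  parents[missing] <- replicate(length(missing), character(0), simplify = FALSE)
  g <- structure(
    list(terms = ids, names = names[ids], parents = parents[ids],
         synonyms = synonyms, obsolete = obsolete),
    class = "ontology_graph"
  )
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    rlang::abort(sprintf("is_a cycle detected: %s", paste(cyc, collapse = " -> ")),
                 class = "tissuetox_ontology_error")
  }
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms, %d is_a edges, %d obsolete\n",
              length(x$terms), sum(lengths(x$parents)), length(x$obsolete)))
  invisible(x)
}

# Kahn topological sort; returns first detected cycle or NULL.
find_cycle <- function(graph) {
  indeg <- stats::setNames(integer(length(graph$terms)), graph$terms)
  children <- list()
  for (child in names(graph$parents)) {
    for (p in graph$parents[[child]]) {
      children[[p]] <- c(children[[p]], child)
      indeg[[child]] <- indeg[[child]] + 1L
    }
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(graph$terms)) return(NULL)
  # walk the residual graph to name one cycle
  residual <- names(indeg)[indeg > 0L]
  v <- residual[1]
  path <- character(0)
  while (!v %in% path) {
    path <- c(path, v)
    v <- intersect(graph$parents[[v]], residual)[1]
  }
  c(path[which(path == v):length(path)], v)
}

#' Parse an OBO ontology file
#'
#' Reads `[Term]` stanzas, keeping ids, names, exact synonyms and is_a
#' parents. Obsolete terms are recorded but excluded from the analysis
#' graph. Only `is_a` relationships are retained.
#'
#' @param path OBO 1.2/1.4 file
#' @return an [ontology_graph()]
#' @export
load_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) {
    rlang::abort(sprintf("no [Term] stanzas found in %s", path),
                 class = "tissuetox_load_error")
  }
  stanza_bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(0); nm <- character(0)
  parents <- list(); synonyms <- list(); obsolete <- character(0)
  for (i in seq_along(term_starts)) {
    chunk <- lines[(stanza_bounds[i] + 1L):(stanza_bounds[i + 1L] - 1L)]
    other_stanza <- grep("^\\[", chunk)  # e.g. a following [Typedef]
    if (length(other_stanza) > 0) chunk <- chunk[seq_len(min(other_stanza) - 1L)]
    id <- sub("^id: *", "", grep("^id: ", chunk, value = TRUE)[1])
    if (is.na(id)) {
      rlang::abort(sprintf("[Term] stanza %d in %s has no id", i, path),
                   class = "tissuetox_load_error")
    }
    if (any(grepl("^is_obsolete: *true", chunk))) {
      obsolete <- c(obsolete, id)
      next
    }
    name_line <- grep("^name: ", chunk, value = TRUE)
    ids <- c(ids, id)
    nm[id] <- if (length(name_line) > 0) sub("^name: *", "", name_line[1]) else id
    isa <- grep("^is_a: ", chunk, value = TRUE)
    parents[[id]] <- sub(" *!.*$", "", sub("^is_a: *", "", isa))
    syn <- grep("^synonym: ", chunk, value = TRUE)
    synonyms[[id]] <- sub('^synonym: *"(.*)".*$', "\\1", syn)
  }
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate term id '%s' in %s", ids[duplicated(ids)][1], path),
                 class = "tissuetox_load_error")
  }
  ontology_graph(ids, nm, parents, synonyms, obsolete)
}

#' Write an ontology graph to OBO format
#' @param graph an [ontology_graph()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in graph$terms) {
    stanza <- c("[Term]", paste0("id: ", id), paste0("name: ", graph$names[[id]]))
    for (s in graph$synonyms[[id]]) {
      stanza <- c(stanza, sprintf('synonym: "%s" EXACT []', s))
    }
    for (p in graph$parents[[id]]) {
      stanza <- c(stanza, sprintf("is_a: %s ! %s", p, graph$names[[p]]))
    }
    writeLines(c(stanza, ""), con)
  }
  for (id in graph$obsolete) {
    writeLines(c("[Term]", paste0("id: ", id), "is_obsolete: true", ""), con)
  }
  invisible(path)
}

assert_term <- function(graph, term) {
  if (!term %in% graph$terms) {
    rlang::abort(sprintf("unknown term '%s'", term),
                 class = "tissuetox_ontology_error")
  }
  invisible(NULL)
}

#' All is_a ancestors of a term
#'
#' Transitive closure over is_a edges, excluding the term itself.
#'
#' @param graph an [ontology_graph()]
#' @param term term id in the graph
#' @return character vector of ancestor term ids
#' @export
ancestors <- function(graph, term) {
  assert_term(graph, term)
  out <- character(0)
  frontier <- graph$parents[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier], use.names = FALSE)), out)
  }
  sort(out)
}

#' Propagate gene annotations to ancestor terms
#'
#' Standard true-path propagation: every gene annotated to a term is
#' implicitly annotated to all its is_a ancestors. Annotations to
#' unknown or obsolete terms are skipped with a warning. Set
#' `propagate = FALSE` to test only directly annotated terms.
#'
#' @param graph an [ontology_graph()]
#' @param direct named list, gene id -> character vector of term ids
#' @param propagate logical; if `FALSE` the propagated map equals the
#'   direct map (after dropping unknown terms)
#' @return an `annotation_map`: list with elements `direct` and
#'   `propagated` (both gene -> term id vectors)
#' @export
propagate_annotations <- function(graph, direct, propagate = TRUE) {
  known <- lapply(direct, function(terms) {
    bad <- setdiff(terms, graph$terms)
    if (length(bad) > 0) {
      rlang::warn(sprintf("skipping annotation(s) to unknown/obsolete term(s): %s",
                          paste(bad, collapse = ", ")))
    }
    intersect(terms, graph$terms)
  })
  known <- known[lengths(known) > 0]
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(term) {
    if (is.null(anc_cache[[term]])) anc_cache[[term]] <- ancestors(graph, term)
    anc_cache[[term]]
  }
  propagated <- if (propagate) {
    lapply(known, function(terms) {
      sort(union(terms, unique(unlist(lapply(terms, anc_of), use.names = FALSE))))
    })
  } else {
    lapply(known, sort)
  }
  structure(list(direct = lapply(known, sort), propagated = propagated),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes, %d direct / %d propagated annotations\n",
              length(x$direct), sum(lengths(x$direct)), sum(lengths(x$propagated))))
  invisible(x)
}

#' Load a gene -> term annotation TSV
#'
#' Two columns (`gene<TAB>term`), no header required; a header line is
#' detected and skipped when the second field is not a term id already
#' seen in `graph`.
#'
#' @param path TSV path
#' @param graph an [ontology_graph()] used for propagation
#' @param propagate passed to [propagate_annotations()]
#' @return an `annotation_map`
#' @export
load_annotations <- function(path, graph, propagate = TRUE) {
  raw <- readr::read_tsv(path, col_names = c("gene", "term"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) > 0 && !raw$term[1] %in% c(graph$terms, graph$obsolete)) {
    header_like <- tolower(raw$term[1]) %in% c("term", "doid", "do_term")
    if (header_like) raw <- raw[-1, ]
  }
  direct <- split(raw$term, raw$gene)
  propagate_annotations(graph, direct, propagate = propagate)
}

#' Write direct annotations to TSV
#' @param annotations an `annotation_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotations <- function(annotations, path) {
  df <- tibble::tibble(
    gene = rep(names(annotations$direct), lengths(annotations$direct)),
    term = unlist(annotations$direct, use.names = FALSE)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Ontology terms matching tissue keywords
#'
#' Case-insensitive match of each keyword against term names and
#' synonyms. The default mode requires a whole-word match ("kidney"
#' matches "chronic kidney failure" but not "kidneylike"); substring
#' mode relaxes this.
#'
#' @param graph an [ontology_graph()]
#' @param keywords non-empty character vector of keywords
#' @param mode `"word"` (default) or `"substring"`
#' @return character vector of matching term ids
#' @export
tissue_terms <- function(graph, keywords, mode = c("word", "substring")) {
  mode <- match.arg(mode)
  stopifnot(length(keywords) > 0)
  texts <- lapply(graph$terms, function(id) {
    c(graph$names[[id]], graph$synonyms[[id]])
  })
  hit <- rep(FALSE, length(graph$terms))
  for (kw in keywords) {
    pat <- if (mode == "word") {
      paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw), "\\b")
    } else {
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw)
    }
    hit <- hit | vapply(texts, function(tx) any(grepl(pat, tx, ignore.case = TRUE)),
                        logical(1))
  }
  sort(graph$terms[hit])
}

#' Extract a term's ancestor hierarchy as a small graph
#'
#' Returns the term, all its ancestors, and the is_a edges among them --
#' the sub-DAG one would draw to show where an enriched disease sits in
#' the ontology. Each node is flagged by membership in `enriched`, so a
#' partially recovered hierarchy (e.g. high-level terms enriched but
#' the specific leaf missed) is visible directly.
#'
#' @param graph an [ontology_graph()]
#' @param term term id
#' @param enriched character vector of enriched term ids used to flag
#'   nodes
#' @return list with `nodes` (tibble: term, name, enriched) and `edges`
#'   (tibble: child, parent)
#' @export
hierarchy_path <- function(graph, term, enriched = character(0)) {
  assert_term(graph, term)
  node_ids <- c(term, ancestors(graph, term))
  edges <- purrr::map_dfr(node_ids, function(id) {
    ps <- intersect(graph$parents[[id]], node_ids)
    if (length(ps) == 0) return(tibble::tibble(child = character(0), parent = character(0)))
    tibble::tibble(child = id, parent = ps)
  })
  list(
    nodes = tibble::tibble(term = node_ids,
                           name = unname(graph$names[node_ids]),
                           enriched = node_ids %in% enriched),
    edges = edges
  )
}
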