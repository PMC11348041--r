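Package: tissuetox
Title: Tissue-Aware In Silico Toxicogenomics for Chemical-Disease Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers chemical-disease associations from chemical-protein
    interaction data by Disease Ontology over-representation analysis
    (hypergeometric tests with Benjamini-Hochberg correction), optionally
    augmented with tissue-specific gene/protein expression filters that
    remove relatively low-expressed interacting proteins before testing.
    Supports RNA-seq (TPM), quantitative proteomics (ppb) and
    semi-quantitative proteomics expression matrices, provides discovery-
    and enrichment-rate benchmarking against curated chemical-disease
    associations, and ships a seed-reproducible synthetic data generator
    with planted tissue-specific signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
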