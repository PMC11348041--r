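---
title: "Tissue-filtered chemical–disease inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-filtered chemical–disease inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuetox)
```

## The inference model

tissuetox infers the diseases a chemical may affect from databased
chemical–protein interactions rather than from new transcriptomics
experiments. The conventional pipeline treats the chemical's interacting
proteins (at a confidence threshold on the 0–1000 interaction score) as
a gene set and asks, for each Disease Ontology (DO) term, whether the
set is over-represented among the genes annotated to that term. The
test statistic is the hypergeometric upper tail
`P(X >= k)` with universe size `N`, `K` term-annotated genes in the
universe, a target set of `n` genes and `k` annotated target genes,
adjusted across the tested terms by the Benjamini–Hochberg (BH)
step-up procedure; terms with adjusted p below `alpha` (default 0.05)
are the inferred diseases.

The *augmented* variant inserts one step: before testing, interacting
proteins whose expression in a user-chosen tissue does not exceed an
expression threshold are removed. The premise is biological: a protein
that is essentially absent from a tissue cannot mediate a disease in
that tissue, so keeping it only dilutes the gene set with plausible
false positives. The expected trade-off — and what the evaluation bench
measures — is a precision-like gain (enrichment rate) paid for by a
bounded recall-like loss (discovery rate).

Key modelling assumptions:

* Protein and gene identifiers share one namespace (an optional
  two-column mapping file in `load_interactions()` translates them when
  they do not).
* Gene–term annotations obey the true-path rule: a gene annotated to a
  term is implicitly annotated to every `is_a` ancestor. Annotations
  are therefore propagated before testing; `propagate = FALSE`
  disables this for sensitivity analysis, since over-representation
  tools differ on this point.
* Only `is_a` edges of the ontology are traversed; other relationship
  types are ignored.
* The background universe is the set of genes with at least one
  propagated annotation. In augmented mode the default
  (`background = "filtered"`) restricts the universe by the same
  tissue filter as the target set, keeping foreground and background
  sampled from the same population; `background = "unfiltered"` keeps
  the global universe instead, because either convention is defensible
  and published systems are not explicit about which they use.

## Expression dialects and thresholds

Three kinds of expression matrix are supported, with per-dialect filter
thresholds that a value must strictly exceed to survive:

| dialect | unit | low | medium | high |
|---|---|---|---|---|
| `rna_tpm` | transcripts per million | 0.5 | 1 | 5 |
| `protein_ppb` | parts per billion | 500 | 1000 | 1500 |
| `protein_semiquant` | ordinal level 1/2/3 | keeps {2,3} | keeps {3} | keeps {3} |

The strict inequality is deliberate: a 0.5 TPM gene is a low-expression
gene and is removed by the low filter. The same boundary rule is applied
uniformly to the ppb thresholds. On a three-level ordinal scale the
medium and high filters necessarily coincide; both retain only level 3.
Thresholds are attached to each dataset object and can be overridden for
non-default datasets.

Thresholds always apply to raw values. The `log10(value + 0.01)`
transform in `log_summary()` exists purely for distribution summaries
(the pseudo-count avoids the undefined logarithm of zero) and never
influences filtering. `threshold_percentile()` reports where a
threshold sits in a tissue's value distribution, as the percentage of
measured values at or below it.

Cells absent from a matrix are "not measured", which is distinct from a
measured 0. A gene without a measured value in the tissue is removed by
any filter level other than `none` under the default
`missing_gene_policy = "drop"`: absence of evidence of expression
should not rescue a gene from a tissue filter. The `"keep"` policy
implements the opposite reading for users who prefer to treat
unmeasured genes as unknowable rather than absent.

## Evaluation statistics

Given inferred tissue-relevant associations `x` and curated
tissue-relevant associations `y`,

* discovery rate `= |x ∩ y| / |y|` (undefined when `|y| = 0`),
* enrichment rate `= |x ∩ y| / |x|` (undefined when `|x| = 0`).

Both evaluators restrict `x` and `y` to the tissue-relevant DO terms
(identified by case-insensitive whole-word keyword match on term names
and exact synonyms; substring mode is available) before computing
rates: mixing tissues in the denominator of the enrichment rate would
make per-tissue filters incomparable. Undefined rates exclude the
chemical from that cell's average — scoring an undefined rate as zero
would conflate "nothing inferred" with "everything inferred was wrong" —
and the number of exclusions is reported.

Two aggregation modes are provided because both are reasonable and they
answer different questions: `evaluate_disease_inference()` averages
per-chemical rates (how well is an individual chemical's disease
profile inferred?), while `evaluate_chemical_identification()` pools
the (chemical, term) pairs per tissue before computing one rate (can
the chemicals linked to a tissue's diseases be identified as a
population?). Improvements are reported as absolute percentage-point
differences between the augmented and conventional averages by
default; `improvement = "relative"` switches to percent of the
conventional value.

`top_k_tissues()` selects the tissues with the most curated disease
terms (default k = 5), breaking count ties lexicographically so the
selection is reproducible.

## The synthetic data generator

`generate_bundle()` produces a complete, internally consistent input
bundle — ontology, annotations, interactions, expression, curated truth
— from one seeded RNG stream. Its default dimensions (500 genes, 50
terms, 4 tissues, 10 chemicals) are the package's standard benchmark
conditions: large enough that hypergeometric p-values behave like they
do on real universes, small enough that a 20-seed benchmark runs in
about a minute on one CPU; the multi-seed suites in the tests and the
acceptance script use exactly these sizes.

What it emulates:

* a random `is_a` DAG (depth-bounded random tree plus a few extra
  edges) with dedicated leaf terms per tissue whose names embed the
  tissue keyword, so keyword search recovers them;
* log-normal background expression per gene × tissue with
  `meanlog = log(0.5)`, `sdlog = 2`, placing the median at the 0.5 TPM
  low threshold and the upper quartile near 2 TPM, so the published
  absolute thresholds are meaningful on synthetic data; a configurable
  fraction of genes is tissue-specific (elevated log-normal,
  `meanlog = log(50)`, almost surely above the high threshold);
* planted signal: for each planted (chemical, term, tissue) triple the
  chemical interacts at high confidence with genes annotated to the
  planted term and highly expressed in the tissue, and with decoy
  genes annotated to *other* tissue-relevant terms but forced below
  the low threshold there (uniform on [0, 0.4] TPM). A low filter
  removes the decoys, so the decoy terms lose their enrichment while
  the planted term keeps it — precisely the mechanism by which a
  tissue filter should raise the enrichment rate without losing the
  true association;
* the decoy geometry (4 decoy terms × 6 genes against 8 signal genes
  per tissue) was sized by a Poisson approximation so that decoy terms
  are decisively enriched under conventional analysis (upper-tail
  p ≈ 5·10⁻⁴ against ~25 tested terms) and decisively lost under the
  filter — the benchmark should measure the filter, not borderline
  test behaviour;
* the three expression dialects derive from one latent TPM-like
  matrix (ppb = 1000 × TPM; ordinal levels by cutting at 0.5 and 5),
  so a bundle's filter decisions are comparable across dialects;
* ~1% of unplanted cells are left unmeasured to exercise the
  missing-value path.

What it does not emulate — and hence what passing benchmarks do and do
not show: real STITCH score distributions (planted interactions all
score 900; noise scores are uniform), correlated expression across
tissues or genes, the size and depth of the real Disease Ontology,
annotation bias toward well-studied genes, and incompleteness of
curated references (the synthetic truth is exactly the planted set).
Passing the planted-signal benchmark shows the pipeline's machinery —
filtering, universe handling, testing, restriction, rate computation —
behaves as designed under conditions where the right answer is known;
it does not certify effect sizes on real databases.

With `frac_tissue_specific = 0` planting is disabled entirely and the
bundle is pure noise with random curated pairs; this is the negative
control in which improvements should hover around zero.

## Numerical and degenerate-case choices

* `hypergeom_upper_tail()` evaluates `phyper(k − 1, K, N − K, n,
  lower.tail = FALSE)`, which works on log-scale combinatorics
  internally; `k = 0` returns exactly 1 and all argument-domain
  violations are errors rather than NaNs. Exhaustive subset
  enumeration for every valid `(k, K, n, N)` with `N ≤ 12` agrees to
  within 10⁻¹².
* `bh_adjust()` validates `[0, 1]`, delegates to
  `p.adjust(method = "BH")`, and is checked against a hand-applied
  step-up formula and for permutation invariance.
* Result ordering is adjusted-p ascending with ties broken by term id,
  so identical inputs yield byte-identical reports.
* Terms with `k = 0` are not tested (they cannot be over-represented
  and would only dilute the BH family); the BH family is all terms
  tested within one run, never across chemicals or configurations.
* An empty protein set after filtering yields an explicit
  `empty_protein_set` flag and an empty result table, with a warning
  rather than an error: downstream evaluation treats the resulting
  undefined rates by exclusion.
* Ontology loading rejects `is_a` cycles (naming one offending cycle)
  and skips annotations to unknown or obsolete terms with a warning.

## Known limitations

* The keyword-based tissue–term mapping is lexical; terms relevant to a
  tissue but not naming it (or any synonym) are missed.
* Semi-quantitative data cannot distinguish medium from high filtering.
* No regulation direction: an interaction is an interaction, whether
  the chemical induces or represses the protein.
* Enrichment treats terms independently; parent–child dependence in the
  ontology is handled only through annotation propagation, not through
  dependency-aware corrections.
* The CLI is a thin wrapper intended for scripted pipelines; it does
  not replace the interactive exploration a web front-end offers.
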