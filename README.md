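# tissuetox

Tissue-aware in silico toxicogenomics: inferring the diseases a chemical
may affect from its protein interaction partners, with an expression
filter that removes partners that are barely expressed in the tissue of
interest.

## The problem and the method

In silico toxicogenomics systems infer chemical–disease associations in
three steps: (1) look up the chemical's interacting proteins in a
chemical–protein interaction database (STITCH-style tables with a
0–1000 confidence score); (2) for every Disease Ontology (DO) term, test
whether the partner set is enriched for genes annotated to that term,
using a one-sided hypergeometric test

```
P(X >= k),   X ~ Hypergeometric(N, K, n)
```

where `N` is the background universe of annotated genes, `K` of them
annotated to the term, `n` the partner-set size and `k` the annotated
partners, with Benjamini–Hochberg correction across all tested terms;
(3) call terms with adjusted p < 0.05 the inferred diseases.

Because interaction databases pool evidence across all tissues, this
*conventional* inference can be dominated by proteins that are hardly
expressed where the disease happens. The *augmented* method adds a
filter between steps 1 and 2: partners whose expression in a chosen
tissue does not exceed a low/medium/high threshold (defaults 0.5/1/5
TPM for RNA-seq, 500/1000/1500 ppb for quantitative proteomics, ordinal
levels for semi-quantitative proteomics) are removed before testing,
and by default the background universe is filtered the same way.

Performance against a curated chemical–disease reference is measured
with two set statistics over tissue-relevant associations `x` (inferred)
and `y` (curated):

```
discovery rate  = |x ∩ y| / |y|     (recall-like)
enrichment rate = |x ∩ y| / |x|     (precision-like)
```

The package provides loaders for all input formats (expression TSV in
three dialects, interaction TSV, gene–DO annotation TSV, OBO ontology,
curated association TSV), the inference engine, the evaluation bench,
and a seed-reproducible synthetic data generator that plants
tissue-specific chemical–disease signal so the whole pipeline can be
exercised and benchmarked without any external database.

## Worked example

```r
library(tissuetox)

b <- generate_bundle(fixture_config(seed = 1))   # synthetic inputs
conv <- infer_diseases("CHEM001", b$interactions, b$annotations, b$graph,
                       mode = "conventional")
aug  <- infer_diseases("CHEM001", b$interactions, b$annotations, b$graph,
                       mode = "augmented", dataset = b$datasets[["SYN-RNA-1"]],
                       tissue = "kidney", level = "low")
conv
#> <inference_report> CHEM001 [conventional]: 36 proteins, 41 terms tested, 9 enriched (alpha=0.05)
aug
#> <inference_report> CHEM001 [augmented] SYN-RNA-1/kidney/low: 9 proteins, 21 terms tested, 4 enriched (alpha=0.05)
head(aug$enriched[, c("term", "name", "k", "n", "K", "N", "adjusted_p")], 2)
#>   term         name                            k     n     K     N adjusted_p
#> 1 DOID:0000031 synthetic kidney disorder 1     8     9    13   236 1.13e-9
#> 2 DOID:0000028 synthetic condition 28          8     9    18   236 1.88e-8
```

The low-expression filter shrinks CHEM001's partner set from 36 to 9
proteins: the decoy partners — annotated to other kidney disorders but
barely expressed in kidney — are gone, and the planted kidney disorder
tops the enriched list. Benchmarking all ten chemicals against the
bundle's curated truth:

```r
ev <- evaluate_disease_inference(
  b$chemicals, b$interactions, b$annotations, b$graph, b$curated,
  b$datasets, b$tissue_sets, levels = "low")
ev[ev$tissue == "kidney", c("level", "metric", "conventional", "augmented", "improvement")]
#>   level          metric conventional augmented improvement
#> 1   low  discovery_rate          1.0         1           0
#> 2   low enrichment_rate          0.2         1          80
```

The filter leaves the discovery rate untouched (the true association is
found either way) while the enrichment rate jumps from 0.2 to 1.0: an
improvement of 80 percentage points, the qualitative trade-off the
augmented method is designed to produce.

A command-line wrapper over the same functions ships in
`inst/cli/tissuetox.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","tissuetox.R",package="tissuetox"))')" \
  simulate --seed 1 --out bundle/
```

with subcommands `infer`, `evaluate`, `simulate` and
`summarize-expression`.

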