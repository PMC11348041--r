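# exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every n-subset of a universe with K successes and count
# those containing at least k successes
enum_upper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# hand application of the BH step-up formula, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("hypergeometric upper tail matches enumeration and guards its domain", {
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1.0)
  # C(5,4)/C(10,4) = 5/210: all four draws are successes
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), choose(5, 4) / choose(10, 4),
               tolerance = 1e-14)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), enum_upper_tail(4, 5, 4, 10),
               tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), class = "tissuetox_domain_error")
  expect_error(hypergeom_upper_tail(2, 5, 4, 3), class = "tissuetox_domain_error")
  expect_error(hypergeom_upper_tail(1.5, 5, 4, 10), class = "tissuetox_domain_error")
  # spot grid against the oracle
  for (N in c(6, 8)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_upper_tail(k, K, n, N), enum_upper_tail(k, K, n, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment follows the step-up formula and is permutation-stable", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "tissuetox_domain_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "tissuetox_domain_error")
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-14)
  }
})

test_that("over-representation counts and p-values match the small worked case", {
  fx <- two_term_annotations(sprintf("g%02d", 1:20), sprintf("g%02d", 1:5))
  target <- c(sprintf("g%02d", 1:4), "g06")  # 4 of 5 in the leaf term
  res <- enrich(target, fx$annotations, term_names = fx$graph$names)
  leaf <- res[res$term == "DOID:T", ]
  expect_equal(leaf$k, 4); expect_equal(leaf$n, 5)
  expect_equal(leaf$K, 5); expect_equal(leaf$N, 20)
  expect_equal(leaf$p_value, enum_upper_tail(4, 5, 5, 20), tolerance = 1e-12)
  expect_equal(leaf$gene_ratio, 4 / 5)
  expect_equal(leaf$background_ratio, 5 / 20)
  expect_identical(leaf$genes[[1]], sprintf("g%02d", 1:4))
  expect_equal(res$adjusted_p, bh_oracle(res$p_value), tolerance = 1e-14)
  # the root term annotates everything: k = n, p = 1
  expect_equal(res$p_value[res$term == "DOID:R"], 1.0)
})

test_that("degenerate target sets behave sanely", {
  universe <- sprintf("g%02d", 1:20)
  fx <- two_term_annotations(universe, sprintf("g%02d", 1:5))
  # target = universe: every term has k = K and p = 1
  res <- enrich(universe, fx$annotations)
  expect_true(all(res$k == res$K))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
  # empty target set warns and returns an empty frame
  expect_warning(res0 <- enrich(character(0), fx$annotations), "empty target")
  expect_equal(nrow(res0), 0)
  # stray genes outside the universe are dropped with a warning
  expect_warning(res1 <- enrich(c("g01", "not_a_gene"), fx$annotations),
                 "outside the universe")
  expect_equal(unique(res1$n), 1)
  # terms with k = 0 are never reported
  res2 <- enrich("g06", fx$annotations)
  expect_false("DOID:T" %in% res2$term)
})

test_that("enrichment output is deterministic with term-id tie-breaks", {
  fx <- two_term_annotations(sprintf("g%02d", 1:20), sprintf("g%02d", 1:5))
  target <- sprintf("g%02d", 1:5)
  r1 <- enrich(target, fx$annotations)
  r2 <- enrich(target, fx$annotations)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$adjusted_p))
  ties <- split(r1$term, r1$adjusted_p)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("conventional inference equals an augmented run with level none", {
  b <- generate_bundle(fixture_config(seed = 5, n_genes = 120, n_chemicals = 3,
                                      n_terms = 30, n_tissues = 2,
                                      n_signal_genes = 5, n_decoy_terms = 2,
                                      n_decoy_genes_per_term = 4))
  conv <- infer_diseases("CHEM001", b$interactions, b$annotations, b$graph,
                         mode = "conventional")
  aug0 <- infer_diseases("CHEM001", b$interactions, b$annotations, b$graph,
                         mode = "augmented", dataset = b$datasets[[1]],
                         tissue = b$tissues[1], level = "none")
  expect_identical(conv$results, aug0$results)
  expect_identical(conv$enriched$term, aug0$enriched$term)
})

test_that("the tissue filter sharpens the planted term's signal", {
  b <- generate_bundle(fixture_config(seed = 3))
  tr <- b$planted[1, ]
  conv <- infer_diseases(tr$chemical, b$interactions, b$annotations, b$graph,
                         mode = "conventional")
  aug <- infer_diseases(tr$chemical, b$interactions, b$annotations, b$graph,
                        mode = "augmented", dataset = b$datasets[[1]],
                        tissue = tr$tissue, level = "low")
  p_conv <- conv$results$adjusted_p[conv$results$term == tr$term]
  p_aug <- aug$results$adjusted_p[aug$results$term == tr$term]
  expect_true(tr$term %in% aug$enriched$term)
  expect_lte(p_aug, p_conv)
  # decoy terms relevant to the planted tissue drop out under the filter
  tset <- setdiff(b$tissue_sets[[tr$tissue]], tr$term)
  expect_gt(length(intersect(conv$enriched$term, tset)),
            length(intersect(aug$enriched$term, tset)))
})

test_that("inference handles unknown chemicals and missing augmented inputs", {
  b <- generate_bundle(fixture_config(seed = 2, n_genes = 100, n_chemicals = 2,
                                      n_terms = 25, n_tissues = 2,
                                      n_signal_genes = 4, n_decoy_terms = 2,
                                      n_decoy_genes_per_term = 3))
  expect_warning(rep <- infer_diseases("CHEM999", b$interactions, b$annotations,
                                       b$graph, mode = "conventional"))
  expect_true(rep$empty_protein_set)
  expect_equal(nrow(rep$enriched), 0)
  expect_error(
    infer_diseases("CHEM001", b$interactions, b$annotations, b$graph,
                   mode = "augmented"),
    class = "tissuetox_config_error")
})
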