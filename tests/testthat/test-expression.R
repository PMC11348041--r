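test_that("TSV loading parses all dialects and flags bad cells", {
  path <- write_tsv_fixture(
    c("GeneID", "GeneName", "kidney", "brain"),
    list(c("g1", "alpha", "0.2", "1.5"),
         c("g2", "beta", "0.7", ""),
         c("g3", "gamma", "6.0", "0.1")))
  ds <- load_expression_matrix(path, "rna_tpm")
  expect_equal(gene_count(ds), 3)
  expect_equal(ds$tissues, c("kidney", "brain"))
  expect_true(is.na(ds$values["g2", "brain"]))  # empty cell = not measured
  expect_equal(ds$values["g1", "kidney"], 0.2)

  bad <- write_tsv_fixture(c("GeneID", "kidney"), list(c("g1", "-1")))
  expect_error(load_expression_matrix(bad, "rna_tpm"),
               "negative.*g1.*kidney", class = "tissuetox_load_error")

  sq <- write_tsv_fixture(
    c("GeneID", "kidney", "brain"),
    list(c("p1", "low", "High"), c("p2", "medium", "2")))
  dsq <- load_expression_matrix(sq, "protein_semiquant")
  expect_equal(unname(dsq$values["p1", ]), c(1, 3))
  expect_equal(unname(dsq$values["p2", ]), c(2, 2))
  badsq <- write_tsv_fixture(c("GeneID", "kidney"), list(c("p1", "huge")))
  expect_error(load_expression_matrix(badsq, "protein_semiquant"),
               "unknown expression level 'huge'.*p1",
               class = "tissuetox_load_error")
})

test_that("filter boundaries are exclusive: a value equal to the threshold fails", {
  thr <- default_thresholds("rna_tpm")
  expect_false(passes_filter(0.5, "low", thr, "rna_tpm"))
  expect_true(passes_filter(0.51, "low", thr, "rna_tpm"))
  expect_false(passes_filter(5.0, "high", thr, "rna_tpm"))
  expect_true(passes_filter(5.1, "high", thr, "rna_tpm"))
  thrp <- default_thresholds("protein_ppb")
  expect_false(passes_filter(1500, "high", thrp, "protein_ppb"))
  expect_true(passes_filter(1501, "high", thrp, "protein_ppb"))
  # level none passes every measured value, never an unmeasured one
  expect_true(passes_filter(0, "none", thr, "rna_tpm"))
  expect_false(passes_filter(NA_real_, "none", thr, "rna_tpm"))
  # semi-quantitative: low keeps {2,3}; medium and high keep {3}
  expect_equal(passes_filter(c(1, 2, 3), "low", dialect = "protein_semiquant"),
               c(FALSE, TRUE, TRUE))
  expect_equal(passes_filter(c(1, 2, 3), "medium", dialect = "protein_semiquant"),
               c(FALSE, FALSE, TRUE))
  expect_equal(passes_filter(c(1, 2, 3), "high", dialect = "protein_semiquant"),
               c(FALSE, FALSE, TRUE))
})

test_that("genes_passing_filter selects per tissue and validates the tissue", {
  ds <- tiny_expression()
  expect_setequal(genes_passing_filter(ds, "kidney", "low"), c("g2", "g3"))
  expect_setequal(genes_passing_filter(ds, "kidney", "high"), "g3")
  expect_setequal(genes_passing_filter(ds, "kidney", "none"), c("g1", "g2", "g3"))
  # unmeasured g2/brain is excluded even at level none
  expect_setequal(genes_passing_filter(ds, "brain", "none"), c("g1", "g3"))
  expect_error(genes_passing_filter(ds, "liver", "low"),
               "kidney.*brain", class = "tissuetox_tissue_error")
})

test_that("filter stringency is monotone on random datasets", {
  set.seed(42)
  for (i in 1:10) {
    fx <- random_filter_fixture()
    for (ts in fx$dataset$tissues) {
      sets <- lapply(c("none", "low", "medium", "high"), function(lv)
        genes_passing_filter(fx$dataset, ts, lv))
      for (j in 2:4) expect_true(all(sets[[j]] %in% sets[[j - 1]]))
    }
  }
})

test_that("log summaries use the pseudocount and type-7 quartiles", {
  m <- matrix(c(0, 1, 1, 1), nrow = 4, dimnames = list(paste0("g", 1:4), "t"))
  ds <- expression_dataset(m, "rna_tpm")
  s <- log_summary(ds)
  expect_equal(s$min, log10(0.01), tolerance = 1e-12)
  expect_equal(s$max, log10(1.01), tolerance = 1e-12)

  set.seed(7)
  v <- stats::runif(100, 0, 10)
  ds2 <- expression_dataset(matrix(v, ncol = 1, dimnames = list(sprintf("g%d", 1:100), "t")),
                            "rna_tpm")
  s2 <- log_summary(ds2, pseudocount = 0.01)
  # independent sort-and-interpolate quartile computation
  manual_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  lv <- log10(v + 0.01)
  expect_equal(s2$q1, manual_q(lv, 0.25), tolerance = 1e-12)
  expect_equal(s2$median, manual_q(lv, 0.5), tolerance = 1e-12)
  expect_equal(s2$q3, manual_q(lv, 0.75), tolerance = 1e-12)

  sq <- expression_dataset(matrix(c(1, 2, 3), ncol = 1,
                                  dimnames = list(paste0("p", 1:3), "t")),
                           "protein_semiquant")
  expect_error(log_summary(sq), class = "tissuetox_dialect_error")
})

test_that("threshold percentiles count values at or below the cut", {
  m <- matrix(c(0, 0, 1, 2), ncol = 1, dimnames = list(paste0("g", 1:4), "t"))
  ds <- expression_dataset(m, "rna_tpm")
  expect_equal(threshold_percentile(ds, "t", 0.5), 50)
  expect_equal(threshold_percentile(ds, "t", -1), 0)
  expect_equal(threshold_percentile(ds, "t", 2), 100)
  # non-decreasing in the threshold
  ths <- seq(-1, 3, by = 0.25)
  pct <- vapply(ths, function(x) threshold_percentile(ds, "t", x), numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("write/reload round trip reproduces filter decisions", {
  set.seed(11)
  fx <- random_filter_fixture()
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(fx$dataset, path)
  ds2 <- load_expression_matrix(path, "rna_tpm", dataset_id = "RND")
  for (ts in fx$dataset$tissues) {
    for (lv in c("none", "low", "medium", "high")) {
      expect_identical(genes_passing_filter(fx$dataset, ts, lv),
                       genes_passing_filter(ds2, ts, lv))
    }
  }
})
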