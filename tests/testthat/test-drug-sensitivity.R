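make_results <- function(genes, pcc, q = rep(0.01, length(genes))) {
  tibble::tibble(gene = genes, pcc = pcc, n_pairs = 30,
                 p = q, q = q)
}

test_that("per-gene PCC handles sign, affine invariance and missing cell lines", {
  cells <- paste0("c", 1:6)
  expr <- rbind(
    anti = c(3, 2, 1, 6, 5, 4),
    same = c(1, 2, 3, 4, 5, 6),
    shifted = 5 * c(1, 2, 3, 4, 5, 6) + 7
  )
  colnames(expr) <- cells
  drug <- stats::setNames(c(1, 2, 3, 4, 5, 6), cells)
  drug_neg <- stats::setNames(c(3, 2, 1, 6, 5, 4), cells)
  res <- per_gene_drug_pcc(expr, drug)
  expect_equal(res$pcc[res$gene == "same"], 1)
  expect_equal(res$pcc[res$gene == "shifted"], 1)
  expect_equal(per_gene_drug_pcc(expr, drug_neg)$pcc[1], 1)
  expect_equal(res$pcc[res$gene == "anti"],
               cor(expr["anti", ], drug))

  # NA cell line handled pairwise; gene below min_pairs omitted
  expr2 <- expr
  expr2["same", 1:4] <- NA
  expect_message(res2 <- per_gene_drug_pcc(expr2, drug), "omitted")
  expect_false("same" %in% res2$gene)
  expect_equal(sort(res2$n_pairs), c(6, 6))
})

test_that("p-values follow the t transform and q the BH adjustment", {
  set.seed(5)
  expr <- matrix(rnorm(50 * 20), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  drug <- stats::setNames(rnorm(20), paste0("c", 1:20))
  res <- per_gene_drug_pcc(expr, drug)
  i <- 7
  ct <- cor.test(expr[res$gene[i], ], drug)
  expect_equal(res$pcc[i], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p[i], ct$p.value, tolerance = 1e-10)
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("negative-correlation threshold picks the least extreme significant negative PCC", {
  res <- make_results(c("a", "b", "c"), c(-0.5, -0.2, -0.1),
                      q = c(0.01, 0.04, 0.2))
  expect_equal(negative_fdr_threshold(res), -0.2)
  expect_true(is.na(negative_fdr_threshold(
    make_results(c("a", "b"), c(0.3, 0.5)))))

  # single strongly anticorrelated gene at n = 30 is significant on its own
  set.seed(1)
  cells <- paste0("c", 1:30)
  drug <- stats::setNames(rnorm(30), cells)
  expr <- matrix(-0.9 * drug + sqrt(1 - 0.81) * rnorm(30), nrow = 1,
                 dimnames = list("g1", cells))
  res1 <- per_gene_drug_pcc(expr, drug)
  expect_equal(res1$q, res1$p)  # single-test BH identity
  expect_lt(res1$q, 0.05)
  expect_equal(negative_fdr_threshold(res1), res1$pcc)
})

test_that("random-set null is reproducible, has the configured shape, and respects limits", {
  set.seed(3)
  expr <- matrix(rnorm(100 * 30), nrow = 100,
                 dimnames = list(paste0("g", 1:100), paste0("c", 1:30)))
  drug <- stats::setNames(rnorm(30), paste0("c", 1:30))
  n1 <- random_set_null(10, expr, drug, n_sets = 50, seed = 99)
  n2 <- random_set_null(10, expr, drug, n_sets = 50, seed = 99)
  expect_identical(n1$pcc_sets, n2$pcc_sets)
  expect_equal(dim(n1$pcc_sets), c(50, 10))
  expect_error(random_set_null(101, expr, drug, n_sets = 5, seed = 1),
               class = "pdxresist_validation_error")
  # independent expression: per-set median PCCs centred at zero
  n3 <- random_set_null(10, expr, drug, n_sets = 400, seed = 7)
  expect_lt(abs(mean(apply(n3$pcc_sets, 1, median))), 0.05)
})

test_that("Mann-Whitney enrichment matches rank-arrangement enumeration", {
  null <- structure(list(pcc_sets = matrix(c(3, 4), nrow = 1), set_size = 2,
                         n_sets = 1, seed = 1),
                    class = "null_distribution")
  res <- make_results(c("q1", "q2"), c(1, 2))
  out <- gene_set_negative_enrichment(c("q1", "q2"), res, null)
  expect_equal(out$U, 0)
  expect_equal(out$p, 1 / 6, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:30) {
    m <- sample(2:8, 1)
    n <- sample(2:8, 1)
    vals <- sample(seq(-1, 1, length.out = 200), m + n)  # distinct, no ties
    res <- make_results(paste0("q", 1:m), vals[1:m])
    null <- structure(list(pcc_sets = matrix(vals[(m + 1):(m + n)], nrow = 1),
                           set_size = n, n_sets = 1, seed = 1),
                      class = "null_distribution")
    out <- gene_set_negative_enrichment(paste0("q", 1:m), res, null)
    expect_equal(out$p, mw_less_oracle(vals[1:m], vals[(m + 1):(m + n)]),
                 tolerance = 1e-10)
  }
})

test_that("query identical to the null is unremarkable; planted negative sets are detected", {
  vals <- seq(-0.5, 0.5, length.out = 20)
  res <- make_results(paste0("q", 1:20), vals)
  null <- structure(list(pcc_sets = matrix(rep(vals, 5), nrow = 5, byrow = TRUE),
                         set_size = 20, n_sets = 5, seed = 1),
                    class = "null_distribution")
  out <- gene_set_negative_enrichment(paste0("q", 1:20), res, null)
  expect_equal(out$p, 0.5, tolerance = 0.02)

  cfg <- simulation_config(seed = 17, n_genes = 400, n_cell_lines = 200,
                           planted_rho = -0.4, planted_set_size = 30)
  ed <- simulate_expression_drug(cfg)
  pcc <- per_gene_drug_pcc(ed$expr, ed$drug)
  null <- random_set_null(30, ed$expr, ed$drug, n_sets = 300, seed = 18,
                          results = pcc)
  planted <- ed$truth$gene[ed$truth$planted]
  expect_lt(gene_set_negative_enrichment(planted, pcc, null)$p, 0.001)
})

test_that("enrichment p is calibrated under the null and shrinks with |rho| and panel size", {
  ps <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = s, n_genes = 150, n_cell_lines = 60,
                             planted_rho = 0, planted_set_size = 15)
    ed <- simulate_expression_drug(cfg)
    pcc <- per_gene_drug_pcc(ed$expr, ed$drug)
    null <- random_set_null(15, ed$expr, ed$drug, n_sets = 100,
                            seed = s + 1000, results = pcc)
    gene_set_negative_enrichment(ed$truth$gene[ed$truth$planted], pcc, null)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.05 + 0.12)  # ~5% plus Monte-Carlo slack on 30 reps
  expect_gt(mean(ps), 0.25)                # roughly uniform, not skewed small

  p_at <- function(rho, n_cells, s = 4) {
    cfg <- simulation_config(seed = s, n_genes = 200, n_cell_lines = n_cells,
                             planted_rho = rho, planted_set_size = 20)
    ed <- simulate_expression_drug(cfg)
    pcc <- per_gene_drug_pcc(ed$expr, ed$drug)
    null <- random_set_null(20, ed$expr, ed$drug, n_sets = 200,
                            seed = s + 1, results = pcc)
    gene_set_negative_enrichment(ed$truth$gene[ed$truth$planted], pcc, null)$p
  }
  expect_lt(p_at(-0.4, 100), p_at(-0.2, 100))
  expect_lt(p_at(-0.2, 300), p_at(-0.2, 60))
})

test_that("expression and IC50 TSV readers index by gene/drug and cell line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = c("g1", "g2"), c1 = c(1.5, 2), c2 = c(3, 4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_expression_matrix(path)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["g2", "c2"], 4)
  expect_equal(read_ic50(path, "g1"), c(c1 = 1.5, c2 = 3))
  expect_error(read_ic50(path, "nope"), class = "pdxresist_validation_error")
})
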