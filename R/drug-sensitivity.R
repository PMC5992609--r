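#' Per-gene Pearson correlation with a drug IC50 profile
#'
#' Correlates each gene's expression across cancer cell lines with the
#' (log-scale) IC50 profile of one drug, using pairwise-complete
#' observations. Two-sided p-values come from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom and are
#' Benjamini-Hochberg adjusted across genes. Genes with fewer than
#' `min_pairs` complete pairs are omitted (count reported via message).
#'
#' @param expr Numeric matrix, genes x cell lines, with dimnames.
#' @param drug Named numeric vector of IC50 values indexed by cell line;
#'   names must overlap `colnames(expr)`.
#' @param min_pairs Minimum complete pairs per gene (default 3).
#' @return Tibble: `gene`, `pcc`, `n_pairs`, `p`, `q`.
#' @export
per_gene_drug_pcc <- function(expr, drug, min_pairs = 3) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)) || is.null(names(drug))) {
    abort_pdx("expr must have dimnames and drug must be a named vector",
              "pdxresist_validation_error")
  }
  shared <- intersect(colnames(expr), names(drug))
  if (length(shared) < min_pairs) {
    abort_pdx("fewer shared cell lines than min_pairs",
              "pdxresist_validation_error")
  }
  x <- expr[, shared, drop = FALSE]
  y <- drug[shared]
  ok_y <- !is.na(y)
  n_pairs <- rowSums(!is.na(x[, ok_y, drop = FALSE]))
  r <- suppressWarnings(as.vector(stats::cor(t(x), y, use = "pairwise.complete.obs")))
  keep <- n_pairs >= min_pairs & !is.na(r)
  if (any(!keep)) {
    message(sprintf("%d gene(s) omitted (< %d complete pairs or constant expression)",
                    sum(!keep), min_pairs))
  }
  r <- r[keep]
  n <- n_pairs[keep]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  tibble::tibble(gene = rownames(expr)[keep], pcc = unname(r),
                 n_pairs = unname(n), p = unname(p), q = bh_fdr(unname(p)))
}

#' Threshold of significant negative correlations
#'
#' The least extreme (closest to zero) Pearson correlation among genes with
#' negative correlation and `q < fdr_level` — the dashed-line threshold used
#' when plotting the correlation distribution of a gene set against random
#' sets.
#'
#' @param results Tibble from [per_gene_drug_pcc()].
#' @param fdr_level FDR threshold (default 0.05).
#' @return The threshold PCC, or `NA_real_` when no gene qualifies.
#' @export
negative_fdr_threshold <- function(results, fdr_level = 0.05) {
  sig <- results$pcc[results$pcc < 0 & results$q < fdr_level]
  if (length(sig) == 0) return(NA_real_)
  max(sig)
}

#' Random-gene-set null distribution of correlation profiles
#'
#' Draws `n_sets` gene sets of size `query_size` uniformly at random (without
#' replacement within a set; sets may overlap each other) from all genes with
#' defined correlations, recording each set's vector of per-gene PCCs.
#' Reproducible given `seed`.
#'
#' @param query_size Size of each random set.
#' @param expr,drug As in [per_gene_drug_pcc()].
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed (required).
#' @param results Optional precomputed [per_gene_drug_pcc()] tibble (avoids
#'   recomputation).
#' @return An object of class `null_distribution`: list with `pcc_sets`
#'   (matrix `n_sets` x `query_size`), `set_size`, `n_sets`, `seed`.
#' @export
random_set_null <- function(query_size, expr, drug, n_sets = 1000, seed,
                            results = NULL) {
  if (missing(seed)) abort_pdx("seed is required", "pdxresist_config_error")
  if (is.null(results)) results <- per_gene_drug_pcc(expr, drug)
  if (query_size > nrow(results)) {
    abort_pdx("query_size exceeds the number of genes with defined correlations",
              "pdxresist_validation_error")
  }
  pcc <- stats::setNames(results$pcc, results$gene)
  set.seed(seed)
  sets <- matrix(NA_real_, nrow = n_sets, ncol = query_size)
  for (i in seq_len(n_sets)) {
    sets[i, ] <- pcc[sample.int(length(pcc), query_size)]
  }
  structure(list(pcc_sets = sets, set_size = query_size, n_sets = n_sets,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("random-set null: %d sets of %d genes (seed %d)\n",
              x$n_sets, x$set_size, x$seed))
  invisible(x)
}

#' Negative-correlation enrichment of a gene set against a random-set null
#'
#' Tests whether the per-gene correlations of a query gene set with a drug's
#' IC50 profile are shifted toward negative values relative to the pooled
#' correlations of random gene sets of the same size, with a one-sided
#' Mann-Whitney rank test (alternative: query PCCs are smaller). Exact
#' enumeration is used when both groups have at most 8 values and no ties;
#' the normal approximation with tie correction otherwise.
#'
#' @param query Character vector of gene symbols.
#' @param results [per_gene_drug_pcc()] tibble for the drug.
#' @param null A [random_set_null()] object.
#' @return List with `U` (Mann-Whitney statistic for the query group), `p`
#'   (one-sided p-value) and `n_query` (query genes with defined
#'   correlations).
#' @export
gene_set_negative_enrichment <- function(query, results, null) {
  stopifnot(inherits(null, "null_distribution"))
  qp <- results$pcc[results$gene %in% query]
  if (length(qp) == 0) {
    abort_pdx("no query genes with defined correlations",
              "pdxresist_validation_error")
  }
  pooled <- as.vector(null$pcc_sets)
  exact <- length(qp) <= 8 && length(pooled) <= 8 &&
    !any(duplicated(c(qp, pooled)))
  wt <- suppressWarnings(
    stats::wilcox.test(qp, pooled, alternative = "less",
                       exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, n_query = length(qp))
}

#' Read a genes x cell-lines expression TSV
#' @param path TSV with gene symbols in the first column, one column per
#'   cell line.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a drugs x cell-lines IC50 TSV and extract one drug's profile
#' @param path TSV with drug names in the first column, one column per cell
#'   line.
#' @param drug Drug name (row) to extract; if NULL the full matrix is
#'   returned.
#' @return Named numeric vector (or matrix when `drug` is NULL).
#' @export
read_ic50 <- function(path, drug = NULL) {
  m <- read_expression_matrix(path)
  if (is.null(drug)) return(m)
  if (!drug %in% rownames(m)) {
    abort_pdx(paste("drug not found:", drug), "pdxresist_validation_error")
  }
  m[drug, ]
}
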