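#' Run the full chemoresistance-mutation analysis pipeline
#'
#' Orchestrates all stages from one configuration: input acquisition (either
#' file paths or the seeded synthetic generators), exclusion filtering,
#' per-arm resistance classification, deleteriousness labelling with the
#' category contrast, cross-arm overlap summary, pathway over-representation
#' of the deleterious de novo + enriched genes, and the random-gene-set null
#' for expression-IC50 correlation enrichment. Writes per-stage TSVs and a
#' JSON summary to `out_dir` and returns the summary invisibly-visible as a
#' list.
#'
#' The configuration is a nested list (or path to a YAML file) with keys:
#' * `seed` (required), `out_dir` (optional; no files written when NULL)
#' * `simulate: true` to use the generators, or `inputs:` with
#'   `variants` (TSV/VCF path), `roles` (`germline`, `parental`, named
#'   `adapted`), `predictions` (TSV), `gene_sets` (GMT), `expression` (TSV),
#'   `ic50` (TSV) and `drug` (drug name)
#' * `thresholds:` `min_coverage` (20), `min_alt_reads` (2), `fdr` (0.05),
#'   `min_delta` (0.10), `n_null_sets` (1000)
#' * `simulation:` overrides passed to [simulation_config()]
#'
#' @param config A list or a YAML file path.
#' @return List with elements `records`, `overlap`, `impact`, `pathways`,
#'   `drug_correlation`, `summary` (the JSON-ready summary) and `settings`
#'   (every threshold in effect).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) {
    abort_pdx("config must declare a seed", "pdxresist_config_error")
  }
  thr <- config$thresholds
  settings <- list(
    seed = config$seed,
    min_coverage = thr$min_coverage %||% 20,
    min_alt_reads = thr$min_alt_reads %||% 2,
    fdr = thr$fdr %||% 0.05,
    min_delta = thr$min_delta %||% 0.10,
    n_null_sets = thr$n_null_sets %||% 1000,
    fdr_scope = "within-arm",
    fisher_sidedness = "two-sided",
    min_delta_interpretation = "absolute AF difference (fraction units)",
    null_comparison = "query PCCs vs pooled random-set PCCs"
  )

  if (isTRUE(config$simulate)) {
    sim_args <- config$simulation %||% list()
    sim_args$seed <- config$seed
    scfg <- do.call(simulation_config, sim_args)
    cohort <- simulate_variant_cohort(scfg)
    table <- cohort$table
    predictions <- cohort$predictions
    ed <- simulate_expression_drug(scfg)
    expr <- ed$expr
    drug <- ed$drug
    gene_sets <- NULL  # built below from the query against a synthetic universe
    truth <- cohort$truth
  } else {
    inp <- config$inputs
    if (is.null(inp$variants) || is.null(inp$roles)) {
      abort_pdx("inputs must provide `variants` and `roles`",
                "pdxresist_config_error")
    }
    roles <- sample_roles(inp$roles$germline, inp$roles$parental,
                          unlist(inp$roles$adapted))
    table <- read_variant_table(inp$variants, roles)
    predictions <- if (!is.null(inp$predictions)) {
      read_prediction_labels(inp$predictions)
    } else {
      tibble::tibble(variant_id = character(0), sift = character(0),
                     polyphen = character(0))
    }
    gene_sets <- if (!is.null(inp$gene_sets)) read_gmt(inp$gene_sets) else NULL
    expr <- if (!is.null(inp$expression)) read_expression_matrix(inp$expression) else NULL
    drug <- if (!is.null(inp$ic50)) read_ic50(inp$ic50, inp$drug) else NULL
    truth <- NULL
  }

  somatic <- apply_exclusion_filters(table, min_coverage = settings$min_coverage)
  records <- classify_cohort(somatic, fdr_level = settings$fdr,
                             min_delta = settings$min_delta,
                             min_coverage = settings$min_coverage,
                             min_alt_reads = settings$min_alt_reads)
  overlap <- summarize_overlap(records)
  impact <- deleterious_by_category(records, predictions)

  # genes carrying deleterious de novo or enriched mutations form the query
  uniq <- dplyr::distinct(records, .data$variant_id, .data$gene,
                          .data$consequence, .data$status)
  uniq <- dplyr::left_join(uniq, predictions, by = "variant_id")
  uniq$impact <- suppressWarnings(
    classify_impact(uniq$consequence, uniq$sift, uniq$polyphen))
  query_genes <- unique(uniq$gene[uniq$status %in% c("de_novo", "enriched") &
                                    uniq$impact == "deleterious"])

  pathways <- NULL
  if (isTRUE(config$simulate) && length(query_genes) >= 2) {
    sim_pw <- simulate_pathway_collection(query_genes, seed = config$seed + 3L)
    gene_sets <- sim_pw$collection
  }
  if (!is.null(gene_sets) && length(query_genes) > 0) {
    pathways <- pathway_enrichment(query_genes, gene_sets,
                                   fdr_level = settings$fdr)
  }

  drug_correlation <- NULL
  if (!is.null(expr) && !is.null(drug)) {
    results <- per_gene_drug_pcc(expr, drug)
    query <- if (isTRUE(config$simulate)) {
      # planted gene set stands in for the mutated-gene set on synthetic data
      ed$truth$gene[ed$truth$planted]
    } else {
      intersect(query_genes, results$gene)
    }
    query <- intersect(query, results$gene)
    if (length(query) > 0) {
      null <- random_set_null(length(query), expr, drug,
                              n_sets = settings$n_null_sets,
                              seed = config$seed + 4L, results = results)
      enr <- gene_set_negative_enrichment(query, results, null)
      drug_correlation <- list(
        results = results,
        threshold = negative_fdr_threshold(results, settings$fdr),
        enrichment = enr
      )
    }
  }

  summary <- list(
    settings = settings,
    n_variants_input = nrow(table$variants),
    n_somatic = nrow(somatic$variants),
    filter_log = as.list(attr(somatic, "filter_log")),
    status_counts_per_arm = as.data.frame(overlap$per_arm_counts),
    arm_multiplicity = as.data.frame(overlap$arm_multiplicity),
    deleterious_fractions = as.data.frame(impact$fractions),
    deleterious_contrast = impact$test,
    significant_pathways = if (!is.null(pathways)) {
      pathways$pathway[pathways$significant]
    } else character(0),
    drug_enrichment_p = if (!is.null(drug_correlation)) {
      drug_correlation$enrichment$p
    } else NULL,
    negative_pcc_threshold = if (!is.null(drug_correlation)) {
      drug_correlation$threshold
    } else NULL
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    utils::write.table(as.data.frame(records), out("classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(impact$fractions),
                       out("deleterious_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pathways)) {
      utils::write.table(as.data.frame(pathways), out("pathways.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(drug_correlation)) {
      utils::write.table(as.data.frame(drug_correlation$results),
                         out("drug_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(records = records, overlap = overlap, impact = impact,
                 pathways = pathways, drug_correlation = drug_correlation,
                 truth = truth, summary = summary, settings = settings))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
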