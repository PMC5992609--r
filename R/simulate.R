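#' Simulation configuration for synthetic pipeline inputs
#'
#' Defines the conditions emulated by the generators: an exome cohort
#' sequenced at ~80x mean coverage over a germline sample, a parental
#' xenograft and four treatment-adapted arms, with planted mutations in each
#' resistance category; an expression x IC50 panel of cancer cell lines with
#' a planted negatively correlated gene set; and a deep amplicon with a known
#' substitution error rate. Defaults mirror the modelled study design:
#' planted category counts 64 de novo / 43 completely depleted / 22 enriched
#' / 19 partially depleted / 39 unchanged shared mutations, consequence mix
#' proportional to (6 frameshift, 7 nonsense, 1 splice, 173 missense), 638
#' cell lines, enrichment shift 0.05 -> 0.30.
#'
#' @param n_variants Named integer vector of planted counts per category;
#'   categories: de_novo, completely_depleted, enriched, partially_depleted,
#'   common_unchanged, germline_contaminant, common_snp,
#'   excluded_consequence.
#' @param mean_coverage Mean exome depth (default 80).
#' @param dispersion Negative-binomial dispersion of depth (default 0.1;
#'   `size = 1/dispersion`).
#' @param category_afs Named list of `c(parental, adapted)` true allele
#'   fractions per category.
#' @param arms Adapted arm names.
#' @param arm_assignment `"all"` (each planted variant shifts in every arm)
#'   or `"single"` (round-robin: each variant shifts in exactly one arm).
#' @param deleterious_prob Named vector: probability a planted missense
#'   variant in each category is deleterious by both predictors.
#' @param noise_free Deterministic mode: depth fixed at `mean_coverage`, alt
#'   reads = round(AF x depth).
#' @param n_genes,n_cell_lines,planted_rho,planted_set_size Expression/IC50
#'   simulator: matrix size, planted correlation with the IC50 profile and
#'   planted-set size.
#' @param amplicon_length,amplicon_mean_coverage,error_rate,planted_afs Deep
#'   amplicon simulator: positions, mean depth, substitution error rate and
#'   planted mutation allele fractions.
#' @param seed Integer seed (mandatory; all generators are pure functions of
#'   the configuration including the seed).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_variants = c(de_novo = 64, completely_depleted = 43, enriched = 22,
                   partially_depleted = 19, common_unchanged = 39,
                   germline_contaminant = 20, common_snp = 20,
                   excluded_consequence = 20),
    mean_coverage = 80,
    dispersion = 0.1,
    category_afs = list(
      de_novo = c(parental = 0, adapted = 0.30),
      completely_depleted = c(parental = 0.30, adapted = 0),
      enriched = c(parental = 0.05, adapted = 0.30),
      partially_depleted = c(parental = 0.30, adapted = 0.05),
      common_unchanged = c(parental = 0.30, adapted = 0.30),
      germline_contaminant = c(parental = 0.50, adapted = 0.50),
      common_snp = c(parental = 0.50, adapted = 0.50),
      excluded_consequence = c(parental = 0.30, adapted = 0.30)
    ),
    arms = c("cisplatin", "fluorouracil", "lurbinectedin", "olaparib"),
    arm_assignment = c("all", "single"),
    deleterious_prob = c(de_novo = 0.6, completely_depleted = 0.5,
                         enriched = 0.7, partially_depleted = 0.4,
                         common_unchanged = 0.3),
    noise_free = FALSE,
    n_genes = 1000, n_cell_lines = 638,
    planted_rho = -0.4, planted_set_size = 40,
    amplicon_length = 500, amplicon_mean_coverage = 2000,
    error_rate = 0.002, planted_afs = c(0.05, 0.10, 0.30),
    seed) {
  if (missing(seed)) abort_pdx("seed is mandatory", "pdxresist_config_error")
  arm_assignment <- match.arg(arm_assignment)
  cats <- c("de_novo", "completely_depleted", "enriched", "partially_depleted",
            "common_unchanged", "germline_contaminant", "common_snp",
            "excluded_consequence")
  if (!all(names(n_variants) %in% cats) || any(n_variants < 0)) {
    abort_pdx("n_variants must be a named non-negative vector over the known categories",
              "pdxresist_config_error")
  }
  fr <- unlist(category_afs)
  if (any(fr < 0 | fr > 1)) {
    abort_pdx("category allele fractions must lie in [0, 1]",
              "pdxresist_config_error")
  }
  if (abs(planted_rho) >= 1) {
    abort_pdx("planted_rho must lie strictly inside (-1, 1)",
              "pdxresist_config_error")
  }
  if (error_rate < 0 || error_rate >= 1) {
    abort_pdx("error_rate must lie in [0, 1)", "pdxresist_config_error")
  }
  structure(
    list(n_variants = n_variants, mean_coverage = mean_coverage,
         dispersion = dispersion, category_afs = category_afs, arms = arms,
         arm_assignment = arm_assignment, deleterious_prob = deleterious_prob,
         noise_free = noise_free, n_genes = n_genes,
         n_cell_lines = n_cell_lines, planted_rho = planted_rho,
         planted_set_size = planted_set_size,
         amplicon_length = amplicon_length,
         amplicon_mean_coverage = amplicon_mean_coverage,
         error_rate = error_rate, planted_afs = planted_afs, seed = seed),
    class = "simulation_config"
  )
}

draw_depth <- function(n, config) {
  if (config$noise_free) {
    rep(round(config$mean_coverage), n)
  } else {
    stats::rnbinom(n, mu = config$mean_coverage, size = 1 / config$dispersion)
  }
}

draw_alt <- function(depth, af, config) {
  if (config$noise_free) round(af * depth) else stats::rbinom(length(depth), depth, af)
}

#' Simulate an exome variant cohort with planted resistance categories
#'
#' Generates per-sample allele counts for a germline sample, a parental
#' xenograft and the configured adapted arms. Depth is negative-binomial
#' around the mean coverage (or fixed in noise-free mode); mutant reads are
#' binomial at the category's true allele fraction, and exactly zero in roles
#' where the category requires absence. Germline contaminants carry germline
#' allele fractions of 0.5 or 1.0; common SNPs are flagged `is_common`;
#' excluded-consequence variants receive synonymous/intronic/UTR/in-frame
#' labels. Missense variants get SIFT/PolyPhen-2 style labels with a planted
#' per-category both-deleterious probability.
#'
#' @param config A [simulation_config].
#' @return List with `table` (a [variant_table]), `truth` (tibble:
#'   `variant_id`, `gene`, `category`, `affected_arms`, `true_deleterious`),
#'   `predictions` (tibble: `variant_id`, `sift`, `polyphen`) and `roles`.
#' @export
simulate_variant_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  roles <- sample_roles(
    "germline", "parental",
    stats::setNames(paste0("adapted_", config$arms), config$arms)
  )
  nv <- config$n_variants
  n_total <- sum(nv)
  category <- rep(names(nv), nv)

  cons_probs <- c(frameshift = 6, nonsense = 7, splice_site = 1, missense = 173) / 187
  consequence <- ifelse(
    category == "excluded_consequence",
    sample(c("synonymous", "intronic", "utr", "inframe_indel"), n_total,
           replace = TRUE),
    sample(names(cons_probs), n_total, replace = TRUE, prob = cons_probs)
  )

  variants <- tibble::tibble(
    chrom = paste0("chr", sample(1:22, n_total, replace = TRUE)),
    pos = sample.int(5e7, n_total),
    ref = sample(c("A", "C", "G", "T"), n_total, replace = TRUE),
    alt = NA_character_,
    gene = sprintf("GENE%04d", seq_len(n_total)),
    consequence = consequence,
    is_common = category == "common_snp"
  )
  variants$alt <- vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  vid <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(vid)) {  # astronomically unlikely; resample positions
    dup <- which(duplicated(vid))
    variants$pos[dup] <- variants$pos[dup] + sample.int(1000, length(dup))
    vid <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  }

  affected <- if (config$arm_assignment == "all") {
    rep("all", n_total)
  } else {
    config$arms[(seq_len(n_total) - 1) %% length(config$arms) + 1]
  }

  germline_af <- numeric(n_total)
  germline_af[category == "germline_contaminant"] <-
    sample(c(0.5, 1.0), sum(category == "germline_contaminant"), replace = TRUE)
  germline_af[category == "common_snp"] <- 0.5

  truth_af <- function(cat, side) {
    vapply(cat, function(cc) config$category_afs[[cc]][[side]], numeric(1))
  }
  parental_af <- truth_af(category, "parental")
  # germline-positive variants are present in the xenografts too
  parental_af[germline_af > 0] <- pmax(parental_af[germline_af > 0],
                                       germline_af[germline_af > 0])

  obs <- list()
  add_obs <- function(sample_id, af) {
    depth <- draw_depth(n_total, config)
    alt <- draw_alt(depth, af, config)
    alt <- pmin(alt, depth)
    tibble::tibble(variant_id = vid, sample = sample_id,
                   alt_reads = as.integer(alt), total_reads = as.integer(depth))
  }
  obs$germline <- add_obs("germline", germline_af)
  obs$parental <- add_obs("parental", parental_af)
  for (arm in config$arms) {
    af_arm <- truth_af(category, "adapted")
    if (config$arm_assignment == "single") {
      off <- affected != arm & affected != "all"
      af_arm[off] <- parental_af[off]   # unaffected arms track the parental AF
      # de novo variants exist only in their own arm
      af_arm[off & category == "de_novo"] <- 0
    }
    af_arm[germline_af > 0] <- pmax(af_arm[germline_af > 0],
                                    germline_af[germline_af > 0])
    obs[[paste0("adapted_", arm)]] <- add_obs(paste0("adapted_", arm), af_arm)
  }

  missense <- consequence == "missense"
  del_prob <- config$deleterious_prob[category]
  del_prob[is.na(del_prob)] <- 0.3
  planted_del <- missense & stats::runif(n_total) < del_prob
  sift <- ifelse(missense,
                 ifelse(planted_del, "deleterious",
                        sample(c("tolerated", "deleterious"), n_total, TRUE,
                               prob = c(0.8, 0.2))),
                 "unknown")
  polyphen <- ifelse(missense,
                     ifelse(planted_del, "deleterious",
                            ifelse(sift == "deleterious", "benign",
                                   sample(c("benign", "deleterious"), n_total,
                                          TRUE, prob = c(0.8, 0.2)))),
                     "unknown")
  true_deleterious <- consequence %in% c("frameshift", "nonsense", "splice_site") |
    (missense & planted_del)

  list(
    table = variant_table(variants, dplyr::bind_rows(obs), roles),
    truth = tibble::tibble(variant_id = vid, gene = variants$gene,
                           category = category, affected_arms = affected,
                           true_deleterious = true_deleterious),
    predictions = tibble::tibble(variant_id = vid, sift = sift,
                                 polyphen = polyphen),
    roles = roles
  )
}

#' Simulate an expression matrix and a drug IC50 profile
#'
#' IC50 values are standard normal per cell line; a planted set of genes is
#' drawn from a bivariate normal with correlation `planted_rho` to the IC50
#' vector, all remaining genes are independent standard normal.
#'
#' @param config A [simulation_config].
#' @return List with `expr` (genes x cell lines matrix), `drug` (named
#'   vector) and `truth` (tibble: `gene`, `planted`).
#' @export
simulate_expression_drug <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  cells <- sprintf("CL%04d", seq_len(config$n_cell_lines))
  ic50 <- stats::setNames(stats::rnorm(config$n_cell_lines), cells)

  expr <- matrix(stats::rnorm(config$n_genes * config$n_cell_lines),
                 nrow = config$n_genes, dimnames = list(genes, cells))
  planted <- sample(genes, config$planted_set_size)
  rho <- config$planted_rho
  for (g in planted) {
    expr[g, ] <- rho * ic50 + sqrt(1 - rho^2) * stats::rnorm(config$n_cell_lines)
  }
  list(expr = expr, drug = ic50,
       truth = tibble::tibble(gene = genes, planted = genes %in% planted))
}

#' Simulate a deep-amplicon pileup with a planted error rate
#'
#' Depth per position is negative-binomial around the configured amplicon
#' mean; at clean positions, non-reference calls are binomial at the planted
#' substitution error rate, split uniformly over the three non-reference
#' bases. Planted mutations add mutant calls at their configured allele
#' fractions at distinct positions, which are flagged.
#'
#' @param config A [simulation_config].
#' @return List with `pileup` (an [amplicon_pileup]) and `truth` (tibble:
#'   `pos`, `af`, `alt`).
#' @export
simulate_amplicon_pileup <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  L <- config$amplicon_length
  eps <- config$error_rate
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  depth <- stats::rnbinom(L, mu = config$amplicon_mean_coverage,
                          size = 1 / config$dispersion)
  depth <- pmax(depth, 1L)

  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  n_err <- stats::rbinom(L, depth, eps)
  for (i in seq_len(L)) {
    others <- setdiff(bases, ref[i])
    split <- if (n_err[i] > 0) {
      tabulate(sample.int(3, n_err[i], replace = TRUE), nbins = 3)
    } else c(0L, 0L, 0L)
    counts[i, others] <- split
    counts[i, ref[i]] <- depth[i] - n_err[i]
  }

  mut_pos <- sample.int(L, length(config$planted_afs))
  mut_alt <- character(length(mut_pos))
  for (k in seq_along(mut_pos)) {
    i <- mut_pos[k]
    alt <- sample(setdiff(bases, ref[i]), 1)
    mut_alt[k] <- alt
    extra <- stats::rbinom(1, depth[i], config$planted_afs[k])
    counts[i, alt] <- counts[i, alt] + extra
  }

  pileup <- amplicon_pileup(tibble::tibble(
    pos = seq_len(L), ref = ref,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    ins = 0L, del = 0L,
    flagged = seq_len(L) %in% mut_pos
  ))
  list(pileup = pileup,
       truth = tibble::tibble(pos = mut_pos, af = config$planted_afs,
                              alt = mut_alt))
}

#' Simulate a pathway annotation collection around a mutated-gene query
#'
#' Builds a GMT-style gene-set collection over a synthetic gene universe:
#' one planted pathway over-populated with query genes plus background
#' pathways drawn uniformly from the universe.
#'
#' @param query Character vector of query gene symbols (become part of the
#'   universe).
#' @param n_pathways Total number of pathways (default 20).
#' @param universe_size Size of the gene universe (default 500).
#' @param planted_overlap Number of query genes placed in the planted
#'   pathway (default half the query, at least 2).
#' @param pathway_size Genes per pathway (default 25).
#' @param seed Integer seed.
#' @return List with `collection` (a [gene_set_collection]) and
#'   `planted_pathway` (its name).
#' @export
simulate_pathway_collection <- function(query, n_pathways = 20,
                                        universe_size = 500,
                                        planted_overlap = max(2, length(query) %/% 2),
                                        pathway_size = 25, seed) {
  if (missing(seed)) abort_pdx("seed is mandatory", "pdxresist_config_error")
  set.seed(seed)
  background <- sprintf("BG%04d", seq_len(max(universe_size - length(query), 1)))
  universe <- unique(c(query, background))
  sets <- lapply(seq_len(n_pathways - 1), function(i) {
    sample(universe, min(pathway_size, length(universe)))
  })
  names(sets) <- sprintf("pathway_%02d", seq_len(n_pathways - 1))
  planted <- unique(c(sample(query, min(planted_overlap, length(query))),
                      sample(background, max(pathway_size - planted_overlap, 1))))
  sets[["planted_pathway"]] <- planted
  list(collection = gene_set_collection(sets, universe),
       planted_pathway = "planted_pathway")
}
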