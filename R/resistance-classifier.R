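#' Classify one variant's resistance status in one adapted arm
#'
#' Implements the three-way scheme used to relate somatic mutations to
#' chemoresistance:
#'
#' * **de novo** — called in the adapted xenograft (passes the calling
#'   thresholds) while completely absent from the parental one: zero mutant
#'   reads at a locus covered at least 20-fold.
#' * **completely depleted** — the mirror image: called in the parental
#'   xenograft, zero mutant reads at >= 20-fold coverage in the adapted one.
#' * **in common** — at least one mutant read with >= 20-fold coverage in
#'   both samples; resolved downstream into enriched / partially depleted /
#'   unchanged by [classify_cohort()] via a Fisher test on the allele counts.
#' * **undetermined** — anything else: a missing observation or coverage too
#'   low to certify presence or absence.
#'
#' @param parental,adapted Lists with elements `alt_reads` and `total_reads`,
#'   or `NULL` when the sample has no observation at the locus.
#' @param consequence Consequence label (frameshift relaxes the coverage
#'   requirement on the side where the mutation is present).
#' @param min_coverage Depth certifying absence or low-frequency presence
#'   (default 20).
#' @param min_alt_reads Mutant reads required for a call (default 2).
#' @return One of `"de_novo"`, `"completely_depleted"`, `"in_common"`,
#'   `"undetermined"`.
#' @examples
#' classify_variant_status(list(alt_reads = 0, total_reads = 25),
#'                         list(alt_reads = 8, total_reads = 40),
#'                         "missense")  # de_novo
#' @export
classify_variant_status <- function(parental, adapted, consequence,
                                    min_coverage = 20, min_alt_reads = 2) {
  absent_certified <- function(o) {
    !is.null(o) && !is.na(o$alt_reads) && o$alt_reads == 0 &&
      o$total_reads >= min_coverage
  }
  called <- function(o) {
    !is.null(o) && !is.na(o$alt_reads) &&
      passes_calling_thresholds(o$alt_reads, o$total_reads, consequence,
                                min_coverage, min_alt_reads)
  }
  present_low <- function(o) {
    !is.null(o) && !is.na(o$alt_reads) && o$alt_reads >= 1 &&
      o$total_reads >= min_coverage
  }
  if (called(adapted) && absent_certified(parental)) return("de_novo")
  if (called(parental) && absent_certified(adapted)) return("completely_depleted")
  if (present_low(parental) && present_low(adapted)) return("in_common")
  "undetermined"
}

#' Fisher exact test for an allele-frequency shift
#'
#' Two-sided Fisher exact test on the 2x2 table of mutant and reference read
#' counts in the parental versus adapted sample, together with the signed
#' allele-frequency difference (adapted minus parental). Used for mutations
#' shared by both samples to decide whether the mutant allele was enriched or
#' depleted under treatment.
#'
#' @param parental,adapted Lists with `alt_reads` and `total_reads`; both
#'   must satisfy the in-common precondition (>= 1 mutant read, >= 20-fold
#'   coverage by default).
#' @param min_coverage,min_alt_reads Precondition thresholds.
#' @return List with `p` (two-sided Fisher p-value) and `delta_af`.
#' @export
fisher_af_shift <- function(parental, adapted, min_coverage = 20,
                            min_alt_reads = 1) {
  for (o in list(parental, adapted)) {
    if (o$total_reads < min_coverage || o$alt_reads < min_alt_reads) {
      abort_pdx("fisher_af_shift requires >= 1 mutant read at >= 20-fold coverage in both samples",
                "pdxresist_contract_error")
    }
  }
  tab <- matrix(c(parental$alt_reads, parental$total_reads - parental$alt_reads,
                  adapted$alt_reads, adapted$total_reads - adapted$alt_reads),
                nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(p = min(p, 1),
       delta_af = adapted$alt_reads / adapted$total_reads -
         parental$alt_reads / parental$total_reads)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values; order-preserving with the
#' input, each adjusted value lies in `[p, 1]`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    abort_pdx("p-values must lie in [0, 1]", "pdxresist_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify every (somatic variant, adapted arm) pair of a cohort
#'
#' Applies [classify_variant_status()] per variant and arm, then resolves the
#' in-common branch: Fisher exact p-values on the parental-vs-adapted allele
#' counts are adjusted by Benjamini-Hochberg within each arm, and a shared
#' mutation is called **enriched** when `q < fdr_level` and its allele
#' frequency rose by at least `min_delta` (10 percentage points by default),
#' **partially depleted** when `q < fdr_level` and it fell by at least
#' `min_delta`, and **common_unchanged** otherwise. Both the significance and
#' the effect-size condition are required; a significant shift smaller than
#' `min_delta` is deliberately not reported as a change.
#'
#' @param table A [variant_table] that already passed
#'   [apply_exclusion_filters()].
#' @param fdr_level FDR threshold for a significant shift (default 0.05).
#' @param min_delta Minimum absolute allele-frequency change, in fraction
#'   units (default 0.10).
#' @param min_coverage,min_alt_reads Calling thresholds passed through.
#' @return Tibble with one row per (variant, arm): `variant_id`, `gene`,
#'   `consequence`, `arm`, `status`, `parental_af`, `adapted_af`, `delta_af`,
#'   `fisher_p`, `fdr_q`. `fisher_p`/`fdr_q` are `NA` outside the in-common
#'   branch.
#' @export
classify_cohort <- function(table, fdr_level = 0.05, min_delta = 0.10,
                            min_coverage = 20, min_alt_reads = 2) {
  stopifnot(inherits(table, "variant_table"))
  v <- table$variants
  if (nrow(v) == 0) {
    warning("empty somatic variant set; returning no records")
    return(tibble::tibble(
      variant_id = character(0), gene = character(0),
      consequence = character(0), arm = character(0), status = character(0),
      parental_af = numeric(0), adapted_af = numeric(0),
      delta_af = numeric(0), fisher_p = numeric(0), fdr_q = numeric(0)
    ))
  }
  par <- observations_for_sample(table, table$roles$parental)

  out <- lapply(names(table$roles$adapted), function(arm) {
    ad <- observations_for_sample(table, table$roles$adapted[[arm]])
    n <- nrow(v)
    status <- character(n)
    p <- rep(NA_real_, n)
    delta <- rep(NA_real_, n)
    paf <- ifelse(!is.na(par$total_reads) & par$total_reads > 0,
                  par$alt_reads / par$total_reads, NA_real_)
    aaf <- ifelse(!is.na(ad$total_reads) & ad$total_reads > 0,
                  ad$alt_reads / ad$total_reads, NA_real_)
    for (i in seq_len(n)) {
      po <- if (is.na(par$alt_reads[i])) NULL else
        list(alt_reads = par$alt_reads[i], total_reads = par$total_reads[i])
      ao <- if (is.na(ad$alt_reads[i])) NULL else
        list(alt_reads = ad$alt_reads[i], total_reads = ad$total_reads[i])
      status[i] <- classify_variant_status(po, ao, v$consequence[i],
                                           min_coverage, min_alt_reads)
      if (status[i] == "in_common") {
        ft <- fisher_af_shift(po, ao, min_coverage = min_coverage)
        p[i] <- ft$p
        delta[i] <- ft$delta_af
      } else if (!is.null(po) && !is.null(ao) &&
                 par$total_reads[i] > 0 && ad$total_reads[i] > 0) {
        delta[i] <- aaf[i] - paf[i]
      }
    }
    q <- rep(NA_real_, n)
    common <- which(status == "in_common")
    if (length(common) > 0) {
      q[common] <- bh_fdr(p[common])
      status[common] <- ifelse(
        q[common] < fdr_level & delta[common] >= min_delta, "enriched",
        ifelse(q[common] < fdr_level & delta[common] <= -min_delta,
               "partially_depleted", "common_unchanged"))
    }
    tibble::tibble(
      variant_id = v$variant_id, gene = v$gene, consequence = v$consequence,
      arm = arm, status = status,
      parental_af = paf, adapted_af = aaf, delta_af = delta,
      fisher_p = p, fdr_q = q
    )
  })
  dplyr::bind_rows(out)
}

#' Cross-arm overlap summary of classification records
#'
#' Summarises how mutation statuses distribute across treatment arms: counts
#' per status per arm, the number of variants holding a status in exactly
#' `k` arms (arm-specificity spectrum), and the variants sharing a status
#' across all arms. Completely and partially depleted calls are additionally
#' pooled into a single `depleted` category, deduplicated per variant, since
#' the same variant can be completely depleted in one setting and partially
#' depleted in another.
#'
#' @param records Tibble from [classify_cohort()].
#' @return An object of class `cross_model_summary`: a list with
#'   `per_arm_counts`, `arm_multiplicity` (per status and pooled `depleted`:
#'   variants with that status in exactly k arms), `shared_all` (variants
#'   with a status in every arm) and `n_arms`.
#' @export
summarize_overlap <- function(records) {
  arms <- unique(records$arm)
  n_arms <- length(arms)

  per_arm_counts <- dplyr::count(records, .data$arm, .data$status,
                                 name = "n")

  multiplicity_of <- function(df) {
    dplyr::count(dplyr::count(df, .data$variant_id, name = "n_arms_with"),
                 .data$n_arms_with, name = "n_variants")
  }
  statuses <- setdiff(unique(records$status), NA)
  arm_multiplicity <- dplyr::bind_rows(lapply(statuses, function(s) {
    m <- multiplicity_of(records[records$status == s, ])
    m$status <- s
    m
  }))
  pooled <- records[records$status %in%
                      c("completely_depleted", "partially_depleted"), ]
  pooled <- dplyr::distinct(pooled, .data$variant_id, .data$arm)
  if (nrow(pooled) > 0) {
    m <- multiplicity_of(pooled)
    m$status <- "depleted"
    arm_multiplicity <- dplyr::bind_rows(arm_multiplicity, m)
  }
  arm_multiplicity <- arm_multiplicity[, c("status", "n_arms_with", "n_variants")]

  shared_all <- lapply(stats::setNames(nm = statuses), function(s) {
    tab <- table(records$variant_id[records$status == s])
    names(tab)[tab == n_arms]
  })
  shared_all$depleted <- {
    tab <- table(pooled$variant_id)
    names(tab)[tab == n_arms]
  }

  structure(
    list(per_arm_counts = per_arm_counts,
         arm_multiplicity = tibble::as_tibble(arm_multiplicity),
         shared_all = shared_all,
         n_arms = n_arms),
    class = "cross_model_summary"
  )
}

#' @export
print.cross_model_summary <- function(x, ...) {
  cat(sprintf("cross-arm summary over %d arms\n", x$n_arms))
  print(tidyr::pivot_wider(x$per_arm_counts, names_from = "status",
                           values_from = "n", values_fill = 0L))
  invisible(x)
}
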