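#' Consensus deleteriousness classification
#'
#' A mutation is labelled deleterious when it is a frameshift, nonsense or
#' canonical splice-site change, or a missense change predicted deleterious
#' by *both* SIFT and PolyPhen-2. All remaining missense changes are
#' non-deleterious. PolyPhen-2's probably/possibly-damaging grades are
#' expected to be collapsed to `"deleterious"` upstream; missense variants
#' with missing or unknown predictions default to non-deleterious (keeping
#' the deleterious set specific), with a warning.
#'
#' @param consequence Character vector of consequence labels, restricted to
#'   frameshift, nonsense, splice_site, missense.
#' @param sift SIFT labels: `"deleterious"`, `"tolerated"` or `"unknown"`
#'   (`NA` treated as unknown).
#' @param polyphen PolyPhen-2 labels: `"deleterious"`, `"benign"` or
#'   `"unknown"` (`NA` treated as unknown).
#' @return Character vector, `"deleterious"` or `"non_deleterious"`.
#' @examples
#' classify_impact("nonsense")                                  # deleterious
#' classify_impact("missense", "deleterious", "benign")         # non_deleterious
#' classify_impact("missense", "deleterious", "deleterious")    # deleterious
#' @export
classify_impact <- function(consequence, sift = NA_character_,
                            polyphen = NA_character_) {
  n <- length(consequence)
  sift <- rep_len(ifelse(is.na(sift), "unknown", sift), n)
  polyphen <- rep_len(ifelse(is.na(polyphen), "unknown", polyphen), n)
  bad <- setdiff(unique(consequence), RETAINED_CONSEQUENCES)
  if (length(bad) > 0) {
    abort_pdx(paste("classify_impact only applies to retained consequences; got:",
                    paste(bad, collapse = ", ")),
              "pdxresist_validation_error")
  }
  if (!all(sift %in% c("deleterious", "tolerated", "unknown"))) {
    abort_pdx("sift labels must be deleterious/tolerated/unknown",
              "pdxresist_validation_error")
  }
  if (!all(polyphen %in% c("deleterious", "benign", "unknown"))) {
    abort_pdx("polyphen labels must be deleterious/benign/unknown",
              "pdxresist_validation_error")
  }
  missing_pred <- consequence == "missense" &
    (sift == "unknown" | polyphen == "unknown")
  if (any(missing_pred)) {
    warning(sprintf("%d missense variant(s) lack predictions from both algorithms; classified non_deleterious",
                    sum(missing_pred)))
  }
  ifelse(consequence %in% c("frameshift", "nonsense", "splice_site"),
         "deleterious",
         ifelse(sift == "deleterious" & polyphen == "deleterious",
                "deleterious", "non_deleterious"))
}

#' Two-proportion z-test (pooled variance, no continuity correction)
#'
#' Compares the proportion of successes in two groups with the classical
#' pooled z statistic
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}}
#' where \eqn{\hat p} pools both groups, and the two-sided p-value
#' \eqn{2(1 - \Phi(|z|))}. Used to compare the fraction of deleterious
#' mutations between resistance categories (e.g. enriched versus partially
#' depleted).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `z`, `p`, and the group proportions `p1`, `p2`. When the
#'   pooled proportion is degenerate (0 or 1), `z = 0`, `p = 1`, with a
#'   warning.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort_pdx("need 0 <= k <= n and n > 0 in both groups",
              "pdxresist_validation_error")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    warning("degenerate pooled proportion (0 or 1); z undefined, reported as 0")
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = ztest_two_sided_p(z), p1 = p1, p2 = p2)
}

#' Two-sided standard-normal p-value for a z statistic
#'
#' @param z z statistic(s).
#' @return `2 * (1 - pnorm(|z|))`, vectorised.
#' @examples
#' ztest_two_sided_p(2.08) # ~0.0375
#' @export
ztest_two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Read a prediction-label table
#'
#' TSV with the variant key columns `chrom, pos, ref, alt` plus `sift` and
#' `polyphen` label columns (vocabularies as in [classify_impact()]).
#'
#' @param path File path.
#' @return Tibble with a derived `variant_id` key plus the label columns.
#' @export
read_prediction_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "sift", "polyphen")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_pdx(paste("prediction-label TSV missing columns:",
                    paste(missing, collapse = ", ")),
              "pdxresist_parse_error")
  }
  tibble::tibble(
    variant_id = variant_key(df$chrom, df$pos, df$ref, df$alt),
    sift = df$sift, polyphen = df$polyphen
  )
}

#' Deleterious fraction per resistance category, with a category contrast
#'
#' Joins impact labels onto classification records, computes the fraction of
#' deleterious mutations per status (deduplicated per variant within a
#' status), and contrasts two categories with [two_proportion_ztest()].
#'
#' @param records Tibble from [classify_cohort()].
#' @param predictions Tibble with `variant_id`, `sift`, `polyphen` (e.g. from
#'   [read_prediction_labels()]); variants absent from it get unknown labels.
#' @param contrast Character vector of two statuses to compare
#'   (default enriched vs partially_depleted).
#' @return List with `fractions` (tibble: status, n_variants, n_deleterious,
#'   fraction) and `test` (the z-test result for `contrast`, or NULL if a
#'   contrast group is empty).
#' @export
deleterious_by_category <- function(records, predictions,
                                    contrast = c("enriched", "partially_depleted")) {
  uniq <- dplyr::distinct(records, .data$variant_id, .data$consequence,
                          .data$status)
  uniq <- dplyr::left_join(uniq, predictions, by = "variant_id")
  uniq$impact <- suppressWarnings(
    classify_impact(uniq$consequence, uniq$sift, uniq$polyphen))
  fractions <- dplyr::summarise(
    dplyr::group_by(uniq, .data$status),
    n_variants = dplyr::n_distinct(.data$variant_id),
    n_deleterious = dplyr::n_distinct(
      .data$variant_id[.data$impact == "deleterious"]),
    fraction = .data$n_deleterious / .data$n_variants,
    .groups = "drop"
  )
  g1 <- fractions[fractions$status == contrast[1], ]
  g2 <- fractions[fractions$status == contrast[2], ]
  test <- NULL
  if (nrow(g1) == 1 && nrow(g2) == 1 && g1$n_variants > 0 && g2$n_variants > 0) {
    test <- two_proportion_ztest(g1$n_deleterious, g1$n_variants,
                                 g2$n_deleterious, g2$n_variants)
  }
  list(fractions = fractions, test = test)
}
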