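#' Mutation-calling thresholds
#'
#' A point mutation is called when the locus is covered at least
#' `min_coverage`-fold and the mutant nucleotide is seen in at least
#' `min_alt_reads` independent reads. Frameshift mutations are exempt from
#' the coverage requirement: two mutant reads suffice regardless of depth.
#'
#' @param alt_reads,total_reads Read counts (vectorised).
#' @param consequence Consequence label(s), recycled as needed.
#' @param min_coverage Minimum total depth for non-frameshift calls
#'   (default 20).
#' @param min_alt_reads Minimum mutant read count (default 2).
#' @return Logical vector.
#' @examples
#' passes_calling_thresholds(2, 20, "missense")    # TRUE
#' passes_calling_thresholds(3, 15, "missense")    # FALSE: depth < 20
#' passes_calling_thresholds(2, 5, "frameshift")   # TRUE: no depth rule
#' @export
passes_calling_thresholds <- function(alt_reads, total_reads, consequence,
                                      min_coverage = 20, min_alt_reads = 2) {
  check_counts(alt_reads, total_reads, "passes_calling_thresholds input")
  is_fs <- consequence == "frameshift"
  ifelse(is_fs,
         alt_reads >= min_alt_reads,
         alt_reads >= min_alt_reads & total_reads >= min_coverage)
}

#' Restrict a variant table to the analysable somatic mutation set
#'
#' Removes (a) common variants (present in dbSNP with minor allele
#' frequency > 1%, carried on the `is_common` flag), (b) consequences with no
#' expected functional impact (synonymous, intronic, UTR and in-frame
#' insertions/deletions) and (c) variants that are not somatic relative to
#' the patient: a retained variant must show zero mutant reads in the
#' germline sample at certified coverage (>= `min_coverage`). Variants whose
#' germline observation is missing or under-covered cannot be certified
#' somatic and are dropped, with the counts reported in
#' `attr(, "filter_log")`.
#'
#' @param table A [variant_table].
#' @param min_coverage Germline depth required to certify absence
#'   (default 20).
#' @return A filtered [variant_table]; observations of retained variants are
#'   passed through unmodified. The attached `filter_log` attribute counts
#'   removals by reason.
#' @export
apply_exclusion_filters <- function(table, min_coverage = 20) {
  stopifnot(inherits(table, "variant_table"))
  v <- table$variants
  gl <- observations_for_sample(table, table$roles$germline)

  common <- v$is_common
  excluded_cons <- !(v$consequence %in% RETAINED_CONSEQUENCES)
  germline_uncertified <- is.na(gl$total_reads) | gl$total_reads < min_coverage
  germline_positive <- !is.na(gl$alt_reads) & gl$alt_reads > 0

  drop <- common | excluded_cons | germline_positive |
    (germline_uncertified & !common & !excluded_cons & !germline_positive)
  keep_ids <- v$variant_id[!drop]

  out <- variant_table(
    v[!drop, setdiff(names(v), "variant_id")],
    table$observations[table$observations$variant_id %in% keep_ids, ],
    table$roles
  )
  attr(out, "filter_log") <- c(
    common_variant = sum(common),
    excluded_consequence = sum(excluded_cons & !common),
    germline_positive = sum(germline_positive & !common & !excluded_cons),
    insufficient_germline_coverage =
      sum(germline_uncertified & !germline_positive & !common & !excluded_cons)
  )
  out
}
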