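# internal helpers shared across modules

CONSEQUENCES <- c("frameshift", "nonsense", "splice_site", "missense",
                  "synonymous", "intronic", "utr", "inframe_indel")

RETAINED_CONSEQUENCES <- c("frameshift", "nonsense", "splice_site", "missense")

RESISTANCE_STATUSES <- c("de_novo", "completely_depleted", "enriched",
                         "partially_depleted", "common_unchanged",
                         "undetermined")

abort_pdx <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pdxresist_error"))
}

#' @importFrom rlang .data
NULL

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

check_counts <- function(alt_reads, total_reads, where = "observation") {
  bad <- which(!is.finite(alt_reads) | !is.finite(total_reads) |
                 alt_reads < 0 | total_reads < 0 | alt_reads > total_reads |
                 alt_reads != round(alt_reads) | total_reads != round(total_reads))
  if (length(bad) > 0) {
    abort_pdx(
      sprintf("invalid read counts in %s (first offending row: %d; need 0 <= alt_reads <= total_reads, integers)",
              where, bad[1]),
      "pdxresist_validation_error"
    )
  }
  invisible(TRUE)
}
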