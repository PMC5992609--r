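#' Construct a deep-amplicon pileup
#'
#' Per-position base-call counts for one amplicon from deep targeted
#' sequencing, restricted upstream to high-quality base calls (Phred > 30).
#' Positions carrying true mutations or germline variation are flagged and
#' excluded from error-rate estimation.
#'
#' @param counts Tibble/data frame with columns `pos`, `ref` (one of
#'   A/C/G/T), base-call count columns `A`, `C`, `G`, `T`, indel columns
#'   `ins`, `del`, and logical `flagged`.
#' @return An object of class `amplicon_pileup` (a tibble).
#' @export
amplicon_pileup <- function(counts) {
  counts <- tibble::as_tibble(counts)
  required <- c("pos", "ref", "A", "C", "G", "T", "ins", "del", "flagged")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort_pdx(paste("pileup missing columns:", paste(missing, collapse = ", ")),
              "pdxresist_validation_error")
  }
  if (!all(counts$ref %in% c("A", "C", "G", "T"))) {
    abort_pdx("ref base must be one of A/C/G/T", "pdxresist_validation_error")
  }
  num <- as.matrix(counts[, c("A", "C", "G", "T", "ins", "del")])
  if (any(num < 0) || any(num != round(num))) {
    abort_pdx("pileup counts must be non-negative integers",
              "pdxresist_validation_error")
  }
  structure(counts[, required], class = c("amplicon_pileup", class(counts)))
}

#' Estimate the pooled per-base error rate of an amplicon
#'
#' The per-base error rate is the fraction of non-reference base calls among
#' all base calls at positions not affected by mutations or variation
#' (i.e. not flagged), pooled across positions. Equivalent to the
#' coverage-weighted mean of per-position mismatch rates. Indel calls are
#' excluded by default (indel error is treated separately; see
#' [detection_call()]).
#'
#' @param pileup An [amplicon_pileup].
#' @param include_indels Count `ins`/`del` calls as errors and in the
#'   denominator (default FALSE).
#' @return An object of class `error_model`: list with
#'   `per_base_error_rate`, `n_positions_used`, `n_bases_used`.
#' @export
estimate_per_base_error <- function(pileup, include_indels = FALSE) {
  stopifnot(inherits(pileup, "amplicon_pileup"))
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(pileup[, bases])
  total <- rowSums(m)
  ref_calls <- m[cbind(seq_len(nrow(m)), match(pileup$ref, bases))]
  mismatch <- total - ref_calls
  if (include_indels) {
    mismatch <- mismatch + pileup$ins + pileup$del
    total <- total + pileup$ins + pileup$del
  }
  eligible <- !pileup$flagged & total > 0
  if (!any(eligible)) {
    abort_pdx("no unflagged covered positions to estimate the error rate from",
              "pdxresist_validation_error")
  }
  structure(
    list(per_base_error_rate = sum(mismatch[eligible]) / sum(total[eligible]),
         n_positions_used = sum(eligible),
         n_bases_used = sum(total[eligible])),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("amplicon error model: rate %.3g from %d positions (%d base calls)\n",
              x$per_base_error_rate, x$n_positions_used, x$n_bases_used))
  invisible(x)
}

#' Detection-limit call for a low-frequency mutation
#'
#' A substitution observed at an allele frequency below the amplicon's
#' per-base error rate is below the detection limit; at or above the rate it
#' is detected. Small insertions/deletions have a negligible background error
#' rate, so any non-zero indel allele frequency is reported as detected.
#'
#' @param af Allele fraction(s) in `[0, 1]` (vectorised).
#' @param model An [estimate_per_base_error()] result.
#' @param is_indel Logical (recycled).
#' @return Character vector, `"detected"` or `"below_limit"`.
#' @export
detection_call <- function(af, model, is_indel = FALSE) {
  stopifnot(inherits(model, "error_model"))
  if (any(af < 0 | af > 1)) {
    abort_pdx("allele fractions must lie in [0, 1]", "pdxresist_validation_error")
  }
  is_indel <- rep_len(is_indel, length(af))
  ifelse(is_indel,
         ifelse(af > 0, "detected", "below_limit"),
         ifelse(af >= model$per_base_error_rate, "detected", "below_limit"))
}

#' Read an amplicon pileup TSV
#' @param path TSV with the columns described in [amplicon_pileup()].
#' @return An `amplicon_pileup`.
#' @export
read_amplicon_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$flagged <- as.logical(df$flagged)
  amplicon_pileup(df)
}

#' Write an amplicon pileup TSV
#' @param pileup An `amplicon_pileup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_pileup <- function(pileup, path) {
  utils::write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
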