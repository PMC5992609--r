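# Small hand-built cohort fixtures.

toy_roles <- function(arms = c(cisplatin = "CIS", olaparib = "OLA")) {
  sample_roles("GL", "PAR", arms)
}

# One-variant builder: supply per-sample (alt, total) pairs as a named list.
toy_table <- function(obs_by_sample,
                      consequence = "missense",
                      is_common = FALSE,
                      roles = toy_roles()) {
  variants <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T",
    gene = "GENE1", consequence = consequence, is_common = is_common
  )
  observations <- dplyr::bind_rows(lapply(names(obs_by_sample), function(s) {
    tibble::tibble(variant_id = "chr1:100:A:T", sample = s,
                   alt_reads = obs_by_sample[[s]][1],
                   total_reads = obs_by_sample[[s]][2])
  }))
  variant_table(variants, observations, roles)
}

# Multi-variant builder from a long data frame of observations.
build_table <- function(variants_df, obs_df, roles = toy_roles()) {
  variant_table(variants_df, obs_df, roles)
}

obs <- function(alt, total) list(alt_reads = alt, total_reads = total)
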