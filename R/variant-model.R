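#' Define the sample roles of a PDX sequencing cohort
#'
#' A cohort consists of a patient germline sample, the parental (untreated)
#' xenograft and one or more treatment-adapted xenograft arms. All downstream
#' classification is performed per adapted arm against the same parental
#' sample, using the germline sample to restrict analysis to somatic
#' mutations.
#'
#' @param germline Sample identifier of the germline (normal) sample.
#' @param parental Sample identifier of the parental xenograft.
#' @param adapted Named character vector mapping arm names (e.g. `cisplatin`)
#'   to sample identifiers. At least one arm is required.
#'
#' @return An object of class `sample_roles`.
#' @examples
#' sample_roles("GL", "P0",
#'              c(cisplatin = "CIS", fluorouracil = "FLU",
#'                lurbinectedin = "LUR", olaparib = "OLA"))
#' @export
sample_roles <- function(germline, parental, adapted) {
  if (is.null(names(adapted)) || any(names(adapted) == "") || length(adapted) < 1) {
    abort_pdx("`adapted` must be a named vector with at least one arm",
              "pdxresist_config_error")
  }
  ids <- c(germline, parental, unname(adapted))
  if (anyDuplicated(ids)) {
    abort_pdx("sample identifiers must be unique across roles",
              "pdxresist_config_error")
  }
  structure(
    list(germline = germline, parental = parental,
         adapted = adapted),
    class = "sample_roles"
  )
}

#' @export
print.sample_roles <- function(x, ...) {
  cat("PDX sample roles\n")
  cat("  germline:", x$germline, "\n")
  cat("  parental:", x$parental, "\n")
  cat("  adapted arms:",
      paste(sprintf("%s=%s", names(x$adapted), x$adapted), collapse = ", "),
      "\n")
  invisible(x)
}

#' Construct a variant table
#'
#' The central container of the pipeline: a set of genomic variants together
#' with per-sample allele-count observations. An observation that is absent
#' from the table is a distinct state from one recorded with zero reads;
#' classification treats only explicit observations as evidence of coverage.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gene`, `consequence` (one of frameshift, nonsense, splice_site,
#'   missense, synonymous, intronic, utr, inframe_indel) and `is_common`
#'   (logical; present in dbSNP with minor allele frequency > 1%).
#' @param observations Tibble with columns `variant_id`, `sample`,
#'   `alt_reads`, `total_reads`; at most one row per (variant, sample).
#' @param roles A [sample_roles] object.
#'
#' @return An object of class `variant_table` with elements `variants`
#'   (including a derived `variant_id` key), `observations` and `roles`.
#' @export
variant_table <- function(variants, observations, roles) {
  stopifnot(inherits(roles, "sample_roles"))
  variants <- tibble::as_tibble(variants)
  observations <- tibble::as_tibble(observations)

  required_v <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "is_common")
  missing_v <- setdiff(required_v, names(variants))
  if (length(missing_v) > 0) {
    abort_pdx(paste("variants table missing columns:",
                    paste(missing_v, collapse = ", ")),
              "pdxresist_validation_error")
  }
  if (any(variants$pos < 1)) {
    abort_pdx("variant positions must be >= 1 (1-based coordinates)",
              "pdxresist_validation_error")
  }
  if (any(variants$ref == variants$alt)) {
    abort_pdx("ref and alt alleles must differ", "pdxresist_validation_error")
  }
  bad_cons <- setdiff(unique(variants$consequence), CONSEQUENCES)
  if (length(bad_cons) > 0) {
    abort_pdx(paste("unknown consequence label(s):",
                    paste(bad_cons, collapse = ", ")),
              "pdxresist_validation_error")
  }
  variants$variant_id <- variant_key(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)
  if (anyDuplicated(variants$variant_id)) {
    abort_pdx("duplicate variants (same chrom:pos:ref:alt)",
              "pdxresist_validation_error")
  }

  required_o <- c("variant_id", "sample", "alt_reads", "total_reads")
  missing_o <- setdiff(required_o, names(observations))
  if (length(missing_o) > 0) {
    abort_pdx(paste("observations table missing columns:",
                    paste(missing_o, collapse = ", ")),
              "pdxresist_validation_error")
  }
  check_counts(observations$alt_reads, observations$total_reads, "observations")
  orphans <- setdiff(observations$variant_id, variants$variant_id)
  if (length(orphans) > 0) {
    abort_pdx(paste("observations reference unknown variants:",
                    paste(utils::head(orphans, 3), collapse = ", ")),
              "pdxresist_validation_error")
  }
  known <- c(roles$germline, roles$parental, unname(roles$adapted))
  unknown_s <- setdiff(unique(observations$sample), known)
  if (length(unknown_s) > 0) {
    abort_pdx(paste("observations reference samples with no declared role:",
                    paste(unknown_s, collapse = ", ")),
              "pdxresist_role_error")
  }
  if (anyDuplicated(observations[, c("variant_id", "sample")])) {
    abort_pdx("more than one observation for the same (variant, sample)",
              "pdxresist_validation_error")
  }

  structure(
    list(variants = variants,
         observations = observations[, required_o],
         roles = roles),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants, %d observations, %d adapted arms\n",
              nrow(x$variants), nrow(x$observations), length(x$roles$adapted)))
  invisible(x)
}

#' Allele fraction of a variant observation
#'
#' The fraction of reads supporting the mutant allele: the number of mutant
#' reads divided by the total read depth at the locus. Undefined (an error)
#' at zero depth.
#'
#' @param alt_reads,total_reads Non-negative integer read counts (vectorised).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' allele_fraction(10, 40) # 0.25
#' @export
allele_fraction <- function(alt_reads, total_reads) {
  check_counts(alt_reads, total_reads, "allele_fraction input")
  if (any(total_reads == 0)) {
    abort_pdx("allele fraction undefined at total_reads = 0",
              "pdxresist_undefined_af_error")
  }
  alt_reads / total_reads
}

#' Read a variant table from TSV or VCF
#'
#' The TSV layout is long format, one row per (variant, sample) observation,
#' with columns `chrom, pos, ref, alt, gene, consequence, sample, alt_reads,
#' total_reads` and optionally `is_common` (0/1 or logical; defaults to
#' FALSE). A VCF must carry per-sample `AD` (ref,alt allele depths) and `DP`
#' FORMAT fields; gene, consequence and common-variant annotations are read
#' from the INFO keys `GENE`, `CSQ` and the `COMMON` flag. Multi-allelic
#' records are split into one variant per alternate allele.
#'
#' @param path File path.
#' @param roles A [sample_roles] object.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return A [variant_table].
#' @export
read_variant_table <- function(path, roles, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_pdx(paste("file not found:", path), "pdxresist_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") read_variant_tsv(path, roles) else read_variant_vcf(path, roles)
}

read_variant_tsv <- function(path, roles) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort_pdx(paste("cannot parse TSV:", conditionMessage(e)),
                                  "pdxresist_parse_error")
  )
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "sample", "alt_reads", "total_reads")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_pdx(paste0("TSV ", path, " missing columns: ",
                     paste(missing, collapse = ", ")),
              "pdxresist_parse_error")
  }
  if (!"is_common" %in% names(df)) df$is_common <- FALSE
  df$is_common <- as.logical(df$is_common)

  variants <- dplyr::distinct(
    tibble::as_tibble(df[, c("chrom", "pos", "ref", "alt", "gene",
                             "consequence", "is_common")])
  )
  observations <- tibble::tibble(
    variant_id = variant_key(df$chrom, df$pos, df$ref, df$alt),
    sample = df$sample,
    alt_reads = as.integer(df$alt_reads),
    total_reads = as.integer(df$total_reads)
  )
  variant_table(variants, observations, roles)
}

read_variant_vcf <- function(path, roles) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)

  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0("^(;)?", key, "="), "",
                    sub("^;", "", regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))))
    out
  }
  info <- vcfR::getINFO(vcf)
  gene <- info_field(info, "GENE")
  csq <- info_field(info, "CSQ")
  common <- grepl("(^|;)COMMON(;|$|=1)", info)

  rows <- list()
  obs <- list()
  samples <- colnames(ad)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        gene = gene[i], consequence = csq[i], is_common = common[i]
      )
      for (s in samples) {
        ad_parts <- suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
        if (all(is.na(ad_parts))) next  # sample not observed at this site
        alt_k <- ad_parts[k + 1]
        tot <- dp[i, s]
        if (is.na(tot)) tot <- sum(ad_parts, na.rm = TRUE)
        obs[[length(obs) + 1]] <- tibble::tibble(
          variant_id = variant_key(fix$CHROM[i], as.integer(fix$POS[i]),
                                   fix$REF[i], alts[k]),
          sample = s,
          alt_reads = alt_k,
          total_reads = as.integer(tot)
        )
      }
    }
  }
  variant_table(dplyr::bind_rows(rows), dplyr::bind_rows(obs), roles)
}

#' Write a variant table to a long-format TSV
#'
#' Inverse of [read_variant_table()] for the TSV format: re-reading the
#' written file yields a field-identical table.
#'
#' @param table A [variant_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  df <- dplyr::inner_join(table$observations, table$variants, by = "variant_id")
  df <- df[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
               "is_common", "sample", "alt_reads", "total_reads")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Observation lookup for one sample: named list of vectors aligned to
# variant ids; NA marks "absent from file" (distinct from zero reads).
observations_for_sample <- function(table, sample_id) {
  obs <- table$observations[table$observations$sample == sample_id, ]
  idx <- match(table$variants$variant_id, obs$variant_id)
  list(alt_reads = obs$alt_reads[idx], total_reads = obs$total_reads[idx])
}
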