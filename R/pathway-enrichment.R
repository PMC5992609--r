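#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (pathway name -> gene
#'   symbols). Empty pathways are rejected.
#' @param universe Character vector of all annotated genes; defaults to the
#'   union of all set members. Every pathway is restricted to the universe.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == "")) {
    abort_pdx("`sets` must be a non-empty named list", "pdxresist_validation_error")
  }
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(universe)
  sets <- lapply(sets, intersect, y = universe)
  if (any(lengths(sets) == 0)) {
    abort_pdx("pathways with no genes in the universe are not allowed",
              "pdxresist_validation_error")
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (tab-separated: set name, description, member
#'   genes).
#' @param universe Optional explicit gene universe (see
#'   [gene_set_collection()]).
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  gene_set_collection(fgsea::gmtPathways(path), universe)
}

#' Write gene sets to a GMT file
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation by Fisher's exact test
#'
#' For each pathway, forms the 2x2 contingency table of query membership
#' versus pathway membership over the gene universe
#' (`a` = query genes in the pathway, `b` = query genes outside it,
#' `c` = pathway genes not in the query, `d` = the rest of the universe) and
#' tests over-representation with a one-sided Fisher exact test.
#' Benjamini-Hochberg adjustment is applied across all pathways; a pathway is
#' significant when `q < fdr_level`. Query genes outside the universe are
#' dropped (count reported via message).
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection].
#' @param fdr_level FDR threshold (default 0.05).
#' @return Tibble with one row per pathway: `pathway`, the `a`,`b`,`c`,`d`
#'   counts, `odds_ratio` (conditional MLE), `p`, `q`, `significant`.
#' @export
pathway_enrichment <- function(query, collection, fdr_level = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  dropped <- setdiff(query, collection$universe)
  if (length(dropped) > 0) {
    message(sprintf("%d query gene(s) outside the annotation universe dropped",
                    length(dropped)))
  }
  query <- intersect(query, collection$universe)
  if (length(query) == 0) {
    abort_pdx("no query genes in the annotation universe",
              "pdxresist_validation_error")
  }
  n_univ <- length(collection$universe)
  rows <- lapply(names(collection$sets), function(nm) {
    pw <- collection$sets[[nm]]
    a <- length(intersect(query, pw))
    b <- length(query) - a
    c <- length(pw) - a
    d <- n_univ - a - b - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                             alternative = "greater")
    tibble::tibble(pathway = nm, a = a, b = b, c = c, d = d,
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_level
  dplyr::arrange(out, .data$p)
}
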