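## Pedigree-based co-segregation assessment and familial/sporadic labeling.
## Co-segregation here is the operational literature-curation rule: at least
## two genotype-positive family members sharing the phenotype. No LOD
## scoring.

.PED_PHENOTYPES <- c(.PHENOTYPE_LEVELS, "unaffected")

#' Read pedigree tables from TSV
#'
#' Dialect: one row per member with columns family_id, variant_id,
#' member_id, proband (true/false), sex (male/female/unknown), genotype
#' (carrier/non_carrier/unknown), phenotype, relation, and optional
#' father_id / mother_id for transmission checks. Exactly one proband per
#' family.
#'
#' @param path TSV path.
#' @return data.frame of all members; split by family_id for the
#'   per-family operations.
#' @export
readPedigrees <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("family_id", "variant_id", "member_id", "proband", "sex",
            "genotype", "phenotype")
  if (!all(need %in% names(df)))
    stop("pedigree table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!"relation" %in% names(df)) df$relation <- NA_character_
  df$proband <- .parse_bool(as.character(df$proband))
  attr(df$proband, "bad") <- NULL
  df$proband <- as.logical(df$proband)
  df$proband[is.na(df$proband)] <- FALSE
  errs <- character()
  for (fam in unique(df$family_id)) {
    sub <- df[df$family_id == fam, ]
    if (sum(sub$proband) != 1L)
      errs <- c(errs, paste0("family ", fam, ": needs exactly one proband"))
    if (anyDuplicated(sub$member_id))
      errs <- c(errs, paste0("family ", fam, ": duplicate member_id"))
    bad <- setdiff(sub$genotype, c("carrier", "non_carrier", "unknown"))
    if (length(bad))
      errs <- c(errs, paste0("family ", fam, ": unknown genotype ",
                             paste(sQuote(bad), collapse = ", ")))
    badp <- setdiff(sub$phenotype, .PED_PHENOTYPES)
    if (length(badp))
      errs <- c(errs, paste0("family ", fam, ": unknown phenotype ",
                             paste(sQuote(badp), collapse = ", ")))
  }
  if (length(errs))
    stop("pedigree validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  df
}

#' Assess familial co-segregation
#'
#' Returns `"yes"` when at least two genotype-positive (carrier) members
#' share the same phenotype label from `phenotype_set`; `"no"` when
#' genotype data exist but the criterion fails; `"not_assessed"` when
#' fewer than two members have a known genotype. By default the shared
#' label must be identical (the literal rule); with
#' `equivalence = TRUE` the whole `phenotype_set` is treated as one
#' disease spectrum, so two carriers with any labels from the set count.
#'
#' @param pedigree one family's rows (see [readPedigrees()]).
#' @param phenotype_set phenotype labels that count as affected for this
#'   assessment; must be non-empty.
#' @param equivalence treat `phenotype_set` as a single spectrum.
#' @param count_proband whether the proband counts toward the two
#'   genotype-positive members (default TRUE).
#' @return `"yes"`, `"no"` or `"not_assessed"`.
#' @export
assessCosegregation <- function(pedigree,
                                phenotype_set = .PHENOTYPE_LEVELS,
                                equivalence = FALSE,
                                count_proband = TRUE) {
  if (length(phenotype_set) == 0L)
    stop("phenotype_set must be non-empty", call. = FALSE)
  known <- pedigree$genotype %in% c("carrier", "non_carrier")
  if (sum(known) < 2L) return("not_assessed")
  eligible <- pedigree$genotype == "carrier"
  if (!count_proband) eligible <- eligible & !pedigree$proband
  ph <- pedigree$phenotype[eligible]
  ph <- ph[ph %in% phenotype_set]
  hit <- if (equivalence) length(ph) >= 2L
         else any(table(ph) >= 2L)
  if (hit) "yes" else "no"
}

#' Familial or sporadic label for a family
#'
#' Familial when at least two members (regardless of genotype) carry an
#' affected phenotype label; otherwise sporadic.
#'
#' @param pedigree one family's rows.
#' @return `"familial"` or `"sporadic"`.
#' @export
familialLabel <- function(pedigree) {
  affected <- !is.na(pedigree$phenotype) &
    pedigree$phenotype %in% .PHENOTYPE_LEVELS
  if (sum(affected) >= 2L) "familial" else "sporadic"
}

#' X-linked transmission consistency check
#'
#' For genes on the X chromosome, a carrier father cannot transmit the
#' variant to a son. The check walks recorded father-child links
#' (father_id column) and returns FALSE on any carrier-father to
#' carrier-son transmission; it is informational only and never alters a
#' classification. Autosomal genes, and pedigrees without parent links,
#' are vacuously consistent.
#'
#' @param pedigree one family's rows.
#' @param gene gene symbol.
#' @param xlinked_genes genes treated as X-linked, default `"TAZ"`.
#' @return logical.
#' @export
xlinkedConsistency <- function(pedigree, gene, xlinked_genes = "TAZ") {
  if (!toupper(gene) %in% toupper(xlinked_genes)) return(TRUE)
  if (!"father_id" %in% names(pedigree)) return(TRUE)
  carriers <- pedigree$member_id[pedigree$genotype == "carrier"]
  sons <- pedigree$genotype == "carrier" & pedigree$sex == "male" &
    !is.na(pedigree$father_id) & pedigree$father_id %in% carriers
  !any(sons)
}

#' Summarize a set of pedigrees
#'
#' @param pedigrees full pedigree table (all families).
#' @param ... passed to [assessCosegregation()].
#' @return data.frame with one row per family: family_id, variant_id,
#'   label (familial/sporadic), cosegregation.
#' @export
summarizePedigrees <- function(pedigrees, ...) {
  fams <- split(pedigrees, pedigrees$family_id)
  out <- data.frame(
    family_id = names(fams),
    variant_id = vapply(fams, function(f) f$variant_id[1], character(1)),
    label = vapply(fams, familialLabel, character(1)),
    cosegregation = vapply(fams, assessCosegregation, character(1), ...),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
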