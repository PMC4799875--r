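#' @import methods
NULL

## Controlled vocabularies used across the package ---------------------------

#' One-letter amino-acid alphabet (20 canonical residues)
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.INHERITANCE_LEVELS <- c("autosomal_dominant", "autosomal_recessive",
                         "X_linked", "sporadic", "unknown")
.COSEG_LEVELS      <- c("yes", "no", "not_assessed")
.PHENOTYPE_LEVELS  <- c("LVNC", "DCM", "HCM", "Barth", "CHD", "other")
.CLASS_LEVELS      <- c("missense", "nonsense")
.CONSENSUS_LEVELS  <- c("pathogenic", "VUS", "benign", "not_analyzed",
                        "unclassifiable")
.TOOLS             <- c("conservation", "grantham", "sift", "polyphen2")

## Internal: run code with a local RNG seed, leaving the caller's RNG intact.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Classes --------------------------------------------------------------------

#' Curated variant catalog
#'
#' Holds one row per catalog record (a published allele; a cis compound
#' allele is one record) in `records`, and one row per constituent protein
#' change in `changes`. Per-variant tallies throughout the package operate on
#' `changes` so a cis double mutation counts as two variants, matching the
#' study's counting convention.
#'
#' @slot records data.frame of record-level annotations (gene, hgvs_p,
#'   variant_class, inheritance, cosegregation, phenotypes, tool labels,
#'   population presence flags, citations, isoform_mismatch, synthetic).
#' @slot changes data.frame with one row per parsed protein change
#'   (record_id, variant_id, gene, ref, pos, alt, raw).
#' @slot provenance free-text provenance metadata.
#' @export
setClass("VariantCatalog",
         slots = c(records = "data.frame",
                   changes = "data.frame",
                   provenance = "character"))

setValidity("VariantCatalog", function(object) {
  rec <- object@records
  chg <- object@changes
  msg <- character()
  need_rec <- c("record_id", "gene", "hgvs_p", "variant_class")
  if (!all(need_rec %in% names(rec)))
    return(paste("records lacks columns:",
                 paste(setdiff(need_rec, names(rec)), collapse = ", ")))
  need_chg <- c("record_id", "variant_id", "gene", "ref", "pos", "alt", "raw")
  if (!all(need_chg %in% names(chg)))
    return(paste("changes lacks columns:",
                 paste(setdiff(need_chg, names(chg)), collapse = ", ")))
  key <- paste(rec$gene, rec$hgvs_p)
  if (anyDuplicated(key))
    msg <- c(msg, paste("duplicate (gene, hgvs_p):",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (any(!nzchar(rec$gene)))
    msg <- c(msg, "empty gene symbol")
  if (nrow(chg) && !all(chg$record_id %in% rec$record_id))
    msg <- c(msg, "changes reference unknown record_id")
  if (nrow(chg) && anyDuplicated(chg$variant_id))
    msg <- c(msg, "duplicate variant_id in changes")
  ## class consistency: nonsense iff any constituent change is a stop gain
  if (nrow(rec)) {
    has_stop <- vapply(split(chg$alt == "*", chg$record_id)[rec$record_id],
                       any, logical(1))
    want <- ifelse(has_stop, "nonsense", "missense")
    bad <- rec$record_id[rec$variant_class != want]
    if (length(bad))
      msg <- c(msg, paste("variant_class inconsistent with HGVS for:",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Background-population allele-count store
#'
#' One cohort's allele counts keyed on (gene, HGVS p.), possibly split by
#' subpopulation. Invariants (AC <= AN, carriers <= AC, AN <= 2 * cohort
#' size) are enforced by the validity method.
#'
#' @slot cohort_id cohort label, e.g. "ESP" or "ExAC".
#' @slot counts data.frame with columns gene, hgvs_p, subpop, AC, AN,
#'   carrier_count (NA when only alleles are known), n_individuals.
#' @slot n_individuals total cohort size.
#' @export
setClass("PopulationStore",
         slots = c(cohort_id = "character",
                   counts = "data.frame",
                   n_individuals = "integer"))

setValidity("PopulationStore", function(object) {
  ct <- object@counts
  need <- c("gene", "hgvs_p", "subpop", "AC", "AN")
  if (!all(need %in% names(ct)))
    return(paste("counts lacks columns:",
                 paste(setdiff(need, names(ct)), collapse = ", ")))
  msg <- character()
  if (any(ct$AC < 0) || any(ct$AN <= 0)) msg <- c(msg, "need AC >= 0 and AN > 0")
  if (any(ct$AC > ct$AN)) msg <- c(msg, "AC exceeds AN")
  if (length(object@n_individuals) != 1L || object@n_individuals < 0L)
    msg <- c(msg, "n_individuals must be a single non-negative integer")
  ## per-variant checks against genotype-level fields when present
  if (nrow(ct) && "carrier_count" %in% names(ct)) {
    key <- paste(ct$gene, ct$hgvs_p)
    for (k in unique(key)) {
      sub <- ct[key == k, , drop = FALSE]
      carr <- sum(sub$carrier_count, na.rm = TRUE)
      if (!all(is.na(sub$carrier_count))) {
        if (carr > sum(sub$AC)) msg <- c(msg, paste("carriers > AC for", k))
        if (carr > object@n_individuals)
          msg <- c(msg, paste("carriers > cohort size for", k))
      }
      if (sum(sub$AN) > 2 * object@n_individuals)
        msg <- c(msg, paste("AN > 2 * cohort size for", k))
    }
  }
  if (length(msg)) paste(unique(msg), collapse = "; ") else TRUE
})

#' Aggregate triage report
#'
#' Deterministic container for the pipeline's headline statistics: tallies,
#' population-presence counts and overlap, consensus class counts with
#' truncated integer percentages, stratified pathogenic fractions, and
#' heredity counts.
#'
#' @slot stats named list of computed aggregates.
#' @slot provenance named list (inputs, configuration, seed) for
#'   reproducibility.
#' @export
setClass("SummaryReport",
         slots = c(stats = "list", provenance = "list"))

## Accessors ------------------------------------------------------------------

#' @describeIn VariantCatalog record-level table (one row per allele record).
#' @param x a `VariantCatalog`.
#' @export
catalogRecords <- function(x) {
  stopifnot(is(x, "VariantCatalog"))
  x@records
}

#' @describeIn VariantCatalog parsed protein changes (one row per variant).
#' @export
proteinChanges <- function(x) {
  stopifnot(is(x, "VariantCatalog"))
  x@changes
}

#' @describeIn VariantCatalog number of variants (protein changes; a cis
#'   compound record contributes one per constituent change).
#' @export
nVariants <- function(x) nrow(proteinChanges(x))

#' @describeIn VariantCatalog number of allele records.
#' @export
nRecords <- function(x) nrow(catalogRecords(x))

#' @describeIn VariantCatalog genes represented in the catalog.
#' @export
catalogGenes <- function(x) sort(unique(proteinChanges(x)$gene))

#' Variant-level view of a catalog
#'
#' Joins each protein change with its record-level annotations, duplicating
#' record columns across the constituent changes of a cis compound allele.
#' This is the unit of analysis for prediction, consensus and tallies.
#'
#' @param x a `VariantCatalog`.
#' @return data.frame with one row per variant.
#' @export
variantTable <- function(x) {
  stopifnot(is(x, "VariantCatalog"))
  chg <- proteinChanges(x)
  rec <- catalogRecords(x)
  idx <- match(chg$record_id, rec$record_id)
  cbind(chg,
        rec[idx, setdiff(names(rec), c("record_id", "gene")), drop = FALSE],
        row.names = NULL)
}

#' @describeIn PopulationStore cohort label.
#' @param x a `PopulationStore`.
#' @export
cohortId <- function(x) {
  stopifnot(is(x, "PopulationStore"))
  x@cohort_id
}

#' @describeIn PopulationStore allele-count table.
#' @export
storeCounts <- function(x) {
  stopifnot(is(x, "PopulationStore"))
  x@counts
}

#' @describeIn PopulationStore cohort size (number of individuals).
#' @export
nIndividuals <- function(x) {
  stopifnot(is(x, "PopulationStore"))
  x@n_individuals
}

#' @describeIn SummaryReport named list of computed aggregates.
#' @param x a `SummaryReport`.
#' @export
reportStats <- function(x) {
  stopifnot(is(x, "SummaryReport"))
  x@stats
}

## show methods ---------------------------------------------------------------

setMethod("show", "VariantCatalog", function(object) {
  cat("VariantCatalog with", nRecords(object), "records /",
      nVariants(object), "variants in",
      length(catalogGenes(object)), "genes\n")
  cls <- table(factor(variantTable(object)$variant_class,
                      levels = .CLASS_LEVELS))
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  if (nzchar(object@provenance[1]))
    cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "PopulationStore", function(object) {
  nv <- length(unique(paste(object@counts$gene, object@counts$hgvs_p)))
  cat("PopulationStore", sQuote(object@cohort_id), "-",
      object@n_individuals, "individuals,",
      nv, "variants,", nrow(object@counts), "count rows\n")
})

setMethod("show", "SummaryReport", function(object) {
  s <- object@stats
  cat("SummaryReport\n")
  cat("  variants:", s$n_variants, "in", s$n_genes, "genes;",
      "analyzed:", s$n_analyzed, "\n")
  cat("  presence: ESP-like", s$n_esp_positive, "| ExAC-like",
      s$n_exac_positive, "| overlap", s$n_overlap, "\n")
  cc <- s$class_counts
  cp <- s$class_percents
  cat("  classes:",
      paste(sprintf("%s %d (%s%%)", names(cc), unlist(cc),
                    ifelse(is.na(unlist(cp)[names(cc)]), "-",
                           unlist(cp)[names(cc)])),
            collapse = ", "), "\n")
  for (nm in names(s$strata)) {
    st <- s$strata[[nm]]
    cat(sprintf("  stratum %-14s %d/%d pathogenic (%s%%)\n", nm,
                st$n_pathogenic, st$n, ifelse(is.na(st$percent), "-",
                                              st$percent)))
  }
  cat("  heredity:", s$n_familial, "familial,",
      s$n_cosegregating, "co-segregating\n")
})
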