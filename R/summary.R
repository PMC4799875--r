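## Aggregate reporting: per-gene tallies, stratified pathogenic fractions,
## and the deterministic SummaryReport.

#' Per-gene variant tally
#'
#' Counts protein changes per gene (a cis compound record contributes one
#' count per constituent change). Genes with zero variants never appear.
#'
#' @param catalog a [VariantCatalog-class].
#' @return named integer vector sorted by decreasing count, ties by gene.
#' @export
tallyByGene <- function(catalog) {
  stopifnot(is(catalog, "VariantCatalog"))
  chg <- proteinChanges(catalog)
  if (nrow(chg) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(chg$gene)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Pathogenic fraction within a stratum
#'
#' Restricts the consensus classifications to the variants satisfying the
#' stratum and counts pathogenic calls; the percent uses the truncated
#' integer convention with the stratum size as denominator.
#'
#' @param classifications data.frame from [classifyCatalog()].
#' @param stratum logical vector aligned with `classifications`, or a
#'   character vector of variant_ids.
#' @return list(n, n_pathogenic, percent); percent NA for an empty
#'   stratum.
#' @export
stratifiedPathogenicity <- function(classifications, stratum) {
  if (is.character(stratum))
    stratum <- classifications$variant_id %in% stratum
  stopifnot(is.logical(stratum), length(stratum) == nrow(classifications))
  sub <- classifications[stratum & !is.na(stratum), , drop = FALSE]
  n <- nrow(sub)
  np <- sum(sub$classification == "pathogenic")
  list(n = n, n_pathogenic = np,
       percent = if (n > 0L) truncatedPercent(np, n) else NA_integer_)
}

#' Build the aggregate triage report
#'
#' Assembles every headline statistic of the pipeline — variant and gene
#' tallies, presence counts and overlap across the two background cohorts,
#' consensus class counts with truncated percentages, stratified pathogenic
#' fractions (per cohort and for the predominant gene), and heredity
#' counts — from the upstream operations, and re-derives the class counts
#' independently as an internal consistency check.
#'
#' @param catalog a [VariantCatalog-class].
#' @param presences named list of presence tables from [lookupPresence()];
#'   the first element is treated as the ESP-like cohort and the second as
#'   the ExAC-like cohort for the overlap and strata.
#' @param classifications data.frame from [classifyCatalog()].
#' @param pedigrees optional pedigree table (see [readPedigrees()]).
#' @param strata_genes genes to report a per-gene pathogenic stratum for;
#'   default: the most variant-rich gene.
#' @param seed optional seed recorded in provenance.
#' @return a [SummaryReport-class].
#' @export
buildReport <- function(catalog, presences, classifications,
                        pedigrees = NULL, strata_genes = NULL,
                        seed = NULL) {
  stopifnot(is(catalog, "VariantCatalog"), is.list(presences),
            length(presences) >= 2L)
  vt <- variantTable(catalog)
  for (p in presences)
    if (!setequal(p$variant_id, vt$variant_id))
      stop("presence table does not cover the catalog", call. = FALSE)
  if (!setequal(classifications$variant_id, vt$variant_id))
    stop("classifications do not cover the catalog", call. = FALSE)

  per_gene <- tallyByGene(catalog)
  ov <- presenceOverlap(presences[[1]], presences[[2]])
  frac <- if (nrow(classifications)) {
    classificationFractions(classifications, denominator = "analyzed")
  } else {
    data.frame(class = .CONSENSUS_LEVELS, count = 0L, percent = NA_integer_,
               stringsAsFactors = FALSE)
  }
  n_analyzed <- sum(classifications$classification != "not_analyzed")

  ## internal self-check: recount classes straight from the vector
  recount <- table(factor(classifications$classification,
                          levels = .CONSENSUS_LEVELS))
  if (!all(as.integer(recount) == frac$count))
    stop("internal consistency check failed: class counts disagree",
         call. = FALSE)

  if (is.null(strata_genes) && length(per_gene))
    strata_genes <- names(per_gene)[1]
  strata <- list()
  for (k in seq_along(presences)) {
    nm <- names(presences)[k]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("cohort", k)
    ids <- presences[[k]]$variant_id[presences[[k]]$present]
    strata[[paste0(nm, "_positive")]] <-
      stratifiedPathogenicity(classifications, ids)
  }
  for (g in strata_genes) {
    ids <- vt$variant_id[vt$gene == g]
    strata[[paste0("gene_", g)]] <-
      stratifiedPathogenicity(classifications, ids)
  }

  heredity <- list(n_familial = NA_integer_, n_cosegregating = NA_integer_)
  if (!is.null(pedigrees)) {
    ps <- summarizePedigrees(pedigrees)
    heredity$n_familial <- sum(ps$label == "familial")
    heredity$n_cosegregating <- sum(ps$label == "familial" &
                                      ps$cosegregation == "yes")
  }

  stats <- list(
    n_variants = nVariants(catalog),
    n_records = nRecords(catalog),
    n_genes = length(per_gene),
    per_gene_counts = as.list(per_gene),
    n_esp_positive = unname(ov["n_a"]),
    n_exac_positive = unname(ov["n_b"]),
    n_overlap = unname(ov["n_both"]),
    n_analyzed = n_analyzed,
    class_counts = stats::setNames(as.list(frac$count), frac$class),
    class_percents = stats::setNames(as.list(frac$percent), frac$class),
    strata = strata,
    n_familial = heredity$n_familial,
    n_cosegregating = heredity$n_cosegregating)

  stopifnot(sum(per_gene) == stats$n_variants,
            stats$n_overlap <= min(stats$n_esp_positive,
                                   stats$n_exac_positive))

  prov <- list(
    catalog_provenance = catalog@provenance,
    cohorts = vapply(presences, function(p) p$cohort[1], character(1)),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  new("SummaryReport", stats = stats, provenance = prov)
}

#' Serialize a report to canonical JSON
#'
#' Fixed key order and fixed numeric formatting: identical inputs give a
#' byte-identical string.
#'
#' @param report a [SummaryReport-class].
#' @return length-1 character, the JSON document.
#' @export
reportJSON <- function(report) {
  stopifnot(is(report, "SummaryReport"))
  as.character(jsonlite::toJSON(
    list(stats = report@stats, provenance = report@provenance),
    auto_unbox = TRUE, digits = 10, na = "null", pretty = TRUE))
}

#' Write a report to a JSON file
#'
#' @param report a [SummaryReport-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  writeLines(reportJSON(report), path, useBytes = TRUE)
  invisible(path)
}
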