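## Presence/frequency lookup in background-population allele-count stores
## and the carrier-count plausibility rule.

#' Construct a population store
#'
#' @param cohort_id cohort label.
#' @param counts data.frame with columns gene, hgvs_p, subpop, AC, AN and
#'   optionally carrier_count; gene symbols are uppercased and HGVS strings
#'   get a canonical `p.` prefix.
#' @param n_individuals cohort size.
#' @return a [PopulationStore-class].
#' @export
PopulationStore <- function(cohort_id, counts, n_individuals) {
  stopifnot(is.data.frame(counts))
  if (!"subpop" %in% names(counts))
    counts$subpop <- rep("all", nrow(counts))
  if (!"carrier_count" %in% names(counts))
    counts$carrier_count <- rep(NA_integer_, nrow(counts))
  counts$gene <- toupper(trimws(counts$gene))
  counts$hgvs_p <- ifelse(grepl("^p\\.", counts$hgvs_p), counts$hgvs_p,
                          paste0("p.", counts$hgvs_p))
  counts$AC <- as.integer(counts$AC)
  counts$AN <- as.integer(counts$AN)
  counts$carrier_count <- as.integer(counts$carrier_count)
  rownames(counts) <- NULL
  new("PopulationStore", cohort_id = as.character(cohort_id),
      counts = counts, n_individuals = as.integer(n_individuals))
}

#' Read a population allele-count store from TSV
#'
#' Dialect: columns `cohort`, `gene`, `hgvs_p`, `subpop`, `AC`, `AN`,
#' optional `carrier_count`, `n_individuals`. One file may carry several
#' cohorts; `cohort_id` selects one (mandatory when the file is mixed).
#'
#' @param path TSV path.
#' @param cohort_id cohort to extract; default: the single cohort present.
#' @return a [PopulationStore-class].
#' @export
readPopulationStore <- function(path, cohort_id = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("cohort", "gene", "hgvs_p", "AC", "AN", "n_individuals")
  if (!all(need %in% names(df)))
    stop("population store lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  cohorts <- unique(df$cohort)
  if (is.null(cohort_id)) {
    if (length(cohorts) != 1L)
      stop("file holds cohorts ", paste(sQuote(cohorts), collapse = ", "),
           "; supply cohort_id", call. = FALSE)
    cohort_id <- cohorts
  }
  if (!cohort_id %in% cohorts)
    stop("cohort ", sQuote(cohort_id), " not present in ", path, call. = FALSE)
  sub <- df[df$cohort == cohort_id, , drop = FALSE]
  PopulationStore(cohort_id, sub[, setdiff(names(sub), c("cohort",
                                                         "n_individuals"))],
                  n_individuals = unique(sub$n_individuals)[1])
}

#' Read a minimal sites-only VCF as a population store
#'
#' Expects INFO keys `AC` and `AN`, and a per-record `GENE_HGVSP` annotation
#' of the form `GENE:p.X` carrying the protein-level key. Records lacking
#' the annotation are skipped with a warning. Parsing is delegated to
#' `VariantAnnotation::readVcf`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param cohort_id cohort label for the resulting store.
#' @param n_individuals cohort size (sites-only VCFs do not carry it).
#' @return a [PopulationStore-class]; carrier counts are unknown (NA).
#' @export
readPopulationVcf <- function(path, cohort_id, n_individuals) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readPopulationVcf requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!all(c("AC", "AN") %in% names(info)))
    stop("VCF INFO must carry AC and AN", call. = FALSE)
  ann <- if ("GENE_HGVSP" %in% names(info)) {
    v <- info$GENE_HGVSP
    if (is(v, "List") || is.list(v))
      vapply(v, function(x) if (length(x)) as.character(x[[1]])
             else NA_character_, character(1))
    else as.character(v)
  } else rep(NA_character_, nrow(info))
  keep <- !is.na(ann) & grepl(":", ann, fixed = TRUE)
  if (any(!keep))
    warning(sum(!keep), " VCF record(s) lack a GENE_HGVSP annotation; skipped")
  ac <- info$AC
  if (is(ac, "List") || is.list(ac))
    ac <- vapply(ac, function(x) as.integer(x[[1]]), integer(1))
  split_ann <- strsplit(ann[keep], ":", fixed = TRUE)
  counts <- data.frame(
    gene = vapply(split_ann, `[[`, character(1), 1L),
    hgvs_p = vapply(split_ann, `[[`, character(1), 2L),
    subpop = "all",
    AC = as.integer(ac[keep]),
    AN = as.integer(info$AN[keep]),
    stringsAsFactors = FALSE)
  PopulationStore(cohort_id, counts, n_individuals)
}

#' Allele frequency from allele counts
#'
#' Pools subpopulations: AF = sum(AC) / sum(AN), exact at full double
#' precision; any display rounding (the reports use 4 significant figures)
#' is presentation only.
#'
#' @param counts data.frame with columns AC and AN (one row per
#'   subpopulation of one variant), or a numeric vector of allele counts.
#' @param AN allele numbers, when `counts` is given as a numeric AC vector.
#' @return allele frequency in `[0, 1]`.
#' @examples
#' alleleFrequency(data.frame(AC = 1, AN = 121412))  # 8.236e-06
#' @export
alleleFrequency <- function(counts, AN = NULL) {
  if (is.data.frame(counts)) {
    ac <- sum(counts$AC); an <- sum(counts$AN)
  } else {
    ac <- sum(counts); an <- sum(AN)
  }
  if (is.na(an) || an <= 0)
    stop("allele frequency undefined: total AN is zero", call. = FALSE)
  if (ac < 0 || ac > an)
    stop("require 0 <= AC <= AN", call. = FALSE)
  ac / an
}

#' Presence of catalog variants in a population store
#'
#' A variant is present when the store holds a record for its
#' (gene, HGVS p.) key with total AC >= 1. Carrier counts use genotype-level
#' counts when the store has them, otherwise fall back to the allele count
#' (an upper bound on carriers); the convention used is recorded per row.
#'
#' @param catalog a [VariantCatalog-class].
#' @param store a [PopulationStore-class].
#' @param cohort_id expected cohort label; a mismatch with the store is a
#'   configuration error.
#' @param carrier_threshold threshold for [carrierFilter()].
#' @return data.frame with one row per catalog variant: variant_id, gene,
#'   hgvs_p, cohort, present, allele_frequency (NA when absent),
#'   carrier_count, carrier_convention ("genotype", "allele_bound" or NA),
#'   unlikely_pathogenic.
#' @export
lookupPresence <- function(catalog, store, cohort_id = cohortId(store),
                           carrier_threshold = 5L) {
  stopifnot(is(catalog, "VariantCatalog"), is(store, "PopulationStore"))
  if (!identical(cohort_id, cohortId(store)))
    stop("store holds cohort ", sQuote(cohortId(store)),
         ", not ", sQuote(cohort_id), call. = FALSE)
  chg <- proteinChanges(catalog)
  ct <- storeCounts(store)
  store_key <- paste(ct$gene, ct$hgvs_p)
  out <- data.frame(variant_id = chg$variant_id, gene = chg$gene,
                    hgvs_p = chg$raw,
                    cohort = rep(cohort_id, nrow(chg)),
                    present = rep(FALSE, nrow(chg)),
                    allele_frequency = rep(NA_real_, nrow(chg)),
                    carrier_count = rep(0L, nrow(chg)),
                    carrier_convention = rep(NA_character_, nrow(chg)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(chg))) {
    rows <- ct[store_key == paste(chg$gene[i], chg$raw[i]), , drop = FALSE]
    if (nrow(rows) == 0L || sum(rows$AC) < 1L) next
    out$present[i] <- TRUE
    out$allele_frequency[i] <- alleleFrequency(rows)
    if (all(!is.na(rows$carrier_count))) {
      out$carrier_count[i] <- sum(rows$carrier_count)
      out$carrier_convention[i] <- "genotype"
    } else {
      out$carrier_count[i] <- sum(rows$AC)
      out$carrier_convention[i] <- "allele_bound"
    }
  }
  out$unlikely_pathogenic <- carrierFilter(out$carrier_count,
                                           threshold = carrier_threshold)
  out
}

#' Carrier-count plausibility rule
#'
#' Flags a variant as unlikely to be pathogenic when it is carried by more
#' than `threshold` persons in the background cohort (strictly more than;
#' exactly `threshold` carriers do not trigger the flag).
#'
#' @param carrier_count number of carriers (vectorized).
#' @param threshold carrier threshold, default 5.
#' @return logical vector.
#' @examples
#' carrierFilter(c(0, 5, 6))  # FALSE FALSE TRUE
#' @export
carrierFilter <- function(carrier_count, threshold = 5L) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  carrier_count > threshold
}

#' Overlap between two presence tables
#'
#' @param presence_a,presence_b presence tables from [lookupPresence()]
#'   covering the same variant set.
#' @return named integer vector `c(n_a, n_b, n_both)`.
#' @export
presenceOverlap <- function(presence_a, presence_b) {
  if (!setequal(presence_a$variant_id, presence_b$variant_id) ||
      nrow(presence_a) != nrow(presence_b))
    stop("presence tables cover different variant sets", call. = FALSE)
  b <- presence_b[match(presence_a$variant_id, presence_b$variant_id), ]
  c(n_a = sum(presence_a$present),
    n_b = sum(b$present),
    n_both = sum(presence_a$present & b$present))
}
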