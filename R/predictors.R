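## Conservation-across-species channel and normalization adapters for
## externally produced SIFT and PolyPhen-2 labels. SIFT and PolyPhen-2
## themselves are never re-implemented: their categorical outputs are inputs.

#' Construct an alignment column
#'
#' One aligned residue position across a species panel. Gaps are written
#' `"-"`.
#'
#' @param reference reference (human) residue, one letter.
#' @param species named character vector of residues, one per non-reference
#'   species; `"-"` for a gap.
#' @param position 1-based residue index (bookkeeping only).
#' @return list with class `"AlignmentColumn"`.
#' @export
alignmentColumn <- function(reference, species, position = NA_integer_) {
  stopifnot(is.character(reference), length(reference) == 1L,
            reference %in% AA_ALPHABET,
            is.character(species))
  bad <- setdiff(unique(species), c(AA_ALPHABET, "-"))
  if (length(bad))
    stop("residues outside alphabet/gap: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  structure(list(reference = reference, species = species,
                 position = as.integer(position)),
            class = "AlignmentColumn")
}

#' Extract an alignment column from an aligned FASTA
#'
#' Reads an aligned amino-acid FASTA (equal-length sequences, one per
#' species) via `Biostrings::readAAStringSet` and slices one column. The
#' first sequence is taken as the reference unless `reference` names
#' another.
#'
#' @param path FASTA path.
#' @param position 1-based column index.
#' @param reference name of the reference sequence; default: first.
#' @return an [alignmentColumn()].
#' @export
alignmentColumnFromFasta <- function(path, position, reference = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("alignmentColumnFromFasta requires the Biostrings package",
         call. = FALSE)
  aln <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  if (position < 1L || position > w[1])
    stop("position out of range 1..", w[1], call. = FALSE)
  res <- vapply(seq_along(aln), function(i)
    as.character(Biostrings::subseq(aln[[i]], position, position)),
    character(1))
  names(res) <- names(aln)
  if (is.null(reference)) reference <- names(aln)[1]
  if (!reference %in% names(res))
    stop("reference sequence ", sQuote(reference), " not in FASTA",
         call. = FALSE)
  alignmentColumn(res[[reference]], res[names(res) != reference],
                  position = position)
}

#' Conservation call from an alignment column
#'
#' A position with no substitutions across the usable (non-gap) species
#' panel is conserved (pathogenic); one or more substitutions make it not
#' conserved (benign). Fewer than two usable residues (reference included)
#' give no call.
#'
#' @param column an [alignmentColumn()].
#' @return `"pathogenic"`, `"benign"` or `"unavailable"`.
#' @export
conservationCall <- function(column) {
  stopifnot(inherits(column, "AlignmentColumn"))
  usable <- column$species[column$species != "-"]
  if (length(usable) + 1L < 2L) return("unavailable")
  if (all(usable == column$reference)) "pathogenic" else "benign"
}

.normalize_label <- function(label, map, tool) {
  label <- as.character(label)
  out <- rep("unavailable", length(label))
  key <- tolower(trimws(label))
  hit <- key %in% names(map)
  out[hit] <- unname(map[key[hit]])
  odd <- !hit & !is.na(label) & nzchar(key)
  if (any(odd))
    warning("unrecognized ", tool, " label(s): ",
            paste(sQuote(unique(label[odd])), collapse = ", "),
            call. = FALSE)
  out
}

#' Normalize a raw SIFT label
#'
#' Case-insensitive: "damaging" is pathogenic; "tolerated"/"tolerant" is
#' benign; anything else (including empty/NA) is unavailable, with a
#' warning for unrecognized non-empty labels. Numeric SIFT scores are out
#' of scope; only the categorical labels the curated catalog carries are
#' normalized.
#'
#' @param label character vector of raw labels.
#' @return character vector in {pathogenic, benign, unavailable}.
#' @export
normalizeSift <- function(label) {
  .normalize_label(label,
                   c(damaging = "pathogenic",
                     tolerated = "benign", tolerant = "benign"),
                   "SIFT")
}

#' Normalize a raw PolyPhen-2 label
#'
#' "probably damaging" and "possibly damaging" are both pathogenic;
#' "benign" is benign; anything else is unavailable.
#'
#' @param label character vector of raw labels.
#' @return character vector in {pathogenic, benign, unavailable}.
#' @export
normalizePolyphen <- function(label) {
  .normalize_label(label,
                   c("probably damaging" = "pathogenic",
                     "possibly damaging" = "pathogenic",
                     benign = "benign"),
                   "PolyPhen-2")
}

#' Run the four prediction channels over a catalog
#'
#' Per variant: Grantham distance computed from the parsed ref/alt residues
#' and binarized at the cutoff; conservation from the catalog's precomputed
#' `conserved` label or, when absent, from a supplied alignment column (the
#' precomputed label wins when both exist, with a notice); SIFT and
#' PolyPhen-2 labels normalized by the adapters. Stop gains get no calls at
#' all (every channel unavailable): they bypass prediction.
#'
#' @param catalog a [VariantCatalog-class].
#' @param alignments optional named list of [alignmentColumn()]s keyed by
#'   variant_id, used for variants without a precomputed conservation label.
#' @param grantham_cutoff radical/conservative boundary, default 100.
#' @return data.frame with one row per variant: variant_id, gene, raw,
#'   variant_class, grantham_score, and the four calls (columns
#'   conservation, grantham, sift, polyphen2).
#' @export
predictVariants <- function(catalog, alignments = NULL,
                            grantham_cutoff = 100) {
  stopifnot(is(catalog, "VariantCatalog"))
  vt <- variantTable(catalog)
  n <- nrow(vt)
  score <- rep(NA_real_, n)
  mis <- vt$alt != "*"
  score[mis] <- granthamDistance(vt$ref[mis], vt$alt[mis])
  cons <- rep("unavailable", n)
  for (i in seq_len(n)) {
    if (!mis[i]) next
    lab <- vt$conserved[i]
    has_col <- !is.null(alignments) && vt$variant_id[i] %in% names(alignments)
    if (!is.na(lab)) {
      if (has_col)
        message("precomputed conservation label overrides alignment column ",
                "for ", vt$variant_id[i])
      cons[i] <- if (lab == "yes") "pathogenic" else "benign"
    } else if (has_col) {
      cons[i] <- conservationCall(alignments[[vt$variant_id[i]]])
    }
  }
  out <- data.frame(variant_id = vt$variant_id, gene = vt$gene,
                    raw = vt$raw, variant_class = vt$variant_class,
                    grantham_score = score,
                    conservation = cons,
                    grantham = granthamCall(score, cutoff = grantham_cutoff),
                    sift = normalizeSift(vt$sift_label),
                    polyphen2 = normalizePolyphen(vt$polyphen_label),
                    stringsAsFactors = FALSE)
  out$sift[!mis] <- "unavailable"
  out$polyphen2[!mis] <- "unavailable"
  out$conservation[!mis] <- "unavailable"
  out
}
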