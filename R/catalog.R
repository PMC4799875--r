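## Catalog data model and I/O: HGVS p. parsing, variant-class assignment,
## TSV round-trip with full-row diagnostics.

#' Parse a protein-level HGVS short string
#'
#' Accepts the one-letter shorthand `p.<Ref><Pos><Alt>` used throughout the
#' curated catalog, e.g. `p.R243H` or the stop gain `p.G195*`. Three-letter
#' HGVS is deliberately not accepted.
#'
#' @param hgvs HGVS p. string (single change; no semicolons).
#' @param gene gene symbol the change belongs to.
#' @return one-row data.frame with columns gene, ref, pos, alt, raw and a
#'   derived variant_id (`GENE:p.X`).
#' @examples
#' parseProteinChange("p.R243H", "MYH7")
#' parseProteinChange("p.G195*", "TAZ")
#' @export
parseProteinChange <- function(hgvs, gene) {
  stopifnot(is.character(hgvs), length(hgvs) == 1L,
            is.character(gene), length(gene) == 1L, nzchar(gene))
  m <- regmatches(hgvs, regexec("^p\\.([A-Za-z])([0-9]+)([A-Za-z*])$", hgvs))[[1]]
  if (length(m) == 0L)
    stop("malformed HGVS p. string: ", sQuote(hgvs), call. = FALSE)
  ref <- m[2]; pos <- suppressWarnings(as.integer(m[3])); alt <- m[4]
  if (!(ref %in% AA_ALPHABET))
    stop("unknown residue ", sQuote(ref), " in ", sQuote(hgvs), call. = FALSE)
  if (!(alt %in% c(AA_ALPHABET, "*")))
    stop("unknown residue ", sQuote(alt), " in ", sQuote(hgvs), call. = FALSE)
  if (is.na(pos) || pos < 1L)
    stop("invalid position ", sQuote(m[3]), " in ", sQuote(hgvs), call. = FALSE)
  if (ref == alt)
    stop("identical reference and alternate residue ", sQuote(ref),
         " in ", sQuote(hgvs), call. = FALSE)
  data.frame(gene = toupper(gene), ref = ref, pos = pos, alt = alt,
             raw = hgvs, variant_id = paste0(toupper(gene), ":", hgvs),
             stringsAsFactors = FALSE)
}

## Parse a (possibly semicolon-separated cis compound) hgvs_p cell.
parseChanges <- function(hgvs_p, gene) {
  parts <- trimws(strsplit(hgvs_p, ";", fixed = TRUE)[[1]])
  do.call(rbind, lapply(parts, parseProteinChange, gene = gene))
}

#' Classify a protein change as missense or nonsense
#'
#' A change is nonsense (stop gain) exactly when its alternate residue is
#' `*`; every other substitution in the one-letter alphabet is missense.
#'
#' @param change data.frame of parsed changes (as from
#'   [parseProteinChange()]), or a character vector of alternate residues.
#' @return character vector, `"missense"` or `"nonsense"` per change.
#' @examples
#' classifyVariantClass(parseProteinChange("p.G195*", "TAZ"))
#' @export
classifyVariantClass <- function(change) {
  alt <- if (is.data.frame(change)) change$alt else change
  ifelse(alt == "*", "nonsense", "missense")
}

## Canonical column order of the catalog TSV dialect.
.CATALOG_COLS <- c("gene", "hgvs_p", "variant_class", "inheritance",
                   "cosegregation", "phenotypes", "sift_label",
                   "polyphen_label", "conserved", "grantham_score",
                   "esp_positive", "exac_positive", "isoform_mismatch",
                   "synthetic", "citations")

.parse_bool <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "yes", "1")] <- TRUE
  out[x %in% c("false", "no", "0")] <- FALSE
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  attr(out, "bad") <- bad
  out
}

.check_tokens <- function(x, levels) {
  toks <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  setdiff(toks, levels)
}

## Build a VariantCatalog from a record-level data.frame, collecting every
## validation failure before stopping (never a partial silent load).
makeCatalog <- function(records, provenance = "") {
  stopifnot(is.data.frame(records))
  if (!all(c("gene", "hgvs_p") %in% names(records)))
    stop("catalog requires columns: ",
         paste(setdiff(c("gene", "hgvs_p"), names(records)), collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  for (col in .CATALOG_COLS)
    if (!col %in% names(records)) records[[col]] <- rep(NA, n)
  records <- records[, .CATALOG_COLS, drop = FALSE]
  records$gene <- toupper(trimws(as.character(records$gene)))
  records$hgvs_p <- trimws(as.character(records$hgvs_p))

  errs <- character()
  add <- function(i, msg) errs <<- c(errs, sprintf("row %d: %s", i, msg))

  chg_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (!nzchar(records$gene[i])) add(i, "empty gene symbol")
    ch <- tryCatch(parseChanges(records$hgvs_p[i], records$gene[i]),
                   error = function(e) {
                     add(i, conditionMessage(e)); NULL
                   })
    chg_list[[i]] <- ch
    if (!is.null(ch)) {
      derived <- if (any(ch$alt == "*")) "nonsense" else "missense"
      given <- as.character(records$variant_class[i])
      if (!is.na(given) && nzchar(given) && given != derived)
        add(i, sprintf("variant_class %s inconsistent with %s (expected %s)",
                       sQuote(given), sQuote(records$hgvs_p[i]), derived))
      records$variant_class[i] <- derived
    }
    for (spec in list(list("inheritance", .INHERITANCE_LEVELS),
                      list("phenotypes", .PHENOTYPE_LEVELS))) {
      val <- as.character(records[[spec[[1]]]][i])
      if (!is.na(val) && nzchar(val)) {
        bad <- .check_tokens(val, spec[[2]])
        if (length(bad))
          add(i, sprintf("unknown %s token(s): %s", spec[[1]],
                         paste(sQuote(bad), collapse = ", ")))
      }
    }
    cs <- as.character(records$cosegregation[i])
    if (!is.na(cs) && nzchar(cs) && !(cs %in% .COSEG_LEVELS))
      add(i, paste("unknown cosegregation value", sQuote(cs)))
    cons <- as.character(records$conserved[i])
    if (!is.na(cons) && nzchar(cons) && !(tolower(cons) %in% c("yes", "no")))
      add(i, paste("conserved must be yes/no, got", sQuote(cons)))
  }

  key <- paste(records$gene, records$hgvs_p)
  dup <- duplicated(key)
  if (any(dup))
    for (i in which(dup))
      add(i, paste("duplicate (gene, hgvs_p):", sQuote(key[i])))

  for (col in c("esp_positive", "exac_positive", "isoform_mismatch",
                "synthetic")) {
    b <- .parse_bool(as.character(records[[col]]))
    for (i in which(attr(b, "bad")))
      add(i, sprintf("cannot interpret %s value %s as logical", col,
                     sQuote(as.character(records[[col]][i]))))
    attr(b, "bad") <- NULL
    records[[col]] <- as.logical(b)
  }
  records$isoform_mismatch[is.na(records$isoform_mismatch)] <- FALSE
  records$synthetic[is.na(records$synthetic)] <- FALSE
  records$grantham_score <- suppressWarnings(
    as.numeric(as.character(records$grantham_score)))
  cs <- as.character(records$cosegregation)
  cs[is.na(cs) | !nzchar(cs)] <- "not_assessed"
  records$cosegregation <- cs
  for (col in c("inheritance", "phenotypes", "sift_label", "polyphen_label",
                "conserved", "citations")) {
    v <- as.character(records[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA
    records[[col]] <- v
  }
  records$conserved <- tolower(records$conserved)

  if (length(errs))
    stop("catalog validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)

  rid <- if (n) paste0(records$gene, ":", records$hgvs_p) else character(0)
  records <- cbind(record_id = rid, records, stringsAsFactors = FALSE)
  changes <- if (n) {
    ch <- do.call(rbind, Map(function(ch, rid) {
      ch$record_id <- rid
      ch
    }, chg_list, records$record_id))
    ch[, c("record_id", "variant_id", "gene", "ref", "pos", "alt", "raw")]
  } else {
    data.frame(record_id = character(), variant_id = character(),
               gene = character(), ref = character(), pos = integer(),
               alt = character(), raw = character(), stringsAsFactors = FALSE)
  }
  rownames(records) <- rownames(changes) <- NULL
  new("VariantCatalog", records = records, changes = changes,
      provenance = as.character(provenance))
}

#' Read a curated variant catalog from TSV
#'
#' The dialect is UTF-8 TSV with a header; required columns `gene` and
#' `hgvs_p` (semicolon-separated for cis compound alleles), optional
#' annotation columns (`variant_class`, `inheritance`, `cosegregation`,
#' `phenotypes`, `sift_label`, `polyphen_label`, `conserved`,
#' `grantham_score`, `esp_positive`, `exac_positive`, `isoform_mismatch`,
#' `synthetic`, `citations`). Column order is irrelevant; empty cells mean
#' unknown/absent. Rows failing validation are reported all at once with row
#' numbers; the load never partially succeeds.
#'
#' @param path path to the TSV file.
#' @param provenance free-text provenance recorded on the catalog
#'   (defaults to the file path).
#' @return a [VariantCatalog-class] object.
#' @seealso [writeCatalog()] for the inverse; the pair round-trips.
#' @export
readCatalog <- function(path, provenance = path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = TRUE, fileEncoding = "UTF-8")
  makeCatalog(df, provenance = provenance)
}

#' Write a variant catalog to TSV
#'
#' Serializes record-by-record in the catalog dialect; a cis compound allele
#' is a single row with semicolon-joined changes. `readCatalog()` on the
#' output reproduces the catalog field-for-field.
#'
#' @param catalog a [VariantCatalog-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "VariantCatalog"))
  rec <- catalogRecords(catalog)[, .CATALOG_COLS, drop = FALSE]
  for (col in c("esp_positive", "exac_positive", "isoform_mismatch",
                "synthetic"))
    rec[[col]] <- ifelse(is.na(rec[[col]]), "",
                         ifelse(rec[[col]], "true", "false"))
  rec$grantham_score <- ifelse(is.na(rec$grantham_score), "",
                               format(rec$grantham_score, trim = TRUE))
  for (col in names(rec)) {
    v <- as.character(rec[[col]])
    v[is.na(v)] <- ""
    rec[[col]] <- v
  }
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
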