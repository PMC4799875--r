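## The >=3-agreement consensus rule combining the four tool calls, and the
## truncated integer-percent convention used by every report.

#' Consensus policy
#'
#' The defaults encode the borrowed >=3-agreement scheme: at least
#' `pathogenic_min` pathogenic calls among available tools make a variant
#' pathogenic; 1 to `pathogenic_min - 1` make it a VUS; zero pathogenic
#' calls make it benign, but only on a complete four-tool panel — a partial
#' panel with zero pathogenic votes stays VUS with an
#' `incomplete_tool_panel` flag.
#'
#' @param pathogenic_min minimum pathogenic votes for a pathogenic call.
#' @param benign_requires_full_panel logical; see above.
#' @return named list policy object.
#' @export
consensusPolicy <- function(pathogenic_min = 3L,
                            benign_requires_full_panel = TRUE) {
  stopifnot(pathogenic_min >= 1L, pathogenic_min <= 4L)
  list(pathogenic_min = as.integer(pathogenic_min),
       benign_requires_full_panel = isTRUE(benign_requires_full_panel))
}

#' Consensus classification of one variant
#'
#' Stop gains are never run through the missense tools: they come out
#' `not_analyzed`. A variant whose residue could not be mapped onto the
#' protein isoforms (an explicit catalog annotation, never auto-detected)
#' is `unclassifiable`. Otherwise pathogenic votes among the available
#' tools are counted under the policy.
#'
#' @param calls named character vector with entries for the four tool slots
#'   (`conservation`, `grantham`, `sift`, `polyphen2`), each in
#'   {pathogenic, benign, unavailable}. Duplicate slots are an error.
#' @param variant_class `"missense"` or `"nonsense"`.
#' @param isoform_mismatch logical; residue/isoform mapping failure.
#' @param policy a [consensusPolicy()].
#' @return list: classification, n_tools_available, n_pathogenic_votes,
#'   flags (character vector).
#' @examples
#' consensusClassify(c(conservation = "pathogenic", grantham = "pathogenic",
#'                     sift = "pathogenic", polyphen2 = "benign"))
#' @export
consensusClassify <- function(calls, variant_class = "missense",
                              isoform_mismatch = FALSE,
                              policy = consensusPolicy()) {
  if (anyDuplicated(names(calls)))
    stop("duplicate tool slots: ",
         paste(unique(names(calls)[duplicated(names(calls))]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(names(calls), .TOOLS)
  if (length(bad))
    stop("unknown tool slot(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  full <- stats::setNames(rep("unavailable", length(.TOOLS)), .TOOLS)
  full[names(calls)] <- unname(calls)
  stopifnot(all(full %in% c("pathogenic", "benign", "unavailable")))
  if (identical(variant_class, "nonsense"))
    return(list(classification = "not_analyzed",
                n_tools_available = 0L, n_pathogenic_votes = 0L,
                flags = "stop_gain"))
  if (isTRUE(isoform_mismatch))
    return(list(classification = "unclassifiable",
                n_tools_available = sum(full != "unavailable"),
                n_pathogenic_votes = sum(full == "pathogenic"),
                flags = "residue_isoform_mismatch"))
  navail <- sum(full != "unavailable")
  votes <- sum(full == "pathogenic")
  flags <- character()
  if (votes >= policy$pathogenic_min) {
    cls <- "pathogenic"
  } else if (votes >= 1L) {
    cls <- "VUS"
  } else if (navail == length(.TOOLS) ||
             !policy$benign_requires_full_panel) {
    cls <- "benign"
  } else {
    cls <- "VUS"
    flags <- "incomplete_tool_panel"
  }
  list(classification = cls, n_tools_available = navail,
       n_pathogenic_votes = votes, flags = flags)
}

#' Consensus classification of a whole catalog
#'
#' @param catalog a [VariantCatalog-class].
#' @param predictions tool-call table from [predictVariants()]; computed
#'   from the catalog when not supplied.
#' @param policy a [consensusPolicy()].
#' @return data.frame, one row per variant: variant_id, gene,
#'   classification, n_tools_available, n_pathogenic_votes, flags
#'   (comma-joined).
#' @export
classifyCatalog <- function(catalog, predictions = NULL,
                            policy = consensusPolicy()) {
  stopifnot(is(catalog, "VariantCatalog"))
  if (is.null(predictions)) predictions <- predictVariants(catalog)
  vt <- variantTable(catalog)
  stopifnot(setequal(vt$variant_id, predictions$variant_id))
  predictions <- predictions[match(vt$variant_id, predictions$variant_id), ]
  res <- lapply(seq_len(nrow(vt)), function(i) {
    calls <- c(conservation = predictions$conservation[i],
               grantham = predictions$grantham[i],
               sift = predictions$sift[i],
               polyphen2 = predictions$polyphen2[i])
    consensusClassify(calls, variant_class = vt$variant_class[i],
                      isoform_mismatch = isTRUE(vt$isoform_mismatch[i]),
                      policy = policy)
  })
  data.frame(variant_id = vt$variant_id, gene = vt$gene,
             classification = vapply(res, `[[`, character(1),
                                     "classification"),
             n_tools_available = vapply(res, `[[`, integer(1),
                                        "n_tools_available"),
             n_pathogenic_votes = vapply(res, `[[`, integer(1),
                                         "n_pathogenic_votes"),
             flags = vapply(res, function(r)
               paste(r$flags, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Truncated integer percent
#'
#' The reporting convention everywhere in the package: 100 * count /
#' denominator truncated toward zero (exact integer arithmetic, no
#' floating-point rounding). This is the convention under which the
#' published class percentages are mutually consistent.
#'
#' @param count non-negative integer count(s).
#' @param denominator positive integer denominator.
#' @return integer percent(s); NA for a zero denominator.
#' @examples
#' truncatedPercent(10, 18)  # 55, not 56
#' @export
truncatedPercent <- function(count, denominator) {
  count <- as.integer(count)
  denominator <- as.integer(denominator)
  stopifnot(all(is.na(count) | count >= 0L))
  out <- (100L * count) %/% rep_len(denominator, length(count))
  out[rep_len(denominator, length(count)) <= 0L] <- NA_integer_
  out
}

#' Class counts and truncated percentages
#'
#' @param classifications data.frame from [classifyCatalog()] (or any
#'   data.frame with a `classification` column).
#' @param denominator `"analyzed"` (variants not `not_analyzed`; the
#'   default, matching the published percentages) or `"all"`.
#' @return data.frame with columns class, count, percent (percent NA for
#'   `not_analyzed` under the `"analyzed"` denominator).
#' @export
classificationFractions <- function(classifications,
                                    denominator = c("analyzed", "all")) {
  denominator <- match.arg(denominator)
  cls <- classifications$classification
  if (length(cls) == 0L) stop("no classifications supplied", call. = FALSE)
  stopifnot(all(cls %in% .CONSENSUS_LEVELS))
  counts <- table(factor(cls, levels = .CONSENSUS_LEVELS))
  denom <- if (denominator == "analyzed") sum(cls != "not_analyzed")
           else length(cls)
  out <- data.frame(class = names(counts),
                    count = as.integer(counts),
                    percent = truncatedPercent(as.integer(counts), denom),
                    stringsAsFactors = FALSE)
  if (denominator == "analyzed")
    out$percent[out$class == "not_analyzed"] <- NA_integer_
  out
}
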