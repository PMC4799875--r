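## Grantham physicochemical distance engine. The residue property table
## (side-chain composition c, polarity p, molecular volume v) and the
## constants (alpha, beta, gamma and the normalization rho that scales the
## mean inter-residue distance to 100) ship as checksummed package assets.

.GRANTHAM_MD5 <- c(
  grantham_properties.tsv = "012fcf9e6722ae80d6ac0c44484ae9cf",
  grantham_constants.tsv  = "f073edeec899e12c553ab7d15a853a7e")

.grantham_cache <- new.env(parent = emptyenv())

.grantham_asset <- function(file) {
  path <- system.file("extdata", file, package = "lvncTriage")
  if (!nzchar(path)) stop("missing package asset ", file, call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.GRANTHAM_MD5[file])))
    stop("checksum mismatch for ", file, ": asset corrupted", call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Amino-acid property table used by the Grantham distance
#'
#' Twenty rows (one per canonical residue) with side-chain composition `c`
#' (atomic weight ratio of non-carbon elements), polarity `p` and molecular
#' volume `v`. Loaded from a checksummed package asset and validated.
#'
#' @return data.frame with columns residue, c, p, v.
#' @export
granthamProperties <- function() {
  if (is.null(.grantham_cache$props)) {
    df <- .grantham_asset("grantham_properties.tsv")
    stopifnot(nrow(df) == 20L, setequal(df$residue, AA_ALPHABET),
              all(is.finite(df$c)), all(is.finite(df$p)),
              all(is.finite(df$v)),
              all(df$c >= 0), all(df$p >= 0), all(df$v >= 0))
    .grantham_cache$props <- df
  }
  .grantham_cache$props
}

#' Constants of the Grantham distance
#'
#' Weights `alpha` (composition), `beta` (polarity), `gamma` (volume) and
#' the scale `rho` chosen so that the mean of the 190 inter-residue
#' distances is 100.
#'
#' @return named list with elements alpha, beta, gamma, rho.
#' @export
granthamParameters <- function() {
  if (is.null(.grantham_cache$params)) {
    df <- .grantham_asset("grantham_constants.tsv")
    p <- as.list(stats::setNames(df$value, df$constant))
    stopifnot(setequal(names(p), c("alpha", "beta", "gamma", "rho")),
              all(unlist(p) > 0))
    .grantham_cache$params <- p
  }
  .grantham_cache$params
}

#' Grantham physicochemical distance between two residues
#'
#' D(a, b) = rho * sqrt(alpha (c_a - c_b)^2 + beta (p_a - p_b)^2 +
#' gamma (v_a - v_b)^2). Symmetric, non-negative, zero exactly on the
#' diagonal. Undefined for stop codons and unknown letters. Full precision
#' is returned; round to the nearest integer for matrix-style display and
#' calling.
#'
#' @param a,b one-letter residues (vectorized, recycled).
#' @param props property table, default [granthamProperties()].
#' @param params constants, default [granthamParameters()].
#' @return numeric vector of distances.
#' @examples
#' round(granthamDistance("L", "I"))  # 5
#' round(granthamDistance("R", "C"))  # 180
#' @export
granthamDistance <- function(a, b, props = granthamProperties(),
                             params = granthamParameters()) {
  bad <- setdiff(unique(c(a, b)), props$residue)
  if (length(bad))
    stop("Grantham distance undefined for residue(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  i <- match(a, props$residue)
  j <- match(b, props$residue)
  params$rho * sqrt(params$alpha * (props$c[i] - props$c[j])^2 +
                    params$beta  * (props$p[i] - props$p[j])^2 +
                    params$gamma * (props$v[i] - props$v[j])^2)
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @inheritParams granthamDistance
#' @param digits rounding for display; `NULL` keeps full precision.
#' @return symmetric 20 x 20 matrix with zero diagonal, residues as
#'   dimnames; the mean of the 190 unordered off-diagonal distances is 100
#'   within +-1 by the published normalization.
#' @export
buildGranthamMatrix <- function(props = granthamProperties(),
                                params = granthamParameters(),
                                digits = NULL) {
  if (!setequal(props$residue, AA_ALPHABET))
    stop("property table must cover all 20 residues", call. = FALSE)
  res <- props$residue
  grid <- expand.grid(a = res, b = res, stringsAsFactors = FALSE)
  m <- matrix(granthamDistance(grid$a, grid$b, props, params),
              nrow = length(res), dimnames = list(res, res))
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Binarize a Grantham score into a tool call
#'
#' Scores strictly above the cutoff are radical (pathogenic); at or below,
#' conservative (benign). The boundary score equal to the cutoff is benign:
#' a pathogenic call requires strict excess. NA scores (e.g. stop gains)
#' yield `"unavailable"`.
#'
#' @param score numeric Grantham score(s).
#' @param cutoff radical/conservative boundary, default 100.
#' @return character vector in {pathogenic, benign, unavailable}.
#' @examples
#' granthamCall(c(99, 100, 101))
#' @export
granthamCall <- function(score, cutoff = 100) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff))
  ifelse(is.na(score), "unavailable",
         ifelse(score > cutoff, "pathogenic", "benign"))
}
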