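## Small in-code fixtures shared across test files.

## Write a tiny catalog TSV and return its path.
tiny_catalog_tsv <- function(rows, dir = tempdir()) {
  header <- paste("gene", "hgvs_p", "cosegregation", "phenotypes",
                  "sift_label", "polyphen_label", "conserved",
                  "esp_positive", "exac_positive", sep = "\t")
  path <- tempfile("catalog", tmpdir = dir, fileext = ".tsv")
  writeLines(c(header, rows), path)
  path
}

tiny_catalog <- function() {
  readCatalog(tiny_catalog_tsv(c(
    "MYH7\tp.R243H\tyes\tLVNC\tdamaging\tprobably damaging\tyes\t\ttrue",
    "TAZ\tp.G195*\tno\tLVNC,Barth\t\t\t\tfalse\tfalse",
    "MYBPC3\tp.G5R\tnot_assessed\tLVNC\tdamaging\tbenign\tno\ttrue\ttrue",
    "LDB3\tp.D117N\t\tLVNC\ttolerated\tbenign\tno\ttrue\ttrue")))
}

## Population store over a handful of variants.
tiny_store <- function(cohort = "ESP", n = 6503L) {
  PopulationStore(cohort, data.frame(
    gene = c("MYBPC3", "MYBPC3", "LDB3"),
    hgvs_p = c("p.G5R", "p.G5R", "p.D117N"),
    subpop = c("AA", "EA", "all"),
    AC = c(1L, 2L, 4L),
    AN = c(4406L, 8600L, 13006L),
    carrier_count = c(1L, 2L, 4L)), n)
}

## One-family pedigree data.frame.
family_df <- function(genotypes, phenotypes, sexes = NULL,
                      family_id = "F1", variant_id = "MYH7:p.R243H") {
  n <- length(genotypes)
  data.frame(family_id = family_id, variant_id = variant_id,
             member_id = paste0("m", seq_len(n)),
             proband = c(TRUE, rep(FALSE, n - 1L)),
             sex = sexes %||% rep("unknown", n),
             genotype = genotypes, phenotype = phenotypes,
             relation = NA_character_, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent brute-force consensus oracle used by the exhaustive and
## acceptance tests: a from-scratch restatement of the voting rule.
oracle_consensus <- function(calls) {
  votes <- sum(calls == "pathogenic")
  avail <- sum(calls != "unavailable")
  if (votes >= 3) "pathogenic"
  else if (votes >= 1) "VUS"
  else if (avail == 4) "benign"
  else "VUS"
}

## Independent Grantham oracle: own copy of the property values and a
## direct transcription of the distance formula.
oracle_grantham <- local({
  tab <- data.frame(
    res = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
            "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170))
  function(a, b) {
    i <- match(a, tab$res); j <- match(b, tab$res)
    50.723 * sqrt(1.833 * (tab$c[i] - tab$c[j])^2 +
                  0.1018 * (tab$p[i] - tab$p[j])^2 +
                  0.000399 * (tab$v[i] - tab$v[j])^2)
  }
})
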