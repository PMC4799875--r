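## Seed-deterministic generators for every input the pipeline consumes:
## binomially sampled population cohorts, alignment columns, pedigrees, and
## a study fixture reproducing the curated catalog's marginal structure.
## Named real variants from the source literature are placed with their
## stated attributes; all remaining rows are synthetic placeholders and are
## flagged as such (`synthetic` column, `synthetic` citation).

#' Cohort specification for the population simulator
#'
#' @param cohort_id cohort label.
#' @param subpops data.frame with columns `name` and `n` (individuals).
#' @param male_fraction fraction of males, used for X-linked variants
#'   (hemizygous males contribute one allele each).
#' @param seed RNG seed; fixed seed means fully reproducible output.
#' @return named list specification.
#' @export
cohortSpec <- function(cohort_id, subpops, male_fraction = 0.5,
                       seed = 1L) {
  stopifnot(is.data.frame(subpops), all(c("name", "n") %in% names(subpops)),
            all(subpops$n > 0), male_fraction >= 0, male_fraction <= 1)
  list(cohort_id = cohort_id, subpops = subpops,
       male_fraction = male_fraction, seed = as.integer(seed))
}

#' ESP-like cohort: 6503 exomes (2203 African American + 4300 European
#' American)
#' @param seed RNG seed.
#' @return a [cohortSpec()].
#' @export
espCohortSpec <- function(seed = 1L) {
  cohortSpec("ESP", data.frame(name = c("AA", "EA"), n = c(2203L, 4300L)),
             seed = seed)
}

#' ExAC-like cohort: 60,706 unrelated exomes
#' @param seed RNG seed.
#' @return a [cohortSpec()].
#' @export
exacCohortSpec <- function(seed = 1L) {
  cohortSpec("ExAC", data.frame(name = "all", n = 60706L), seed = seed)
}

#' Simulate a population allele-count store
#'
#' Per variant and subpopulation, individual genotypes are drawn binomially
#' at the variant's true allele frequency (two draws per autosomal
#' individual; one for hemizygous males at X-linked variants). AC, AN and
#' carrier counts are recorded exactly consistent with the drawn genotypes,
#' so every store invariant holds by construction.
#'
#' @param spec a [cohortSpec()].
#' @param variants data.frame with columns gene, hgvs_p, true_af in
#'   `[0, 0.5]`, and optional logical x_linked.
#' @return a [PopulationStore-class].
#' @export
simulateCohort <- function(spec, variants) {
  stopifnot(all(c("gene", "hgvs_p", "true_af") %in% names(variants)),
            all(variants$true_af >= 0), all(variants$true_af <= 0.5))
  if (!"x_linked" %in% names(variants)) variants$x_linked <- FALSE
  rows <- with_seed(spec$seed, {
    out <- list()
    for (s in seq_len(nrow(spec$subpops))) {
      n <- spec$subpops$n[s]
      nm <- as.integer(round(spec$male_fraction * n))
      nf <- n - nm
      for (v in seq_len(nrow(variants))) {
        f <- variants$true_af[v]
        if (variants$x_linked[v]) {
          gm <- stats::rbinom(nm, 1L, f)
          gf <- stats::rbinom(nf, 2L, f)
          g <- c(gm, gf)
          an <- nm + 2L * nf
        } else {
          g <- stats::rbinom(n, 2L, f)
          an <- 2L * n
        }
        out[[length(out) + 1L]] <- data.frame(
          gene = variants$gene[v], hgvs_p = variants$hgvs_p[v],
          subpop = spec$subpops$name[s],
          AC = sum(g), AN = an, carrier_count = sum(g > 0L),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  PopulationStore(spec$cohort_id, rows, sum(spec$subpops$n))
}

#' Simulate one alignment column
#'
#' The reference residue is fixed; each of the `n_species - 1` other
#' species is substituted independently with probability
#' `substitution_prob`, uniformly among the 19 alternative residues. The
#' probability that the column comes out conserved is therefore
#' `(1 - substitution_prob)^(n_species - 1)`.
#'
#' @param n_species total species count including the reference (>= 2).
#' @param substitution_prob per-species substitution probability.
#' @param seed RNG seed.
#' @param reference reference residue, default "K".
#' @return an [alignmentColumn()].
#' @export
simulateAlignmentColumn <- function(n_species, substitution_prob,
                                    seed = 1L, reference = "K") {
  stopifnot(n_species >= 2L, substitution_prob >= 0, substitution_prob <= 1)
  with_seed(seed, {
    k <- n_species - 1L
    res <- rep(reference, k)
    sub <- stats::runif(k) < substitution_prob
    if (any(sub))
      res[sub] <- sample(setdiff(AA_ALPHABET, reference), sum(sub),
                         replace = TRUE)
    alignmentColumn(reference,
                    stats::setNames(res, paste0("species", seq_len(k))))
  })
}

#' Simulate a nuclear pedigree for one variant
#'
#' Parents plus proband plus siblings. The variant is transmitted from one
#' carrier parent (the mother for X-linked genes, so generated pedigrees
#' always satisfy the X-linked consistency check); each sibling inherits
#' with probability 1/2. The proband is an ascertained affected carrier;
#' every other carrier is affected with probability `penetrance`,
#' non-carriers with probability `phenocopy_rate` (default 0: no
#' phenocopies).
#'
#' @param variant list with elements gene, phenotype (a single affected
#'   label, e.g. "LVNC") and optional x_linked (logical).
#' @param n_members total members including both parents (>= 3).
#' @param penetrance probability a non-proband carrier is affected.
#' @param phenocopy_rate probability a non-carrier is affected.
#' @param family_id family label.
#' @param seed RNG seed.
#' @return data.frame in the pedigree dialect (one row per member, with
#'   father_id/mother_id links).
#' @export
simulatePedigree <- function(variant, n_members = 6L, penetrance = 1,
                             phenocopy_rate = 0, family_id = "FAM1",
                             seed = 1L) {
  stopifnot(n_members >= 3L, penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1)
  xl <- isTRUE(variant$x_linked)
  phen <- variant$phenotype
  stopifnot(phen %in% .PHENOTYPE_LEVELS)
  with_seed(seed, {
    n_kids <- n_members - 2L
    kid_sex <- sample(c("male", "female"), n_kids, replace = TRUE)
    ## transmitting parent: mother when X-linked, else random
    trans_mother <- if (xl) TRUE else stats::runif(1) < 0.5
    kid_carrier <- c(TRUE, stats::runif(n_kids - 1L) < 0.5)  # proband first
    kid_aff <- ifelse(kid_carrier,
                      stats::runif(n_kids) < penetrance,
                      stats::runif(n_kids) < phenocopy_rate)
    kid_aff[1] <- TRUE  # ascertainment
    ids <- c("father", "mother", paste0("child", seq_len(n_kids)))
    data.frame(
      family_id = family_id,
      variant_id = paste0(toupper(variant$gene), ":",
                          variant$hgvs %||% "p.?"),
      member_id = ids,
      proband = c(FALSE, FALSE, TRUE, rep(FALSE, n_kids - 1L)),
      sex = c("male", "female", kid_sex),
      genotype = c(ifelse(!trans_mother, "carrier", "non_carrier"),
                   ifelse(trans_mother, "carrier", "non_carrier"),
                   ifelse(kid_carrier, "carrier", "non_carrier")),
      phenotype = c(if (!trans_mother && stats::runif(1) < penetrance)
                      phen else "unaffected",
                    if (trans_mother && stats::runif(1) < penetrance)
                      phen else "unaffected",
                    ifelse(kid_aff, phen, "unaffected")),
      relation = c("father", "mother", "proband",
                   rep("sibling", n_kids - 1L)),
      father_id = c(NA, NA, rep("father", n_kids)),
      mother_id = c(NA, NA, rep("mother", n_kids)),
      stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Study fixture: catalog + stores + pedigrees matching the marginal targets.

#' Marginal targets for the study fixture
#'
#' The defaults encode the curated study's printed marginal structure:
#' 60 variants in 12 genes (24 in MYH7, 7 in MYBPC3; DTNA, MYH7B and CASQ2
#' carry one each), 4 stop gains, 9 ESP-positive / 18 ExAC-positive with 8
#' overlapping (ESP-positive never in MYH7; ExAC-positive in every gene
#' except TPM1), consensus classes 29 pathogenic / 23 VUS / 3 benign /
#' 1 unclassifiable among the 56 analyzed, stratified pathogenic counts 4
#' of 9 (ESP), 10 of 18 (ExAC) and 17 of 24 (MYH7, none benign), and 42
#' familial records of which 30 co-segregate. The 12th gene (ACTC1) and
#' the fourth stop gain are synthetic: the source names only 11 genes and
#' 3 stop gains.
#'
#' @param seed RNG seed driving synthetic residue placement, store counts
#'   and pedigree layout.
#' @return named list of marginal targets.
#' @export
fixtureSpec <- function(seed = 20150717L) {
  list(
    seed = as.integer(seed),
    n_variants = 60L, n_genes = 12L,
    per_gene = c(MYH7 = 24L, MYBPC3 = 7L, ACTC1 = 6L, TNNT2 = 5L,
                 TAZ = 4L, LDB3 = 3L, MIB1 = 3L, PRDM16 = 3L,
                 TPM1 = 2L, CASQ2 = 1L, DTNA = 1L, MYH7B = 1L),
    n_nonsense = 4L,
    n_esp_positive = 9L, n_exac_positive = 18L, n_overlap = 8L,
    class_counts = c(pathogenic = 29L, VUS = 23L, benign = 3L,
                     unclassifiable = 1L),
    esp_pathogenic = 4L, exac_pathogenic = 10L, myh7_pathogenic = 17L,
    esp_excluded_genes = "MYH7", exac_excluded_genes = "TPM1",
    n_familial = 42L, n_cosegregating = 30L,
    x_linked_genes = "TAZ")
}

## Validate mutual consistency of a fixture spec; error lists every
## violated constraint.
checkFixtureSpec <- function(spec) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(sum(spec$per_gene) == spec$n_variants,
      "per-gene counts do not sum to n_variants")
  chk(length(spec$per_gene) == spec$n_genes,
      "per_gene length differs from n_genes")
  chk(spec$n_overlap <= min(spec$n_esp_positive, spec$n_exac_positive),
      "overlap exceeds min(ESP-positive, ExAC-positive)")
  chk(spec$n_esp_positive <= spec$n_variants &&
        spec$n_exac_positive <= spec$n_variants,
      "presence counts exceed n_variants")
  chk(sum(spec$class_counts) + spec$n_nonsense == spec$n_variants,
      "class counts + stop gains do not sum to n_variants")
  chk(spec$n_cosegregating <= spec$n_familial,
      "co-segregating count exceeds familial count")
  chk(spec$esp_pathogenic <= min(spec$n_esp_positive,
                                 spec$class_counts["pathogenic"]),
      "ESP-positive pathogenic count infeasible")
  chk(spec$exac_pathogenic <= min(spec$n_exac_positive,
                                  spec$class_counts["pathogenic"]),
      "ExAC-positive pathogenic count infeasible")
  chk(spec$myh7_pathogenic <= min(spec$per_gene["MYH7"],
                                  spec$class_counts["pathogenic"]),
      "MYH7 pathogenic count infeasible")
  chk(all(c(spec$per_gene, spec$n_nonsense, spec$class_counts,
            spec$n_familial, spec$n_cosegregating) >= 0L),
      "negative marginal target")
  if (length(v))
    stop("inconsistent fixture spec:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  invisible(spec)
}

## Named variants from the source literature with their stated attributes.
## target: P pathogenic, V VUS, B benign, U unclassifiable, S stop gain.
## cis: records sharing a cis group id become one compound-allele record.
.named_skeleton <- function() {
  r <- function(gene, hgvs, esp = FALSE, exac = FALSE, target,
                familial = FALSE, coseg = "not_assessed",
                inh = "unknown", phen = "LVNC", cis = NA_character_,
                cite = "literature")
    data.frame(gene = gene, hgvs = hgvs, esp = esp, exac = exac,
               target = target, familial = familial, coseg = coseg,
               inheritance = inh, phenotypes = phen, cis = cis,
               citation = cite, synthetic = FALSE,
               stringsAsFactors = FALSE)
  rbind(
    r("MYH7", "p.R243H", exac = TRUE, target = "P", familial = TRUE,
      coseg = "yes", inh = "autosomal_dominant"),
    r("MYH7", "p.R1359C", exac = TRUE, target = "P", inh = "sporadic"),
    r("MYH7", "p.Y283D", target = "P", familial = TRUE, coseg = "yes",
      inh = "autosomal_dominant", phen = "LVNC,CHD"),
    r("MYH7", "p.M531R", target = "P", inh = "sporadic"),
    r("MYH7", "p.R281T", target = "P", familial = TRUE, coseg = "yes",
      inh = "autosomal_dominant"),
    r("MYH7", "p.D545N", target = "P", familial = TRUE, coseg = "yes",
      inh = "autosomal_dominant", cis = "MYH7_cis"),
    r("MYH7", "p.D955N", target = "P", familial = TRUE, coseg = "yes",
      inh = "autosomal_dominant", cis = "MYH7_cis"),
    r("MYBPC3", "p.G5R", esp = TRUE, exac = TRUE, target = "V"),
    r("MYBPC3", "p.G490R", esp = TRUE, exac = TRUE, target = "P",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant"),
    r("MYBPC3", "p.R502W", esp = TRUE, exac = TRUE, target = "P",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant",
      phen = "LVNC,HCM"),
    r("MYBPC3", "p.G148R", exac = TRUE, target = "P"),
    r("MYBPC3", "p.R820W", exac = TRUE, target = "P", familial = TRUE,
      coseg = "yes", inh = "autosomal_recessive"),
    r("MYBPC3", "p.P873L", exac = TRUE, target = "P"),
    r("TAZ", "p.G197R", esp = TRUE, exac = TRUE, target = "V",
      familial = TRUE, coseg = "no", inh = "X_linked,sporadic"),
    r("TAZ", "p.G195*", target = "S", familial = TRUE, coseg = "no",
      inh = "X_linked", phen = "LVNC,Barth,DCM,CHD"),
    r("DTNA", "p.P121L", exac = TRUE, target = "B", familial = TRUE,
      coseg = "yes", inh = "autosomal_dominant"),
    r("MYH7B", "p.R890C", esp = TRUE, exac = TRUE, target = "V",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant"),
    r("CASQ2", "p.H244R", esp = TRUE, exac = TRUE, target = "P",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant"),
    r("LDB3", "p.D626N", target = "U"),
    r("LDB3", "p.D117N", esp = TRUE, exac = TRUE, target = "B",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant"),
    r("MIB1", "p.R530*", target = "S", familial = TRUE, coseg = "no",
      inh = "autosomal_dominant"),
    r("MIB1", "p.V943F", esp = TRUE, exac = TRUE, target = "P",
      familial = TRUE, coseg = "yes", inh = "autosomal_dominant"),
    r("PRDM16", "p.K702*", target = "S"),
    r("TNNT2", "p.E96K", esp = TRUE, target = "B", phen = "LVNC,DCM"),
    r("TNNT2", "p.R131W", exac = TRUE, target = "P"),
    r("TPM1", "p.D84N", target = "P", familial = TRUE, coseg = "no",
      inh = "autosomal_dominant", phen = "LVNC,DCM"))
}

## Assign tool labels that drive the consensus rule to the target class.
## Pathogenic targets get three non-Grantham pathogenic labels (>= 3 votes
## whatever the Grantham score); VUS targets get a single damaging SIFT
## label (1-2 votes depending on the Grantham score); benign targets get a
## clean panel and require a conservative Grantham score.
.labels_for_target <- function(df) {
  df$sift_label <- NA_character_
  df$polyphen_label <- NA_character_
  df$conserved <- NA_character_
  df$isoform_mismatch <- FALSE
  alt_pp <- c("probably damaging", "possibly damaging")
  for (i in seq_len(nrow(df))) {
    t <- df$target[i]
    if (t == "S") next
    if (t == "P") {
      df$conserved[i] <- "yes"
      df$sift_label[i] <- "damaging"
      df$polyphen_label[i] <- alt_pp[1L + (i %% 2L)]
    } else if (t == "V") {
      df$conserved[i] <- "no"
      df$sift_label[i] <- "damaging"
      df$polyphen_label[i] <- "benign"
    } else if (t == "B") {
      df$conserved[i] <- "no"
      df$sift_label[i] <- "tolerated"
      df$polyphen_label[i] <- "benign"
    } else if (t == "U") {
      df$isoform_mismatch[i] <- TRUE
      df$conserved[i] <- "no"
      df$sift_label[i] <- "damaging"
      df$polyphen_label[i] <- "possibly damaging"
    }
  }
  df
}

#' Generate the study fixture
#'
#' Builds a complete, mutually consistent set of pipeline inputs — variant
#' catalog (with tool labels), ESP-like and ExAC-like allele-count stores,
#' and one pedigree per familial record — whose independent re-derivation
#' through the full pipeline (parsing, lookup, prediction, consensus,
#' segregation, report) reproduces every marginal in the spec. Named
#' literature variants are placed with their stated attributes; filler rows
#' are synthetic placeholders flagged in the `synthetic` catalog column.
#' Generation is a pure function of the spec (including its seed).
#'
#' @param spec a [fixtureSpec()]; checked for mutual consistency first
#'   (an inconsistent spec is an error listing the violated constraints).
#' @return list with elements catalog ([VariantCatalog-class]), esp and
#'   exac ([PopulationStore-class]), pedigrees (data.frame), spec.
#' @export
makeStudyFixture <- function(spec = fixtureSpec()) {
  checkFixtureSpec(spec)
  named <- .named_skeleton()
  named <- named[named$gene %in% names(spec$per_gene), , drop = FALSE]

  with_seed(spec$seed, {
    ## --- synthetic filler rows per gene -------------------------------------
    filler <- list()
    for (g in names(spec$per_gene)) {
      n_syn <- spec$per_gene[[g]] - sum(named$gene == g)
      if (n_syn < 0L)
        stop("per-gene target for ", g,
             " below the named-variant minimum", call. = FALSE)
      if (n_syn == 0L) next
      used <- as.integer(sub("^p\\.[A-Z]([0-9]+).*$", "\\1",
                             named$hgvs[named$gene == g]))
      pos <- sample(setdiff(100:999, used), n_syn)
      filler[[g]] <- data.frame(
        gene = g, pos = pos, target = "V", esp = FALSE, exac = FALSE,
        stringsAsFactors = FALSE)
    }
    syn <- do.call(rbind, filler)
    rownames(syn) <- NULL

    ## extra stop gains (beyond the named ones), preferring TNNT2
    n_stop_extra <- spec$n_nonsense - sum(named$target == "S")
    if (n_stop_extra < 0L) stop("n_nonsense below named minimum")
    if (n_stop_extra > 0L) {
      cand <- order(syn$gene != "TNNT2", syn$gene, syn$pos)
      syn$target[cand[seq_len(n_stop_extra)]] <- "S"
    }

    ## extra ExAC-positive rows: first cover genes without any, never the
    ## excluded gene(s)
    n_exac_extra <- spec$n_exac_positive - sum(named$exac)
    if (n_exac_extra < 0L) stop("n_exac_positive below named minimum")
    if (n_exac_extra > 0L) {
      has_exac <- unique(named$gene[named$exac])
      ok <- which(syn$target %in% c("V", "P") &
                    !(syn$gene %in% spec$exac_excluded_genes))
      ok <- ok[order(syn$gene[ok], syn$pos[ok])]
      ## one row per still-uncovered gene first, then the rest
      uncovered <- !(syn$gene[ok] %in% has_exac)
      first_of_gene <- !duplicated(syn$gene[ok]) & uncovered
      cand <- c(ok[first_of_gene], ok[!first_of_gene])
      syn$exac[cand[seq_len(n_exac_extra)]] <- TRUE
    }
    n_esp_extra <- spec$n_esp_positive - sum(named$esp)
    if (n_esp_extra < 0L) stop("n_esp_positive below named minimum")
    if (n_esp_extra > 0L) {
      ok <- syn$target %in% c("V", "P") &
        !(syn$gene %in% spec$esp_excluded_genes)
      cand <- which(ok)[order(syn$gene[ok], syn$pos[ok])]
      syn$esp[cand[seq_len(n_esp_extra)]] <- TRUE
    }

    ## pathogenic targets: fill the MYH7 quota, then the remainder in
    ## population-absent rows so the stratified counts stay at spec
    myh7_extra_p <- spec$myh7_pathogenic -
      sum(named$gene == "MYH7" & named$target == "P")
    if (myh7_extra_p < 0L) stop("myh7_pathogenic below named minimum")
    cand <- which(syn$gene == "MYH7" & syn$target == "V")
    if (length(cand) < myh7_extra_p)
      stop("not enough MYH7 filler rows for the pathogenic quota")
    syn$target[cand[seq_len(myh7_extra_p)]] <- "P"

    p_total_extra <- spec$class_counts[["pathogenic"]] -
      sum(named$target == "P") - myh7_extra_p
    if (p_total_extra < 0L) stop("pathogenic count below named minimum")
    if (p_total_extra > 0L) {
      cand <- which(syn$target == "V" & !syn$esp & !syn$exac &
                      syn$gene != "MYH7")
      cand <- cand[order(syn$gene[cand], syn$pos[cand])]
      if (length(cand) < p_total_extra)
        stop("not enough filler rows for the pathogenic quota")
      syn$target[cand[seq_len(p_total_extra)]] <- "P"
    }

    ## residues by target class: radical pair for pathogenic (irrelevant to
    ## the call, which three other tools already carry), conservative pair
    ## for VUS (keeps the vote count at 1)
    syn$hgvs <- ifelse(syn$target == "S", paste0("p.Q", syn$pos, "*"),
                ifelse(syn$target == "P", paste0("p.R", syn$pos, "W"),
                       paste0("p.A", syn$pos, "V")))

    ## familial / co-segregation assignment for filler records; named
    ## counts are per record, so a cis compound allele counts once
    named_first <- !duplicated(ifelse(is.na(named$cis),
                                      paste0("r", seq_len(nrow(named))),
                                      named$cis))
    n_fam_extra <- spec$n_familial - sum(named$familial[named_first])
    n_yes_extra <- spec$n_cosegregating -
      sum(named$coseg[named_first] == "yes")
    if (n_fam_extra < 0L || n_yes_extra < 0L || n_yes_extra > n_fam_extra)
      stop("familial/co-segregation targets below named minimums")
    syn$familial <- FALSE
    syn$coseg <- "not_assessed"
    ord <- order(syn$gene, syn$pos)
    if (n_fam_extra > length(ord))
      stop("not enough filler rows for the familial quota")
    fam_rows <- ord[seq_len(n_fam_extra)]
    syn$familial[fam_rows] <- TRUE
    syn$coseg[fam_rows] <- "no"
    syn$coseg[fam_rows[seq_len(n_yes_extra)]] <- "yes"

    syn_full <- data.frame(
      gene = syn$gene, hgvs = syn$hgvs, esp = syn$esp, exac = syn$exac,
      target = syn$target, familial = syn$familial, coseg = syn$coseg,
      inheritance = ifelse(syn$familial, "autosomal_dominant", "unknown"),
      phenotypes = "LVNC", cis = NA_character_, citation = "synthetic",
      synthetic = TRUE, stringsAsFactors = FALSE)
    all_rows <- rbind(named, syn_full)

    ## benign targets must carry a conservative Grantham score
    ben <- all_rows$target == "B"
    if (any(ben)) {
      ref <- sub("^p\\.([A-Z]).*", "\\1", all_rows$hgvs[ben])
      alt <- sub(".*([A-Z*])$", "\\1", all_rows$hgvs[ben])
      if (any(granthamDistance(ref, alt) > 100))
        stop("benign target with a radical Grantham pair", call. = FALSE)
    }

    ## --- catalog ------------------------------------------------------------
    all_rows <- .labels_for_target(all_rows)
    grp <- ifelse(is.na(all_rows$cis),
                  paste0("row", seq_len(nrow(all_rows))), all_rows$cis)
    grp <- factor(grp, levels = unique(grp))
    rec <- do.call(rbind, lapply(split(all_rows, grp), function(d) {
      data.frame(
        gene = d$gene[1],
        hgvs_p = paste(d$hgvs, collapse = ";"),
        inheritance = d$inheritance[1],
        cosegregation = if (d$familial[1]) d$coseg[1] else "not_assessed",
        phenotypes = d$phenotypes[1],
        sift_label = d$sift_label[1],
        polyphen_label = d$polyphen_label[1],
        conserved = d$conserved[1],
        esp_positive = any(d$esp),
        exac_positive = any(d$exac),
        isoform_mismatch = any(d$isoform_mismatch),
        synthetic = any(d$synthetic),
        citations = d$citation[1],
        stringsAsFactors = FALSE)
    }))
    rownames(rec) <- NULL
    catalog <- makeCatalog(rec,
                           provenance = sprintf(
                             "synthetic study fixture (seed %d)", spec$seed))

    ## --- population stores --------------------------------------------------
    xg <- spec$x_linked_genes
    esp_rows <- all_rows[all_rows$esp, , drop = FALSE]
    esp_counts <- do.call(rbind, lapply(seq_len(nrow(esp_rows)), function(i) {
      xl <- esp_rows$gene[i] %in% xg
      an <- if (xl) c(3304L, 6450L) else c(4406L, 8600L)
      ac <- c(sample(0:2, 1L), sample(1:3, 1L))
      data.frame(gene = esp_rows$gene[i], hgvs_p = esp_rows$hgvs[i],
                 subpop = c("AA", "EA"), AC = ac, AN = an,
                 carrier_count = ac, stringsAsFactors = FALSE)
    }))
    esp <- PopulationStore("ESP", esp_counts, 6503L)

    exac_rows <- all_rows[all_rows$exac, , drop = FALSE]
    exac_counts <- do.call(rbind, lapply(seq_len(nrow(exac_rows)),
                                         function(i) {
      xl <- exac_rows$gene[i] %in% xg
      ac <- if (exac_rows$hgvs[i] == "p.R243H") 1L
            else sample(1:30, 1L)
      data.frame(gene = exac_rows$gene[i], hgvs_p = exac_rows$hgvs[i],
                 subpop = "all", AC = ac,
                 AN = if (xl) 91059L else 121412L,
                 carrier_count = NA_integer_, stringsAsFactors = FALSE)
    }))
    exac <- PopulationStore("ExAC", exac_counts, 60706L)

    ## --- pedigrees: one family per familial record --------------------------
    fam_rec <- catalogRecords(catalog)
    fam_rec <- fam_rec[fam_rec$cosegregation != "not_assessed", ,
                       drop = FALSE]
    peds <- do.call(rbind, lapply(seq_len(nrow(fam_rec)), function(i) {
      rid <- fam_rec$record_id[i]
      first_change <- proteinChanges(catalog)
      vid <- first_change$variant_id[first_change$record_id == rid][1]
      phen <- strsplit(fam_rec$phenotypes[i], ",")[[1]][1]
      if (is.na(phen)) phen <- "LVNC"
      xl <- fam_rec$gene[i] %in% xg
      yes <- fam_rec$cosegregation[i] == "yes"
      kid2_geno <- if (yes) "carrier" else "non_carrier"
      kid2_phen <- phen
      data.frame(
        family_id = sprintf("FAM%03d", i),
        variant_id = vid,
        member_id = c("father", "mother", "proband", "sib"),
        proband = c(FALSE, FALSE, TRUE, FALSE),
        sex = c("male", "female", if (xl) "male" else "female", "female"),
        genotype = c("non_carrier", "carrier", "carrier", kid2_geno),
        phenotype = c("unaffected", "unaffected", phen, kid2_phen),
        relation = c("father", "mother", "proband", "sibling"),
        father_id = c(NA, NA, "father", "father"),
        mother_id = c(NA, NA, "mother", "mother"),
        stringsAsFactors = FALSE)
    }))
    rownames(peds) <- NULL

    ## --- verify the marginals end to end ------------------------------------
    .verify_fixture(spec, catalog, esp, exac, peds)

    list(catalog = catalog, esp = esp, exac = exac, pedigrees = peds,
         spec = spec)
  })
}

## Recompute every marginal through the real pipeline; error on mismatch.
.verify_fixture <- function(spec, catalog, esp, exac, peds) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(nVariants(catalog) == spec$n_variants, "n_variants")
  tally <- tallyByGene(catalog)
  chk(length(tally) == spec$n_genes, "n_genes")
  chk(all(tally[names(spec$per_gene)] == spec$per_gene), "per-gene counts")
  cls <- classifyCatalog(catalog)
  frac <- table(cls$classification)
  chk(identical(unname(frac["not_analyzed"]), spec$n_nonsense),
      "stop-gain count")
  for (k in names(spec$class_counts))
    chk(identical(unname(frac[k]), spec$class_counts[[k]]),
        paste("class count", k))
  pe <- lookupPresence(catalog, esp)
  px <- lookupPresence(catalog, exac)
  ov <- presenceOverlap(pe, px)
  chk(ov[["n_a"]] == spec$n_esp_positive, "ESP-positive count")
  chk(ov[["n_b"]] == spec$n_exac_positive, "ExAC-positive count")
  chk(ov[["n_both"]] == spec$n_overlap, "overlap count")
  chk(stratifiedPathogenicity(cls, pe$variant_id[pe$present])$n_pathogenic ==
        spec$esp_pathogenic, "ESP stratum")
  chk(stratifiedPathogenicity(cls, px$variant_id[px$present])$n_pathogenic ==
        spec$exac_pathogenic, "ExAC stratum")
  vt <- variantTable(catalog)
  chk(stratifiedPathogenicity(cls,
        vt$variant_id[vt$gene == "MYH7"])$n_pathogenic ==
        spec$myh7_pathogenic, "MYH7 stratum")
  ps <- summarizePedigrees(peds)
  chk(sum(ps$label == "familial") == spec$n_familial, "familial count")
  chk(sum(ps$label == "familial" & ps$cosegregation == "yes") ==
        spec$n_cosegregating, "co-segregation count")
  if (length(bad))
    stop("fixture generation failed to satisfy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
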