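test_that("co-segregation needs two carriers sharing a phenotype", {
  two <- family_df(c("carrier", "carrier"), c("LVNC", "LVNC"))
  expect_identical(assessCosegregation(two), "yes")

  differ <- family_df(c("carrier", "carrier"), c("LVNC", "unaffected"))
  expect_identical(assessCosegregation(differ), "no")

  unknown <- family_df(c("unknown", "unknown"), c("LVNC", "LVNC"))
  expect_identical(assessCosegregation(unknown), "not_assessed")

  one_known <- family_df(c("carrier", "unknown"), c("LVNC", "LVNC"))
  expect_identical(assessCosegregation(one_known), "not_assessed")

  expect_error(assessCosegregation(two, phenotype_set = character()),
               "non-empty")
})

test_that("strict label equality vs phenotype-spectrum equivalence", {
  mixed <- family_df(c("carrier", "carrier"), c("LVNC", "DCM"))
  expect_identical(assessCosegregation(mixed), "no")
  expect_identical(assessCosegregation(mixed,
                                       phenotype_set = c("LVNC", "DCM"),
                                       equivalence = TRUE), "yes")
})

test_that("the proband counts toward the two carriers, configurably", {
  fam <- family_df(c("carrier", "carrier", "non_carrier"),
                   c("LVNC", "LVNC", "unaffected"))
  expect_identical(assessCosegregation(fam), "yes")
  expect_identical(assessCosegregation(fam, count_proband = FALSE), "no")
})

test_that("familial label needs two affected members of any genotype", {
  fam <- family_df(c("carrier", "unknown"), c("LVNC", "DCM"))
  expect_identical(familialLabel(fam), "familial")
  spor <- family_df(c("carrier", "non_carrier", "non_carrier"),
                    c("LVNC", "unaffected", "unaffected"))
  expect_identical(familialLabel(spor), "sporadic")
})

test_that("X-linked check flags male-to-male transmission only", {
  ped <- family_df(c("carrier", "carrier"), c("LVNC", "LVNC"),
                   sexes = c("male", "male"))
  ped$father_id <- c(NA, "m1")
  expect_false(xlinkedConsistency(ped, "TAZ"))
  expect_true(xlinkedConsistency(ped, "MYH7"))  # autosomal: vacuous

  ped2 <- family_df(c("carrier", "carrier"), c("LVNC", "LVNC"),
                    sexes = c("female", "male"))
  ped2$father_id <- c(NA, "other")
  ped2$mother_id <- c(NA, "m1")
  expect_true(xlinkedConsistency(ped2, "TAZ"))
})

test_that("adding a matching carrier never flips yes to no", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    fam <- family_df(sample(c("carrier", "non_carrier"), n, replace = TRUE),
                     sample(c("LVNC", "DCM", "unaffected"), n,
                            replace = TRUE))
    before <- assessCosegregation(fam)
    extra <- fam[1, ]
    extra$member_id <- "extra"
    extra$proband <- FALSE
    extra$genotype <- "carrier"
    extra$phenotype <- "LVNC"
    after <- assessCosegregation(rbind(fam, extra))
    if (before == "yes") expect_identical(after, "yes")
  }
})

test_that("pedigree TSV round-trips through validation", {
  fam <- family_df(c("carrier", "carrier", "non_carrier"),
                   c("LVNC", "LVNC", "unaffected"))
  path <- tempfile(fileext = ".tsv")
  write.table(fam, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readPedigrees(path)
  expect_identical(assessCosegregation(back), "yes")

  two_probands <- fam
  two_probands$proband <- TRUE
  write.table(two_probands, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readPedigrees(path), "exactly one proband")

  bad_geno <- fam
  bad_geno$genotype[2] <- "het"
  write.table(bad_geno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPedigrees(path), "unknown genotype")
})

test_that("full penetrance pedigrees with 2+ carriers always co-segregate", {
  hits <- 0L
  for (s in 1:40) {
    ped <- simulatePedigree(list(gene = "MYH7", hgvs = "p.R243H",
                                 phenotype = "LVNC"),
                            n_members = 6, penetrance = 1, seed = s)
    carriers <- sum(ped$genotype == "carrier")
    if (carriers >= 2) {
      hits <- hits + 1L
      expect_identical(assessCosegregation(ped), "yes")
    }
    expect_true(xlinkedConsistency(ped, "MYH7"))
  }
  expect_gte(hits, 10L)  # the condition actually occurred
})

test_that("zero penetrance without phenocopies never co-segregates", {
  for (s in 1:25) {
    ped <- simulatePedigree(list(gene = "MYH7", hgvs = "p.R243H",
                                 phenotype = "LVNC"),
                            n_members = 6, penetrance = 0, seed = s)
    expect_true(assessCosegregation(ped) %in% c("no", "not_assessed"))
  }
})

test_that("generated X-linked pedigrees satisfy the transmission check", {
  for (s in 1:20) {
    ped <- simulatePedigree(list(gene = "TAZ", hgvs = "p.G197R",
                                 phenotype = "LVNC", x_linked = TRUE),
                            n_members = 5, penetrance = 1, seed = s)
    expect_true(xlinkedConsistency(ped, "TAZ"))
    ## transmitting parent is the mother
    expect_identical(ped$genotype[ped$member_id == "father"], "non_carrier")
  }
})
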