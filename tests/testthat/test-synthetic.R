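test_that("simulated cohorts satisfy every store invariant by construction", {
  vars <- data.frame(gene = c("MYH7", "TAZ"),
                     hgvs_p = c("p.R243H", "p.G197R"),
                     true_af = c(0.01, 0.005),
                     x_linked = c(FALSE, TRUE))
  st <- simulateCohort(espCohortSpec(seed = 9L), vars)
  ct <- storeCounts(st)
  expect_true(all(ct$AC <= ct$AN))
  expect_true(all(ct$carrier_count <= ct$AC))
  expect_true(all(ct$AN <= 2L * nIndividuals(st)))
  ## autosomal AN at full call rate: 2 x 6503
  auto <- ct[ct$gene == "MYH7", ]
  expect_equal(sum(auto$AN), 13006L)
  ## X-linked: hemizygous males contribute one allele each
  xl <- ct[ct$gene == "TAZ", ]
  expect_lt(sum(xl$AN), 13006L)
  nm <- as.integer(round(0.5 * c(2203L, 4300L)))
  expect_equal(xl$AN, nm + 2L * (c(2203L, 4300L) - nm))
})

test_that("cohort simulation is a pure function of (spec, seed)", {
  vars <- data.frame(gene = "G", hgvs_p = "p.A5V", true_af = 0.02)
  a <- simulateCohort(cohortSpec("C", data.frame(name = "all", n = 500L),
                                 seed = 4L), vars)
  b <- simulateCohort(cohortSpec("C", data.frame(name = "all", n = 500L),
                                 seed = 4L), vars)
  expect_identical(storeCounts(a), storeCounts(b))
  c2 <- simulateCohort(cohortSpec("C", data.frame(name = "all", n = 500L),
                                  seed = 5L), vars)
  expect_false(identical(storeCounts(a), storeCounts(c2)))
  ## the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(simulateCohort(cohortSpec("C",
                                      data.frame(name = "all", n = 100L),
                                      seed = 2L), vars))
  expect_identical(runif(1), before)
})

test_that("zero-frequency variants are absent from the pipeline's view", {
  cat4 <- tiny_catalog()
  chg <- proteinChanges(cat4)
  vars <- data.frame(gene = chg$gene, hgvs_p = chg$raw, true_af = 0)
  st <- simulateCohort(cohortSpec("ESP",
                                  data.frame(name = "all", n = 1000L),
                                  seed = 1L), vars)
  expect_true(all(storeCounts(st)$AC == 0L))
  expect_false(any(lookupPresence(cat4, st)$present))
})

test_that("frequency out of range is rejected", {
  expect_error(simulateCohort(
    espCohortSpec(), data.frame(gene = "G", hgvs_p = "p.A5V",
                                true_af = 0.7)))
})

test_that("alignment column generator hits its conservation extremes", {
  col0 <- simulateAlignmentColumn(10, 0, seed = 1L)
  expect_identical(conservationCall(col0), "pathogenic")
  col1 <- simulateAlignmentColumn(10, 1, seed = 1L)
  expect_identical(conservationCall(col1), "benign")
  expect_identical(simulateAlignmentColumn(5, 0.3, seed = 2L),
                   simulateAlignmentColumn(5, 0.3, seed = 2L))
})

test_that("an inconsistent fixture spec errors listing the violations", {
  bad <- fixtureSpec()
  bad$n_overlap <- 50L           # > min(ESP+, ExAC+)
  bad$n_cosegregating <- 99L     # > familial
  err <- tryCatch(makeStudyFixture(bad), error = conditionMessage)
  expect_match(err, "overlap exceeds")
  expect_match(err, "co-segregating count exceeds")
})

test_that("fixture marginals are re-derived by the pipeline, not copied", {
  fx <- makeStudyFixture()
  ## named literature variants present with their stated attributes
  rec <- catalogRecords(fx$catalog)
  expect_true("MYH7:p.R243H" %in% rec$record_id)
  expect_false(rec$synthetic[rec$record_id == "MYH7:p.R243H"])
  expect_identical(rec$cosegregation[rec$record_id == "MYH7:p.R243H"],
                   "yes")
  ## placeholders are flagged
  expect_equal(sum(rec$synthetic), nRecords(fx$catalog) - 26L + 1L)
  expect_true(all(rec$citations[rec$synthetic] == "synthetic"))
  ## the worked-example allele frequency comes out of the ExAC-like store
  pres <- lookupPresence(fx$catalog, fx$exac)
  expect_equal(signif(pres$allele_frequency[
    pres$variant_id == "MYH7:p.R243H"], 4), 8.236e-06)
  ## the unclassifiable annotation is explicit, not auto-detected
  cls <- classifyCatalog(fx$catalog)
  expect_identical(cls$classification[cls$variant_id == "LDB3:p.D626N"],
                   "unclassifiable")
})

test_that("fixture stop gains include the three named and one synthetic", {
  fx <- makeStudyFixture()
  vt <- variantTable(fx$catalog)
  stops <- vt[vt$variant_class == "nonsense", ]
  expect_equal(nrow(stops), 4L)
  expect_true(all(c("TAZ:p.G195*", "MIB1:p.R530*", "PRDM16:p.K702*") %in%
                    stops$variant_id))
  expect_equal(sum(stops$synthetic), 1L)
})
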