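test_that("allele frequency is exact pooled AC/AN", {
  ## singleton in an ExAC-sized allele pool; oracle: exact division,
  ## 4 significant figures match the printed frequency 0.000008236
  af <- alleleFrequency(data.frame(AC = 1L, AN = 121412L))
  expect_identical(af, 1 / 121412)
  expect_equal(signif(af, 4), 8.236e-06)

  expect_identical(alleleFrequency(data.frame(AC = 0L, AN = 13006L)), 0)
  expect_identical(alleleFrequency(data.frame(AC = 100L, AN = 100L)), 1)
  ## pooling across subpopulations
  expect_identical(alleleFrequency(data.frame(AC = c(1, 2), AN = c(10, 30))),
                   3 / 40)
  expect_error(alleleFrequency(data.frame(AC = 0L, AN = 0L)), "undefined")
  expect_error(alleleFrequency(data.frame(AC = 5L, AN = 4L)))
})

test_that("carrier filter is strict at the threshold and monotone", {
  expect_identical(carrierFilter(c(0, 5, 6)), c(FALSE, FALSE, TRUE))
  expect_true(carrierFilter(3, threshold = 2))
  expect_error(carrierFilter(1, threshold = -1), "non-negative")
  ## monotone in carrier count, anti-monotone in threshold
  counts <- 0:20
  flags <- carrierFilter(counts)
  expect_true(all(diff(flags) >= 0))
  for (thr in 0:10)
    expect_true(all(carrierFilter(counts, thr) >= carrierFilter(counts,
                                                                thr + 1L)))
})

test_that("presence lookup keys on (gene, HGVS p.) with AC >= 1", {
  cat4 <- tiny_catalog()
  pres <- lookupPresence(cat4, tiny_store())
  expect_equal(nrow(pres), 4L)
  expect_equal(pres$present,
               pres$variant_id %in% c("MYBPC3:p.G5R", "LDB3:p.D117N"))
  g5r <- pres[pres$variant_id == "MYBPC3:p.G5R", ]
  expect_equal(g5r$allele_frequency, 3 / 13006)
  expect_equal(g5r$carrier_count, 3L)
  expect_equal(g5r$carrier_convention, "genotype")
  expect_true(all(is.na(pres$allele_frequency[!pres$present])))
  expect_true(all(pres$carrier_count[!pres$present] == 0L))

  empty <- PopulationStore("ESP", data.frame(
    gene = character(), hgvs_p = character(), subpop = character(),
    AC = integer(), AN = integer()), 6503L)
  expect_false(any(lookupPresence(cat4, empty)$present))

  expect_error(lookupPresence(cat4, tiny_store(), cohort_id = "ExAC"),
               "cohort")
})

test_that("carrier convention falls back to the allele-count bound", {
  cat4 <- tiny_catalog()
  st <- tiny_store()
  counts <- storeCounts(st)
  counts$carrier_count <- NA_integer_
  pres <- lookupPresence(cat4, PopulationStore("ESP", counts, 6503L))
  g5r <- pres[pres$variant_id == "MYBPC3:p.G5R", ]
  expect_equal(g5r$carrier_convention, "allele_bound")
  expect_equal(g5r$carrier_count, 3L)
})

test_that("presence overlap counts and bounds", {
  cat4 <- tiny_catalog()
  a <- lookupPresence(cat4, tiny_store())
  b <- a
  expect_equal(unname(presenceOverlap(a, b)), c(2L, 2L, 2L))

  b$present <- !a$present
  ov <- presenceOverlap(a, b)
  expect_equal(unname(ov), c(2L, 2L, 0L))

  expect_error(presenceOverlap(a, b[-1, ]), "different variant sets")

  ## bound property on random presence patterns
  set.seed(11)
  for (i in 1:50) {
    a$present <- runif(4) < 0.5
    b$present <- runif(4) < 0.5
    ov <- presenceOverlap(a, b)
    expect_lte(ov[["n_both"]], min(ov[["n_a"]], ov[["n_b"]]))
  }
})

test_that("minimal VCF store matches the TSV dialect", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    paste0("##INFO=<ID=GENE_HGVSP,Number=1,Type=String,",
           "Description=\"Protein key\">"),
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tG\tA\t.\t.\tAC=3;AN=13006;GENE_HGVSP=MYBPC3:p.G5R",
    "1\t200\t.\tC\tT\t.\t.\tAC=4;AN=13006;GENE_HGVSP=LDB3:p.D117N",
    "1\t300\t.\tA\tG\t.\t.\tAC=9;AN=13006")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(store <- readPopulationVcf(path, "ESP", 6503L),
                 "GENE_HGVSP")
  ct <- storeCounts(store)
  expect_equal(nrow(ct), 2L)                 # unannotated record skipped
  expect_equal(sort(ct$gene), c("LDB3", "MYBPC3"))
  expect_equal(ct$AC[ct$gene == "MYBPC3"], 3L)
  expect_true(all(is.na(ct$carrier_count)))

  pres <- lookupPresence(tiny_catalog(), store)
  expect_equal(sum(pres$present), 2L)
  expect_equal(pres$allele_frequency[pres$variant_id == "MYBPC3:p.G5R"],
               3 / 13006)
})

test_that("estimated AF converges to the simulated truth", {
  ## 30 seeds here; the full >=100-seed check runs in the acceptance suite
  f <- 0.02
  spec_n <- 1500L
  inside <- vapply(1:30, function(s) {
    st <- simulateCohort(
      cohortSpec("C", data.frame(name = "all", n = spec_n), seed = s),
      data.frame(gene = "G1", hgvs_p = "p.A100V", true_af = f))
    af <- alleleFrequency(storeCounts(st))
    abs(af - f) <= qnorm(0.995) * sqrt(f * (1 - f) / (2 * spec_n))
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})
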