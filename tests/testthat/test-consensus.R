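test_that("the voting rule reproduces its defining cases", {
  p3 <- consensusClassify(c(conservation = "pathogenic",
                            grantham = "pathogenic",
                            sift = "pathogenic", polyphen2 = "benign"))
  expect_identical(p3$classification, "pathogenic")
  expect_equal(p3$n_pathogenic_votes, 3L)

  v1 <- consensusClassify(c(conservation = "benign",
                            grantham = "pathogenic",
                            sift = "benign", polyphen2 = "benign"))
  expect_identical(v1$classification, "VUS")

  stop_gain <- consensusClassify(
    c(conservation = "unavailable", grantham = "unavailable",
      sift = "unavailable", polyphen2 = "unavailable"),
    variant_class = "nonsense")
  expect_identical(stop_gain$classification, "not_analyzed")

  clean <- consensusClassify(c(conservation = "benign", grantham = "benign",
                               sift = "benign", polyphen2 = "benign"))
  expect_identical(clean$classification, "benign")

  mismatch <- consensusClassify(c(conservation = "benign",
                                  grantham = "benign",
                                  sift = "benign", polyphen2 = "benign"),
                                isoform_mismatch = TRUE)
  expect_identical(mismatch$classification, "unclassifiable")
})

test_that("a partial panel never yields benign", {
  out <- consensusClassify(c(conservation = "benign", grantham = "benign",
                             sift = "benign", polyphen2 = "unavailable"))
  expect_identical(out$classification, "VUS")
  expect_identical(out$flags, "incomplete_tool_panel")
  relaxed <- consensusClassify(
    c(conservation = "benign", grantham = "benign",
      sift = "benign", polyphen2 = "unavailable"),
    policy = consensusPolicy(benign_requires_full_panel = FALSE))
  expect_identical(relaxed$classification, "benign")
})

test_that("duplicate tool slots are rejected", {
  expect_error(consensusClassify(c(sift = "benign", sift = "pathogenic",
                                   grantham = "benign",
                                   conservation = "benign")),
               "duplicate")
  expect_error(consensusClassify(c(mutationtaster = "pathogenic")),
               "unknown tool")
})

test_that("classifier equals the exhaustive 81-pattern oracle", {
  states <- c("pathogenic", "benign", "unavailable")
  grid <- expand.grid(conservation = states, grantham = states,
                      sift = states, polyphen2 = states,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 81L)
  for (i in seq_len(nrow(grid))) {
    calls <- unlist(grid[i, ])
    got <- consensusClassify(calls)$classification
    expect_identical(got, oracle_consensus(calls),
                     label = paste(calls, collapse = "/"))
  }
})

test_that("adding a pathogenic vote never moves away from pathogenic", {
  rank <- c(benign = 1L, VUS = 2L, pathogenic = 3L)
  states <- c("pathogenic", "benign", "unavailable")
  grid <- expand.grid(conservation = states, grantham = states,
                      sift = states, polyphen2 = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    calls <- unlist(grid[i, ])
    base <- rank[[consensusClassify(calls)$classification]]
    for (slot in names(calls)) {
      if (calls[[slot]] == "pathogenic") next
      up <- calls
      up[[slot]] <- "pathogenic"
      expect_gte(rank[[consensusClassify(up)$classification]], base)
    }
  }
})

test_that("classification is invariant under tool order", {
  calls <- c(conservation = "pathogenic", grantham = "benign",
             sift = "pathogenic", polyphen2 = "unavailable")
  ref <- consensusClassify(calls)
  for (i in 1:5) {
    perm <- sample(calls)
    expect_identical(consensusClassify(perm), ref)
  }
})

test_that("percent convention is truncation toward zero", {
  expect_identical(truncatedPercent(10, 18), 55L)  # 55.6 prints as 55
  expect_identical(truncatedPercent(4, 9), 44L)
  expect_identical(truncatedPercent(29, 56), 51L)
  expect_identical(truncatedPercent(1, 1), 100L)
  expect_identical(truncatedPercent(0, 7), 0L)
  expect_identical(truncatedPercent(c(1, 3), c(2, 0)), c(50L, NA_integer_))
})

test_that("class fractions count and truncate per denominator", {
  cls <- data.frame(classification = c(rep("pathogenic", 10),
                                       rep("VUS", 4),
                                       rep("not_analyzed", 4)))
  frac <- classificationFractions(cls, denominator = "analyzed")
  expect_equal(frac$count[frac$class == "pathogenic"], 10L)
  expect_equal(frac$percent[frac$class == "pathogenic"],
               truncatedPercent(10, 14))
  expect_true(is.na(frac$percent[frac$class == "not_analyzed"]))

  frac_all <- classificationFractions(cls, denominator = "all")
  expect_equal(frac_all$percent[frac_all$class == "pathogenic"],
               truncatedPercent(10, 18))

  one <- classificationFractions(data.frame(classification = "pathogenic"))
  expect_equal(one$percent[one$class == "pathogenic"], 100L)

  expect_error(classificationFractions(data.frame(classification =
                                                    character())),
               "no classifications")
})

test_that("truncated percents of analyzed classes sum to 97-100", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    cls <- data.frame(classification = sample(
      c("pathogenic", "VUS", "benign", "unclassifiable"), n,
      replace = TRUE))
    frac <- classificationFractions(cls)
    expect_equal(sum(frac$count), n)
    tot <- sum(frac$percent[frac$class != "not_analyzed"])
    expect_gte(tot, 97)
    expect_lte(tot, 100)
  }
})

test_that("the published class triple is the unique truncation solution", {
  ## brute-force integer-constraint solve: p + v + b = 55 analyzed
  ## missense-classified variants (56 analyzed minus 1 unclassifiable),
  ## floor percents at denominator 56 equal to 51/41/5
  sols <- list()
  for (p in 0:55) for (v in 0:(55 - p)) {
    b <- 55 - p - v
    if ((100 * p) %/% 56 == 51 && (100 * v) %/% 56 == 41 &&
        (100 * b) %/% 56 == 5)
      sols[[length(sols) + 1]] <- c(p, v, b)
  }
  expect_length(sols, 1L)
  expect_equal(sols[[1]], c(29, 23, 3))
  ## and no half-up rounding solution exists for the same percents
  round_sols <- 0L
  for (p in 0:55) for (v in 0:(55 - p)) {
    b <- 55 - p - v
    if (round(100 * p / 56) == 51 && round(100 * v / 56) == 41 &&
        round(100 * b / 56) == 5)
      round_sols <- round_sols + 1L
  }
  expect_equal(round_sols, 0L)
})
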