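# The five-category quality classifier: rule order, boundaries, totality.

test_that("classify_bin reproduces the category table", {
  full <- census_of(18, TRUE, TRUE, TRUE)
  expect_equal(category_of(95, 2, full), "high_quality")
  expect_equal(category_of(95, 2, census_of(17, TRUE, TRUE, TRUE)),
               "near_complete")
  # completeness must strictly exceed 90
  expect_equal(category_of(90, 2, census_of(20, TRUE, TRUE, TRUE)),
               "medium_quality")
  expect_equal(category_of(60, 8), "medium_quality")
  expect_equal(category_of(40, 3), "low_quality")
  expect_equal(category_of(55, 15), "failed")
})

test_that("boundary ties resolve by first-match rule order", {
  # contamination exactly 10 with completeness >= 50 is medium, not failed
  expect_equal(category_of(60, 10), "medium_quality")
  expect_equal(category_of(40, 10), "low_quality")
  # contamination exactly 5 stays eligible for near-complete/high
  expect_equal(category_of(95, 5), "near_complete")
  expect_equal(category_of(95, 5, census_of(18, TRUE, TRUE, TRUE)),
               "high_quality")
  # completeness exactly 50 is medium, just below is low
  expect_equal(category_of(50, 2), "medium_quality")
  expect_equal(category_of(49.99, 2), "low_quality")
})

test_that("high quality requires all three rRNA genes and 18 tRNAs", {
  expect_equal(category_of(95, 2, census_of(18, TRUE, TRUE, FALSE)),
               "near_complete")
  expect_equal(category_of(95, 2, census_of(18, FALSE, TRUE, TRUE)),
               "near_complete")
  expect_equal(category_of(95, 2, census_of(17, TRUE, TRUE, TRUE)),
               "near_complete")
  expect_equal(category_of(95, 2, census_of(18, TRUE, TRUE, TRUE)),
               "high_quality")
})

test_that("the rule trace records the first-match evaluation", {
  cl <- classify_bin(quality_estimate("b", 95, 2), empty_rna_census())
  expect_equal(cl$category, "near_complete")
  expect_true(nrow(cl$trace) > 0)
  # high_quality was evaluated and failed on the census checks
  hq <- cl$trace[cl$trace$rule == "high_quality", ]
  expect_true(all(hq$passed[hq$check == "completeness_above_90"]))
  expect_false(any(hq$passed[hq$check == "trna_at_least_18"]))
  # evaluation stopped at the winning rule
  expect_equal(tail(cl$trace$rule, 1), "near_complete")
})

test_that("classifier is total and matches the independent oracle", {
  set.seed(301)
  n <- 10000
  comp <- round(runif(n, 0, 100), 2)
  cont <- round(runif(n, 0, 200) * sample(c(1, 0.05), n, replace = TRUE), 2)
  trna <- sample(0:20, n, replace = TRUE)
  r5 <- runif(n) < 0.5; r16 <- runif(n) < 0.5; r23 <- runif(n) < 0.5
  cats <- character(n)
  for (i in seq_len(n)) {
    cats[i] <- category_of(comp[i], cont[i],
                           census_from(trna[i], r5[i], r16[i], r23[i]))
    expect_false(is.na(cats[i]))
  }
  oracle <- mapply(classify_oracle, comp, cont, trna, r5, r16, r23)
  expect_equal(cats, unname(oracle))
})

test_that("category ordering is monotone in completeness, contamination and census", {
  rank_of <- c(failed = 0, low_quality = 1, medium_quality = 1,
               near_complete = 2, high_quality = 3)
  set.seed(302)
  for (i in 1:300) {
    comp <- runif(1, 0, 99); cont <- runif(1, 0, 15)
    trna <- sample(0:20, 1); flags <- runif(3) < 0.5
    cen <- census_from(trna, flags[1], flags[2], flags[3])
    base <- rank_of[[category_of(comp, cont, cen)]]
    # raising completeness never demotes (low/medium share a rank: that
    # boundary is a completeness partition, not a quality ordering)
    up <- category_of(min(100, comp + runif(1, 0, 100 - comp)), cont, cen)
    expect_gte(rank_of[[up]], base)
    # raising contamination never promotes
    down <- category_of(comp, cont + runif(1, 0, 20), cen)
    expect_lte(rank_of[[down]], base)
    # a fuller census never demotes
    fuller <- census_from(max(trna, sample(0:20, 1)), flags[1] || TRUE,
                          flags[2] || TRUE, flags[3] || TRUE)
    expect_gte(rank_of[[category_of(comp, cont, fuller)]], base)
  }
})

test_that("thresholds are configurable and validated", {
  th <- classification_thresholds(hq_completeness = 95, hq_min_trna = 20)
  expect_equal(category_of(93, 2, census_of(20, TRUE, TRUE, TRUE), th),
               "medium_quality")
  expect_equal(category_of(96, 2, census_of(19, TRUE, TRUE, TRUE), th),
               "near_complete")
  expect_error(classification_thresholds(mq_completeness = 95),
               "mq_completeness <= hq_completeness")
  expect_error(classification_thresholds(hq_contamination = 20),
               "hq_contamination <= mq_contamination")
})

test_that("classify_all joins bins to estimates and handles gaps", {
  q <- list(b1 = quality_estimate("b1", 95, 2),
            b2 = quality_estimate("b2", 60, 8),
            b3 = quality_estimate("b3", 55, 15))
  cen <- list(b1 = census_of(20, TRUE, TRUE, TRUE))
  expect_warning(cls <- classify_all(q, cen), "empty RNA census")
  expect_equal(vapply(cls, `[[`, "", "category"),
               c(b1 = "high_quality", b2 = "medium_quality", b3 = "failed"))

  # a bin on disk without a quality estimate is a hard error
  expect_error(suppressWarnings(
    classify_all(q[1:2], cen, bin_ids = c("b1", "b2", "b9"))), "b9")

  expect_length(classify_all(list(), list()), 0)
})
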