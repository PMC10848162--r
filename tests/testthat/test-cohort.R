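test_that("summarize is invariant to patient order and to re-serialization", {
  fixture <- build_reference_fixture(test_catalog)
  res <- classify_cohort(fixture, test_catalog, test_config)
  s1 <- summarize_cohort(fixture, res, test_catalog, test_config)
  perm <- sample(seq_along(fixture))
  s2 <- summarize_cohort(fixture[perm], res[perm, ], test_catalog, test_config)
  expect_identical(unclass(s1), unclass(s2))
  # write, re-read, summarize again
  dir <- withr::local_tempdir()
  write_cohort(fixture, dir)
  back <- read_cohort(dir, test_catalog)
  s3 <- summarize_cohort(back, catalog = test_catalog, config = test_config)
  expect_identical(unclass(s1), unclass(s3))
})

test_that("an empty cohort gives an all-zero summary", {
  s <- summarize_cohort(list(), catalog = test_catalog, config = test_config)
  expect_identical(s$n, 0L)
  expect_identical(s$pancytopenia_count, 0L)
  expect_identical(nrow(s$primary_label_counts), 0L)
})

test_that("mismatched result ids are an error", {
  fixture <- build_reference_fixture(test_catalog)
  res <- classify_cohort(fixture, test_catalog, test_config)
  res$patient_id[1] <- "nope"
  expect_error(
    summarize_cohort(fixture, res, test_catalog, test_config),
    "align"
  )
})

test_that("percent fields expose both raw and truncated conventions", {
  fixture <- build_reference_fixture(test_catalog)
  s <- summarize_cohort(fixture, catalog = test_catalog, config = test_config)
  fg <- s$feature_group_prevalence
  expect_true(all(fg$percent_trunc == trunc(fg$percent_raw)))
  expect_true(all(abs(fg$percent_raw - 100 * fg$count / s$n) < 1e-9))
})

test_that("chi-square matches the hand-computed contingency formula", {
  # independent oracle: direct formula on a 2x2 table {10,5; 8,7}
  o <- c(10, 5, 8, 7)
  tab <- matrix(o, 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - e)^2 / e) # = 0.5556 (no continuity correction)
  labels <- rep(c("g1", "g1", "g2", "g2"), times = o)
  values <- rep(c("x", "y", "x", "y"), times = o)
  results <- tibble::tibble(
    patient_id = sprintf("p%02d", seq_along(labels)),
    primary = labels, onset_category = "le2"
  )
  out <- group_compare(
    lapply(seq_along(labels), function(i) mk_record(sprintf("p%02d", i))),
    results, values,
    type = "categorical", config = test_config
  )
  expect_equal(out$statistic, oracle, tolerance = 1e-10)
  expect_equal(oracle, 0.55556, tolerance = 1e-4)
  expect_equal(out$df, 1, ignore_attr = TRUE)
})

test_that("anova matches the hand-computed F statistic", {
  y <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b"), each = 3)
  # oracle: between/within decomposition by hand
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 1) / (ssw / 4)
  results <- tibble::tibble(
    patient_id = sprintf("p%d", 1:6), primary = g, onset_category = "le2"
  )
  out <- group_compare(
    lapply(1:6, function(i) mk_record(sprintf("p%d", i))),
    results, y,
    type = "continuous", config = test_config
  )
  expect_equal(out$statistic, f_oracle, tolerance = 1e-10)
  expect_identical(c(out$df, out$df2), c(1, 4))
})

test_that("group comparison needs at least two groups", {
  results <- tibble::tibble(
    patient_id = c("a", "b"), primary = c("DBA", "DBA"),
    onset_category = "le2"
  )
  expect_error(
    group_compare(list(mk_record("a"), mk_record("b")), results, c(1, 2)),
    "at least 2 groups"
  )
})

test_that("sex and age differences across fixture groups are non-significant", {
  fixture <- build_reference_fixture(test_catalog)
  res <- classify_cohort(fixture, test_catalog, test_config)
  sex <- group_compare(fixture, res, "sex", config = test_config)
  expect_false(sex$significant)
  age <- group_compare(fixture, res, "age_years", config = test_config)
  expect_identical(age$method, "anova")
})

test_that("describe_values follows the stated conventions", {
  out <- describe_values(c(1, 2, 3, 4))
  expect_identical(out$median, 2.5)
  expect_equal(out$sd, sd(c(1, 2, 3, 4)))
  single <- describe_values(5)
  expect_true(is.na(single$sd))
  expect_identical(single$mean, 5)
  # fixture evaluation ages were drawn to match the cohort report
  fixture <- build_reference_fixture(test_catalog)
  ages <- describe_values(vapply(fixture, `[[`, 0, "age_years"))
  expect_equal(ages$mean, 9.02, tolerance = 1e-6)
  expect_equal(ages$sd, 6.01, tolerance = 0.005)
})
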