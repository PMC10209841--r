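test_that("normality test behaves at both tails and on degenerate input", {
  set.seed(1)
  expect_gte(normality_test(rnorm(1000)), 0.05)
  expect_lt(normality_test(exp(rnorm(1000))), 0.05)
  expect_true(is.na(normality_test(rep(3.2, 10))))
  expect_error(normality_test(c(1, 2)), "at least 3")
})

test_that("paired comparison gates on normality of both samples", {
  set.seed(2)
  d0 <- rnorm(30, 10, 1); d45 <- d0 - 3 + rnorm(30, 0, 1)  # 3-sd shift
  res <- paired_compare(d0, d45)
  expect_equal(res$test_used, "paired-t")
  expect_true(res$significant)
  expect_equal(res$direction, -1)

  skew0 <- exp(rnorm(30)); skew45 <- skew0 * 0.4
  res2 <- paired_compare(skew0, skew45)
  expect_equal(res2$test_used, "wilcoxon")
  expect_true((res2$normality_p_d0 < 0.05) || (res2$normality_p_d45 < 0.05))

  # gating contract: reported test always matches the normality p-values
  for (s in 1:10) {
    set.seed(600 + s)
    x <- if (s %% 2) rnorm(20) else exp(rnorm(20))
    y <- x + rnorm(20, 0.2)
    r <- paired_compare(x, y)
    normal_both <- !is.na(r$normality_p_d0) && !is.na(r$normality_p_d45) &&
      r$normality_p_d0 >= 0.05 && r$normality_p_d45 >= 0.05
    expect_equal(r$test_used, if (normal_both) "paired-t" else "wilcoxon")
  }
})

test_that("identical samples give a degenerate, non-significant comparison", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_compare(x, x)
  expect_equal(res$test_used, "degenerate")
  expect_false(res$significant)
  expect_true(is.na(res$p_value))
  expect_error(paired_compare(1:4, 1:5), "equal length")
})

test_that("Spearman correlation handles monotone extremes and banding", {
  x <- c(2, 5, 1, 9, 7, 4)
  res <- spearman_correlation(x, exp(x))        # strictly increasing map
  expect_equal(res$rs, 1)
  expect_equal(res$band, "very strong")
  expect_equal(spearman_correlation(x, -x^3)$rs, -1)
  expect_error(spearman_correlation(x, rep(1, 6)), "constant")
  expect_error(spearman_correlation(x, x[1:3]), "equal length")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(25); y <- x + rnorm(25)
  base <- spearman_correlation(x, y)$rs
  expect_equal(spearman_correlation(exp(x), y)$rs, base)
  expect_equal(spearman_correlation(x, y^3 + 5 * y)$rs, base)
  expect_equal(spearman_correlation(rank(x), y)$rs, base)
})

test_that("strength bands are total on [0,1] and closed at the printed bounds", {
  expect_equal(correlation_band(0), "very weak")
  expect_equal(correlation_band(0.19), "very weak")
  expect_equal(correlation_band(0.194), "very weak")
  expect_equal(correlation_band(0.195), "weak")   # rounds to 0.20 before lookup
  expect_equal(correlation_band(0.2), "weak")
  expect_equal(correlation_band(0.39), "weak")
  expect_equal(correlation_band(0.4), "moderate")
  expect_equal(correlation_band(0.47), "moderate")
  expect_equal(correlation_band(0.69), "moderate")
  expect_equal(correlation_band(0.7), "strong")
  expect_equal(correlation_band(0.89), "strong")
  expect_equal(correlation_band(0.9), "very strong")
  expect_equal(correlation_band(1), "very strong")
  expect_equal(correlation_band(-0.47), "moderate")   # magnitude is banded
  # every magnitude on a fine grid maps to exactly one label
  grid <- seq(0, 1, by = 0.001)
  labs <- vapply(grid, correlation_band, character(1))
  expect_true(all(labs %in% c("very weak", "weak", "moderate", "strong",
                              "very strong")))
  expect_true(!is.unsorted(match(labs, c("very weak", "weak", "moderate",
                                         "strong", "very strong"))))
})

test_that("cohort report covers every parameter and validates pairing", {
  set.seed(4)
  tab <- do.call(rbind, lapply(c("ra", "wa", "reference"), function(p) {
    base <- rnorm(12, 50, 5)
    data.frame(subject_id = 1:12, parameter = p, d0 = base,
               d45 = base - 4 + rnorm(12))
  }))
  rep <- cohort_report(tab)
  expect_equal(nrow(rep$comparisons), 3)
  expect_equal(sort(rep$comparisons$parameter), c("ra", "reference", "wa"))
  expect_equal(nrow(rep$correlations), 4)   # ra, wa at D0 and D45

  one <- tab[tab$parameter == "ra", ]
  rep1 <- cohort_report(one, reference = NULL)
  expect_equal(nrow(rep1$comparisons), 1)
  expect_null(rep1$correlations)

  bad <- tab; bad$d45[3] <- NA
  expect_error(cohort_report(bad), "missing pairs.*3")
})

test_that("report files are written as CSV plus readable text", {
  tmp <- withr::local_tempdir()
  set.seed(5)
  tab <- data.frame(subject_id = 1:10, parameter = "wa",
                    d0 = rnorm(10, 1), d45 = rnorm(10, 0.5))
  files <- write_cohort_report(cohort_report(tab), tmp)
  expect_true(all(file.exists(
    file.path(tmp, c("cohort_comparisons.csv", "cohort_report.txt")))))
  back <- read.csv(file.path(tmp, "cohort_comparisons.csv"))
  expect_equal(back$parameter, "wa")
})
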