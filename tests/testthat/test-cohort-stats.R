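test_that("cohort summaries reproduce closed-form mean, SD and 95% CI", {
  s <- summarize_scores(rep(3L, 10), cohort = "z")
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(3, 3))

  # sample SD with the n-1 denominator: sd({1..5}) = sqrt(2.5)
  s <- summarize_scores(1:5)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5), tolerance = 1e-12)

  # the published whole-sample summary (mean 2.19, SD 0.880, n 150)
  # reproduces the printed interval 2.05-2.33 at two decimals
  s <- summarize_from_stats(mean = 2.19, sd = 0.880, n = 150)
  expect_equal(round(s$ci_low, 2), 2.05)
  expect_equal(round(s$ci_high, 2), 2.33)

  expect_error(summarize_scores(integer(0)), "empty")
  expect_warning(s <- summarize_scores(4L), "n = 1")
  expect_true(is.na(s$sd) && is.na(s$ci_low))
})

test_that("CI half-width is exactly t-quantile times sd/sqrt(n)", {
  for (n in c(5, 30, 150, 400)) {
    s <- summarize_from_stats(mean = 0, sd = 1.3, n = n)
    half <- (s$ci_high - s$ci_low) / 2
    expect_equal(half * sqrt(n) / stats::qt(0.975, n - 1), 1.3,
                 tolerance = 1e-12)
  }
})

test_that("pooled t-test matches the hand-computed fixture to 1e-9", {
  # {1,2,3} vs {2,3,4}: pooled variance 1, SE = sqrt(2/3),
  # t = (3-2)/SE = sqrt(3/2), df = 4, one-tailed p(greater) computed by hand
  cmp <- compare_cohorts(c(1, 2, 3), c(2, 3, 4), direction = "greater")
  expect_equal(cmp$df, 4L)
  expect_equal(cmp$t_statistic, 1.224744871391589, tolerance = 1e-9)
  expect_equal(cmp$p_one_tailed, 0.143932067363345, tolerance = 1e-9)
  expect_false(cmp$significant)

  # independent cross-check against stats::t.test (never the implementation)
  tt <- stats::t.test(c(2, 3, 4), c(1, 2, 3), var.equal = TRUE,
                      alternative = "greater")
  expect_equal(cmp$p_one_tailed, unname(tt$p.value), tolerance = 1e-12)
  expect_equal(cmp$t_statistic, unname(tt$statistic), tolerance = 1e-12)
})

test_that("pooled t-test symmetry and degeneracy conventions", {
  # identical groups: exact symmetry point
  cmp <- compare_cohorts(c(2, 3, 4), c(2, 3, 4), direction = "greater")
  expect_identical(cmp$t_statistic, 0)
  expect_identical(cmp$p_one_tailed, 0.5)
  expect_false(cmp$significant)

  # antisymmetry under group swap; the two tails sum to one
  set.seed(51)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(1:5, 40, replace = TRUE)
  f <- compare_cohorts(a, b, "greater")
  r <- compare_cohorts(b, a, "greater")
  expect_equal(f$t_statistic, -r$t_statistic, tolerance = 1e-12)
  expect_equal(f$p_one_tailed + compare_cohorts(a, b, "less")$p_one_tailed, 1,
               tolerance = 1e-12)

  # zero pooled variance with unequal means degenerates
  cmp <- compare_cohorts(c(2, 2, 2), c(4, 4, 4), direction = "greater")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_one_tailed, 0)

  # the study design sizes give the printed degrees of freedom
  expect_equal(compare_cohorts(sample(1:5, 68, TRUE), sample(1:5, 82, TRUE))$df,
               148L)
})

test_that("ages bin by completed years into the reporting categories", {
  expect_equal(as.character(age_bin(c(0.5, 7, 18.9, 1, 2.99, 25))),
               c("<1 year old", "5-7 years old", "15-18 years old",
                 "1-2 years old", "1-2 years old", "19-25 years old"))
  expect_warning(b <- age_bin(27), "19-25")
  expect_equal(as.character(b), "19-25 years old")
  expect_error(age_bin(-1), "non-negative")
  # bins partition 0..25
  set.seed(52)
  expect_false(anyNA(age_bin(stats::runif(200, 0, 25))))
})

test_that("pooling the published per-cohort counts gives the printed percentages", {
  pooled <- pooled_percentages(reference_demographics())
  pick <- function(cat) pooled$pct[pooled$category == cat]
  expect_equal(pick("Male"), 56.67)
  expect_equal(pick("White"), 82.67)
  expect_equal(pick("Solid tumor"), 38.67)
  # counts per dimension sum to the total sample
  sums <- tapply(pooled$n, pooled$dimension, sum)
  expect_true(all(sums == 150L))
})

test_that("demographics_table partitions each cohort and formats both conventions", {
  sim <- generate_cohort(default_scenario(seed = 9L))
  pats <- sim$patients
  tab <- demographics_table(pats)
  for (co in c("2017-2018", "2022-2023", "pooled")) {
    sub <- tab[tab$cohort == co, ]
    n_expected <- if (co == "pooled") nrow(pats) else sum(pats$cohort == co)
    expect_true(all(tapply(sub$n, sub$dimension, sum) == n_expected))
  }
  # per-cohort percentages are integers; pooled keeps two decimals
  per <- tab$pct[tab$cohort != "pooled"]
  expect_true(all(per == round(per)))

  one <- demographics_table(pats[1, ])
  expect_true(all(one$pct[one$n > 0] == 100))
  expect_true(all(one$pct[one$n == 0] == 0))
})
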