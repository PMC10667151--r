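test_that("exact signed-rank p-values match enumeration and base R", {
  # three positive differences: 8 sign patterns, two one-sided tails of 1/8
  res <- wilcoxon_paired(c(1, 2, 3), c(0, 0, 0))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$statistic, 6)

  # antisymmetric differences give p = 1
  anti <- wilcoxon_paired(c(-2, -1, 1, 2), rep(0, 4))
  expect_equal(anti$p_value, 1)

  # tie-free random samples agree with stats::wilcox.test exactly
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- wilcoxon_paired(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, conf.int = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$conf_int, as.vector(ref$conf.int), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("ties and zeros are handled by average ranks and dropping", {
  # zero differences dropped; tied |d| share average ranks yet stay exact
  res <- wilcoxon_paired(c(5, 5, 3, 0), c(4, 4, 0, 0))
  expect_true(res$exact)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_identical(res$n_used, 3L)
  expect_error(wilcoxon_paired(c(1, 2), c(1, 2)), "zero")
})

test_that("exact and normal-approximation p-values agree at moderate n", {
  set.seed(8)
  diffs <- numeric(40)
  for (i in 1:40) {
    a <- rnorm(15, 0.3); b <- rep(0, 15)
    pe <- wilcoxon_paired(a, b, exact_max = 15)$p_value
    pn <- wilcoxon_paired(a, b, exact_max = 0)$p_value
    diffs[i] <- abs(pe - pn)
  }
  # two-sided doubling makes the worst single case slightly larger than the
  # per-tail approximation error
  expect_lt(mean(diffs), 0.01)
  expect_lt(max(diffs), 0.015)
})

test_that("a strong paired effect at n = 14 is detected with high power", {
  # oracle-calibrated: differences ~ N(1, 1) give power > 0.9 at alpha 0.05
  set.seed(41)
  rejected <- replicate(200, {
    wilcoxon_paired(rnorm(14, 1, 1), rep(0, 14))$p_value < 0.05
  })
  expect_gte(mean(rejected), 0.9)
})

test_that("within-subject CV matches the duplicate-measurement estimator", {
  expect_equal(cv_within(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(cv_within(10, 12), 100 * (2 / sqrt(2)) / 11, tolerance = 1e-12)
  expect_equal(cv_within(10, 12), 12.86, tolerance = 1e-3)
  set.seed(2)
  x1 <- runif(8, 20, 30); x2 <- x1 + rnorm(8)
  expect_equal(cv_within(3 * x1, 3 * x2), cv_within(x1, x2),
               tolerance = 1e-12)
  expect_error(cv_within(c(1, -2), c(1, 1)), "non-positive")
})

test_that("ICC(2,1) mean squares match a brute-force ANOVA decomposition", {
  set.seed(6)
  m <- matrix(rnorm(12, 10), 6, 2)
  res <- icc_2_1(m)
  # oracle: two-way ANOVA via stats::aov
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  expect_equal(res$msr, ms[1], tolerance = 1e-10)
  expect_equal(res$msc, ms[2], tolerance = 1e-10)
  expect_equal(res$mse, ms[3], tolerance = 1e-10)
  icc_oracle <- (ms[1] - ms[3]) /
    (ms[1] + (2 - 1) * ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
})

test_that("ICC(2,1) direction and invariances are definitional", {
  set.seed(9)
  x <- rnorm(8, 20, 4)
  dup <- cbind(x, x)
  res <- icc_2_1(dup)
  expect_equal(res$icc, 1, tolerance = 1e-12)
  expect_identical(res$category, "excellent")

  two <- cbind(x, x + rnorm(8, 0, 0.5))
  base <- icc_2_1(two)$icc
  # same constant everywhere: invariant
  expect_equal(icc_2_1(two + 100)$icc, base, tolerance = 1e-9)
  # constant added to one rater only: absolute agreement drops
  shifted <- two; shifted[, 2] <- shifted[, 2] + 10
  expect_lt(icc_2_1(shifted)$icc, base)
  expect_error(icc_2_1(matrix(5, 4, 2)), "variance")
  expect_error(icc_2_1(matrix(1:4, 4, 1)), "raters")
})

test_that("Bland-Altman bias and limits follow the standard formulas", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))

  res <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(res$bias, 0)
  expect_equal(res$loa_lower, -1.96)
  expect_equal(res$loa_upper, 1.96)
  expect_equal(res$ci_bias, c(-1, 1) * qt(0.975, 2) / sqrt(3))
  expect_error(bland_altman(1:2, 2:3), "n >= 3")
})

test_that("Bland-Altman confidence widths shrink as 1/sqrt(n)", {
  set.seed(12)
  width <- function(n) {
    d <- rnorm(n, 0, 1)
    r <- bland_altman(d, rep(0, n))
    diff(r$ci_bias)
  }
  w20 <- median(replicate(200, width(20)))
  w80 <- median(replicate(200, width(80)))
  expect_equal(w20 / w80, 2, tolerance = 0.25)
})

test_that("percentage difference of medians is symmetric and scale-free", {
  expect_equal(pct_diff_medians(37.9, 25.0), 41.0, tolerance = 5e-3)
  expect_equal(pct_diff_medians(15.8, 9.8), 46.9, tolerance = 5e-3)
  expect_equal(pct_diff_medians(7, 7), 0)
  expect_equal(pct_diff_medians(3, 5), pct_diff_medians(5, 3))
  expect_equal(pct_diff_medians(30, 50), pct_diff_medians(3, 5))
  expect_error(pct_diff_medians(1, -1), "non-positive")
})

test_that("cohort summaries are internally consistent", {
  set.seed(33)
  grid <- expand.grid(subject = 1:8, condition = c("long", "short"),
                      muscle = c("gastrocnemius", "soleus"),
                      parameter = c("hpv_au", "ttp_s"))
  grid$value <- ifelse(grid$parameter == "hpv_au", 1.04, 30) +
    rnorm(nrow(grid), 0, 0.02) +
    ifelse(grid$condition == "long" & grid$parameter == "ttp_s", 4, 0)
  rep_tab <- summarize_cohort(grid, "long", "short")
  expect_identical(nrow(rep_tab), 4L)
  for (i in seq_len(nrow(rep_tab))) {
    expect_equal(rep_tab$delta_pct[i],
                 pct_diff_medians(rep_tab$median_a[i], rep_tab$median_b[i]))
  }
  expect_true(all(rep_tab$n_pairs == 8))
  # constant column: IQR 0
  const <- grid; const$value <- 5
  ct <- summarize_cohort(const, "long", "short")
  expect_true(all(ct$iqr_a == 0))
  # missing group warns and is omitted
  part <- grid[!(grid$muscle == "soleus" & grid$condition == "short"), ]
  ws <- testthat::capture_warnings(pt <- summarize_cohort(part, "long",
                                                          "short"))
  expect_true(length(ws) >= 1 && all(grepl("omitted", ws)))
  expect_identical(nrow(pt), 2L)
})

test_that("repeatability summary applies CV_w per parameter and muscle", {
  set.seed(44)
  d <- expand.grid(subject = 1:6, muscle = "gastrocnemius",
                   parameter = "hpv_au", repeat_id = 1:2)
  d$value <- 1.04 + rnorm(nrow(d), 0, 0.01)
  tab <- summarize_repeatability(d)
  x1 <- d$value[d$repeat_id == 1]; x2 <- d$value[d$repeat_id == 2]
  expect_equal(tab$cv_w_pct, cv_within(x1, x2))
  expect_identical(tab$n, 6L)
})
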