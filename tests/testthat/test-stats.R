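test_that("signed-rank p-values match exhaustive sign enumeration", {
  # doubled pairs: all differences negative, n = 5 -> p = 2/32
  m1 <- c(1, 2, 3, 4, 5); m2 <- c(2, 4, 6, 8, 10)
  res <- paired_wilcoxon(m1, m2)
  expect_equal(res$p_value, wilcoxon_enum(m1, m2))
  expect_equal(res$p_value, 0.0625)
  # single pair: both assignments equally extreme
  expect_equal(paired_wilcoxon(1, 2)$p_value, 1)
  # random cases with ties, n = 1..8
  set.seed(13)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    a <- sample(0:6, n, replace = TRUE)
    b <- sample(0:6, n, replace = TRUE)
    expect_equal(paired_wilcoxon(a, b)$p_value, wilcoxon_enum(a, b))
  }
})

test_that("signed-rank agrees with wilcox.test on untied data", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(paired_wilcoxon(a, b)$p_value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("identical vectors give p = 1 with the all-zero flag", {
  res <- paired_wilcoxon(c(3, 1, 4), c(3, 1, 4))
  expect_equal(res$p_value, 1)
  expect_true(res$all_zero)
})

test_that("the test is symmetric under swapping the methods", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    p1 <- paired_wilcoxon(a, b)$p_value
    p2 <- paired_wilcoxon(b, a)$p_value
    expect_equal(p1, p2)
    expect_true(p1 > 0 && p1 <= 1)
  }
})

test_that("ICC(2,1) matches an aov-based mean-squares oracle", {
  set.seed(17)
  a <- rnorm(12, 50, 10)
  b <- a + rnorm(12, 0, 3)
  res <- icc(a, b)
  # independent route: two-way ANOVA via stats::aov
  n <- 12; k <- 2
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(1:n, k)),
                   method = factor(rep(1:k, each = n)))
  ms <- summary(aov(y ~ subject + method, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$estimate, expected)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
})

test_that("perfect agreement gives ICC 1; offsets are penalised", {
  a <- c(10, 20, 30, 40, 55)
  expect_equal(icc(a, a)$estimate, 1)
  offset <- icc(a, a + 30)
  expect_lt(offset$estimate, 1)
  # consistency-type ICC from the same mean squares would be 1; absolute
  # agreement must be smaller for a pure offset
  expect_lt(offset$estimate, 0.9)
})

test_that("ICC is scale invariant and near 0 for independent noise", {
  set.seed(19)
  a <- rnorm(20); b <- a + rnorm(20, 0, 0.5)
  expect_equal(icc(3.7 * a, 3.7 * b)$estimate, icc(a, b)$estimate)
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(50); y <- rnorm(50)
    if (abs(icc(x, y)$estimate) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("zero total variance flags the ICC as undefined", {
  res <- icc(rep(5, 4), rep(5, 4))
  expect_true(res$degenerate)
  expect_true(is.na(res$estimate))
})

test_that("Bland-Altman limits are mean plus/minus two sample SDs", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_diff, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  # diffs {-1, +1}: mean 0, sample SD sqrt(2), limits at +/- 2*sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, -2 * sqrt(2))
  expect_equal(ba$loa_high, 2 * sqrt(2))

  off <- bland_altman(c(4, 5, 6) + 2.5, c(4, 5, 6))
  expect_equal(off$mean_diff, 2.5)
  expect_equal(c(off$loa_low, off$loa_high), c(2.5, 2.5))

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("limits widen monotonically with added difference variance", {
  set.seed(23)
  a <- rnorm(30, 100, 5)
  widths <- sapply(c(0.5, 2, 5), function(s) {
    ba <- bland_altman(a, a + rnorm(30, 0, s))
    ba$loa_high - ba$loa_low
  })
  expect_true(all(diff(widths) > 0))
})

test_that("summary quartiles use linear interpolation", {
  expect_equal(summarize_values(1:5)$median, 3)
  s1 <- summarize_values(23)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(23, 23, 23))
  s3 <- summarize_values(c(9, 23, 97))
  expect_equal(s3$q1, 16)    # sorted-order-statistic interpolation
  expect_equal(s3$q3, 60)
})
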