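test_that("Pearson correlation reproduces the published training-table values", {
  t1 <- load_table1()
  expect_equal(round(cor_test_pearson(t1$extra$wrhw_f1, t1$activity)$statistic, 2),
               0.67)
  expect_equal(round(cor_test_pearson(t1$extra$dryd_f2, t1$activity)$statistic, 2),
               0.58)
  t2 <- load_table2()
  expect_equal(round(cor_test_pearson(t2$extra$rhhk_f3, t2$extra$delta)$statistic, 2),
               0.75)
  expect_equal(round(cor_test_pearson(t2$extra$yrhb_f4, t2$extra$sigma)$statistic, 2),
               0.86)
})

test_that("correlation statistics agree with definitional and stats:: oracles", {
  x <- 1:8
  expect_equal(cor_test_pearson(x, 2 * x + 1)$statistic, 1)
  expect_equal(cor_test_spearman(x, exp(x))$statistic, 1)
  expect_equal(cor_test_spearman(x, -x)$statistic, -1)
  expect_equal(cor_test_kendall(x, x^3)$statistic, 1)
  expect_equal(cor_test_pearson(rep(1, 6), rnorm(6))$alpha, 1)
  set.seed(41)
  for (k in 1:100) {
    n <- sample(5:15, 1)
    x <- round(rnorm(n), 1)  # rounding forces ties
    y <- round(rnorm(n), 1)
    p <- cor_test_pearson(x, y)
    expect_equal(p$statistic, naive_pearson(x, y), tolerance = 1e-10)
    if (sd(x) > 0 && sd(y) > 0) {
      ct <- suppressWarnings(cor.test(x, y))
      expect_equal(p$alpha, ct$p.value, tolerance = 1e-8)
      s <- cor_test_spearman(x, y)
      expect_equal(s$statistic, suppressWarnings(cor(x, y, method = "spearman")),
                   tolerance = 1e-10)
      kd <- cor_test_kendall(x, y)
      expect_equal(kd$statistic, naive_kendall_taub(x, y), tolerance = 1e-10)
      expect_equal(kd$statistic, cor(x, y, method = "kendall"), tolerance = 1e-10)
    }
  }
})

test_that("dichotomous tests median-split correctly and match exact oracles", {
  # perfectly aligned split: Fisher two-sided p = 2/252
  x <- c(1:5, 11:15)
  y <- c(2:6, 12:16)
  dt <- dichotomous_tests(x, y)
  expect_equal(dt$fisher$alpha, 2 / choose(10, 5), tolerance = 1e-12)
  expect_gt(dt$chi2$statistic, 0)
  # independent balanced table: chi2 statistic 0, alpha 1
  x2 <- rep(c(0, 1), 6)
  y2 <- rep(c(0, 0, 1, 1), 3)
  dt2 <- dichotomous_tests(x2, y2)
  expect_equal(dt2$chi2$statistic, 0)
  expect_equal(dt2$chi2$alpha, 1)
  # degenerate margin convention
  dt3 <- dichotomous_tests(rep(1, 8), rnorm(8))
  expect_equal(dt3$chi2$alpha, 1)
  expect_equal(dt3$fisher$alpha, 1)
})

test_that("Fisher exact alpha equals hypergeometric enumeration and fisher.test", {
  set.seed(52)
  for (k in 1:60) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    hx <- factor(x > median(x), c(FALSE, TRUE))
    hy <- factor(y > median(y), c(FALSE, TRUE))
    tab <- table(hx, hy)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- dichotomous_tests(x, y)$fisher$alpha
    expect_equal(got, naive_fisher2x2(tab), tolerance = 1e-10)
    expect_equal(got, fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("applicability criteria flag violated assumptions and pass clean data", {
  # an exact uniform grid passes both uniformity checks
  x <- seq(0, 1, length.out = 20)
  f <- 0.4 * x + seq(-0.01, 0.01, length.out = 20)[order(rnorm(20))]
  ac <- applicability_criteria(x, f)
  expect_named(ac, c("unif_x", "unif_f", "norm_fx", "indep_fx", "norm_xf", "indep_xf"))
  expect_gt(ac$unif_x$alpha, 0.5)
  expect_true(all(vapply(ac, `[[`, character(1), "direction") == "unfavourable"))
  # perfectly linear data passes residual checks by the zero-variance rule
  ac2 <- applicability_criteria(1:10, 2 * (1:10) + 3)
  expect_equal(ac2$norm_fx$alpha, 1)
  expect_equal(ac2$indep_fx$alpha, 1)
  expect_equal(ac2$norm_xf$alpha, 1)
  # strictly alternating residuals around the fit: too many runs
  x3 <- 1:20
  f3 <- x3 + rep(c(0.5, -0.5), 10)
  ac3 <- applicability_criteria(x3, f3)
  # closed-form runs oracle: n1 = n2 = 10, R = 20
  n1 <- 10; n2 <- 10; n <- 20; R <- 20
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  expected <- 2 * pnorm(-abs((R - mu) / sqrt(v)))
  expect_equal(ac3$indep_fx$alpha, max(expected, 1e-10), tolerance = 1e-10)
  expect_lt(ac3$indep_fx$alpha, 0.05)
})

test_that("alphas are uniform or super-uniform under the null", {
  set.seed(63)
  n <- 20; reps <- 2000
  hits <- matrix(0, reps, 5)
  for (r in seq_len(reps)) {
    x <- rnorm(n); y <- rnorm(n)
    hits[r, ] <- c(cor_test_pearson(x, y)$alpha,
                   cor_test_spearman(x, y)$alpha,
                   cor_test_kendall(x, y)$alpha,
                   dichotomous_tests(x, y)$chi2$alpha,
                   dichotomous_tests(x, y)$fisher$alpha) < 0.05
  }
  expect_true(all(colMeans(hits) <= 0.07))
})

test_that("alphas are floored and bounded", {
  x <- 1:30
  r <- cor_test_pearson(x, 3 * x)
  expect_equal(r$alpha, 1e-10)
  expect_lte(cor_test_kendall(x, x + rnorm(30, 0, 1e-3))$alpha, 1)
})
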