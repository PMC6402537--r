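# stats_core: closed-form examples, base-R oracle equivalence on random
# instances, and Monte-Carlo calibration of the tests' error rates.

test_that("kruskal_wallis matches the hand-computed rank-sum example", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12))
  r <- kruskal_wallis(g)
  # ranks 1..12, group mean ranks (2, 5, 8, 11): H = 135/13
  expect_equal(r$statistic, 135 / 13, tolerance = 1e-10)
  expect_equal(r$p, pchisq(135 / 13, 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(r$p, 0.0156, tolerance = 1e-2)
  expect_equal(r$df, 3)
})

test_that("kruskal_wallis handles degenerate input and bad group sizes", {
  r <- kruskal_wallis(list(c(5, 5, 5), c(5, 5), c(5, 5)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  expect_error(kruskal_wallis(list(1, c(1, 2))), "n >= 2")
  expect_error(kruskal_wallis(list(c(1, 2))), ">= 2 groups")
})

test_that("kruskal_wallis agrees with the base-R oracle on random instances", {
  set.seed(42)
  for (i in 1:300) {
    k <- sample(2:5, 1)
    sizes <- sample(3:12, k, replace = TRUE)
    x <- rnorm(sum(sizes))
    if (i %% 3 == 0) x <- round(x, 1)  # force ties
    g <- rep(seq_len(k), sizes)
    ours <- kruskal_wallis(split(x, g))
    ref <- kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("one_way_anova reproduces the eta-squared example and oracle", {
  r <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r$eta_sq, 0.8, tolerance = 1e-12)  # SSB = 4, SST = 5
  expect_equal(r$statistic, 8, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:300) {
    k <- sample(2:5, 1)
    sizes <- sample(3:12, k, replace = TRUE)
    x <- rnorm(sum(sizes), mean = rep(rnorm(k), sizes))
    g <- factor(rep(seq_len(k), sizes))
    ours <- one_way_anova(split(x, g))
    ref <- oneway.test(x ~ g, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_true(ours$eta_sq >= 0 && ours$eta_sq <= 1)
  }
})

test_that("one_way_anova flags degenerate and limiting cases", {
  r <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  expect_equal(r$eta_sq, 0)
  # distinct means with zero within-group variance: eta^2 -> 1
  r2 <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(r2$eta_sq, 1)
  expect_equal(r2$p, 0)
})

test_that("eta squared under permuted labels matches its null expectation", {
  # E[eta^2] under exchangeable labels is (k - 1) / (n - 1), not 0
  set.seed(44)
  x <- rnorm(120)
  etas <- replicate(400, {
    g <- sample(rep(1:4, 30))
    one_way_anova(split(x, g))$eta_sq
  })
  expect_equal(mean(etas), 3 / 119, tolerance = 0.25)
})

test_that("bonferroni applies strict inequality at alpha / m", {
  expect_true(bonferroni(0.001, m = 38))      # 0.001 < 0.05/38
  expect_false(bonferroni(0.0014, m = 38))    # just above 0.05/38
  expect_equal(bonferroni(c(0.04, 0.06)), c(FALSE, FALSE))
  expect_true(bonferroni(0.04, m = 1))        # m = 1 reduces to raw alpha
  expect_false(bonferroni(0.05 / 7, m = 7))   # boundary: not significant
})

test_that("chi_square_proportions matches the closed 2x2 form and oracle", {
  r <- chi_square_proportions(80, 100, 60, 100)
  expect_equal(r$statistic, 200 / 21, tolerance = 1e-10)  # = 9.5238
  expect_equal(r$p, 0.0020, tolerance = 0.05)
  ref <- prop.test(c(80, 60), c(100, 100), correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  # identical proportions
  r0 <- chi_square_proportions(30, 60, 30, 60)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # zero-margin table
  rz <- chi_square_proportions(0, 50, 0, 50)
  expect_true(rz$degenerate)
  expect_equal(rz$p, 1)
})

test_that("chi-square type I error is calibrated near alpha", {
  set.seed(45)
  rej <- mean(replicate(800, {
    chi_square_proportions(rbinom(1, 500, 0.5), 500,
                           rbinom(1, 500, 0.5), 500)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("pearson_r basics, affine invariance, and null sampling bound", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  set.seed(46)
  expect_lt(abs(pearson_r(rnorm(10000), rnorm(10000))), 0.04)
  expect_warning(r <- pearson_r(x, rep(1, 6)), "zero-variance")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "n must be >= 3")
})
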