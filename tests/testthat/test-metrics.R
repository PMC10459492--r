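test_that("VAF identities and derived values hold", {
  y <- c(1, 2, 3)
  expect_equal(vaf(y, y), 100)
  expect_equal(vaf(y, rep(mean(y), 3)), 0)
  expect_equal(vaf(y, y + 7), 100)                 # offset-blind
  # direct arithmetic: var(y - yhat) = var(c(0,0,-2)) = 4/3, var(y) = 1
  expect_equal(vaf(c(1, 2, 3), c(1, 2, 5)), 100 * (1 - (4 / 3) / 1))
  expect_equal(vaf(c(1, 2, 3), c(1, 2, 5)), -33.333, tolerance = 1e-4)
  expect_error(vaf(c(1, 1), c(1, 2)), "zero")
  expect_error(vaf(1:3, 1:4), "length")
  # invariance to prediction offset and common positive rescaling
  set.seed(21)
  y <- rnorm(50); yh <- y + rnorm(50, 0, 0.3)
  expect_equal(vaf(y, yh), vaf(y, yh + 3.7))
  expect_equal(vaf(y, yh), vaf(2.5 * y, 2.5 * yh))
})

test_that("RMSE identities hold", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(22)
  y <- rnorm(30); yh <- rnorm(30)
  expect_equal(rmse(-2 * y, -2 * yh), 2 * rmse(y, yh))
  expect_equal(rmse(y + 1, yh + 1), rmse(y, yh))
})

test_that("table summaries use mean and population standard deviation", {
  tab <- data.frame(participant = 1:3, model = "M", horizon = 1,
                    vaf = c(90, 92, 94), rmse = c(0.2, 0.2, 0.2))
  s <- summarize_metrics(tab)
  expect_equal(s$vaf_mean, 92)
  expect_equal(s$vaf_std, sqrt(mean((c(90, 92, 94) - 92)^2)))
  expect_equal(s$rmse_std, 0)
  one <- summarize_metrics(tab[1, ])
  expect_equal(one$vaf_std, 0)
})

test_that("summaries reproduce every Average/Std cell of the reference tables", {
  # printed values; per-participant inputs are printed at 2 decimals, so
  # recomputed 4-decimal cells can drift by rounding propagation (< 0.002)
  exp1 <- list(
    LASSO = c(0.2555, 93.10, 0.0377, 2.5237),
    MLP = c(0.2840, 91.89, 0.0414, 3.0615),
    GP = c(0.3528, 87.12, 0.0452, 3.3915),
    SVR = c(0.3167, 89.57, 0.0457, 3.0731),
    XGBoost = c(0.3357, 88.14, 0.0566, 4.2675),
    `JADE-STACK` = c(0.2509, 94.50, 0.0407, 1.5273),
    `DE-STACK` = c(0.2571, 92.92, 0.0440, 2.9279),
    `GA-STACK` = c(0.2500, 93.33, 0.0408, 2.6421),
    `PSO-STACK` = c(0.2556, 92.94, 0.0483, 3.2360),
    `NARMAX-HNN` = c(NA, 92.33, NA, 1.4935),
    `NARMAX-P` = c(NA, 93.91, NA, 1.5458),
    Volterra_1 = c(NA, 42.84, NA, 13.7891),
    Volterra_2 = c(NA, 46.20, NA, 7.8842))
  exp3 <- list(
    LASSO = c(0.5688, 66.69, 0.0727, 7.6288),
    MLP = c(0.6541, 59.39, 0.0779, 9.6891),
    GP = c(0.6214, 60.47, 0.0690, 7.6575),
    SVR = c(0.6120, 61.69, 0.0730, 7.7109),
    XGBoost = c(0.6315, 58.68, 0.0840, 11.3155),
    `JADE-STACK` = c(0.5625, 67.50, 0.0680, 7.4431),
    `DE-STACK` = c(0.5637, 65.63, 0.0931, 8.5171),
    `GA-STACK` = c(0.5621, 66.52, 0.0723, 6.9528),
    `PSO-STACK` = c(0.5698, 66.53, 0.0746, 8.7289),
    `NARMAX-HNN` = c(NA, 69.3520, NA, 11.2907),
    `NARMAX-P` = c(NA, 47.09, NA, 13.2842))
  for (h in c(1L, 3L)) {
    s <- summarize_metrics(eeg_results_fixture(h))
    ex <- if (h == 1L) exp1 else exp3
    for (m in names(ex)) {
      r <- s[s$model == m, ]
      e <- ex[[m]]
      if (!is.na(e[1])) expect_lt(abs(r$rmse_mean - e[1]), 0.002)
      expect_lt(abs(r$vaf_mean - e[2]), 0.0051)
      if (!is.na(e[3])) expect_lt(abs(r$rmse_std - e[3]), 0.002)
      expect_lt(abs(r$vaf_std - e[4]), 0.002)
    }
  }
})

test_that("relative improvement is a plain percent ratio", {
  expect_equal(relative_improvement(90, 90), 0)
  expect_equal(relative_improvement(110, 100), 10)
  expect_error(relative_improvement(1, 0), "baseline")
})

test_that("the Friedman statistic follows the mean-rank formula", {
  m <- matrix(rnorm(4), nrow = 4, ncol = 3)  # identical columns: all ties
  expect_equal(friedman_test(m)$statistic, 0)
  m2 <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), nrow = 3, byrow = TRUE)
  # perfectly ordered 3x3: FD = n (k - 1) = 6
  fr <- friedman_test(m2)
  expect_equal(fr$statistic, 6)
  expect_equal(fr$df, 2)
  expect_error(friedman_test(m2[, 1:2]), "more than two")
})

test_that("identical columns carry no rank information", {
  m <- matrix(5, nrow = 4, ncol = 3) + matrix(rnorm(4), 4, 3)
  expect_equal(friedman_test(m)$statistic, 0)
})

test_that("friedman_test agrees with the base-R implementation on random matrices", {
  set.seed(23)
  for (i in 1:8) {
    m <- matrix(rnorm(20), nrow = 5, ncol = 4)
    expect_equal(friedman_test(m)$statistic,
                 unname(stats::friedman.test(m)$statistic))
    expect_equal(friedman_test(m)$p.value,
                 unname(stats::friedman.test(m)$p.value))
  }
})

test_that("rank statistics are invariant to monotone per-block transforms", {
  set.seed(24)
  m <- matrix(rnorm(24), nrow = 4)
  f1 <- friedman_test(m)$statistic
  f2 <- friedman_test(exp(m))$statistic
  m3 <- t(apply(m, 1, function(r) r^3))
  expect_equal(friedman_test(m3)$statistic, f1)
  expect_equal(f2, f1)
})

test_that("the published Friedman statistics are reproduced from the fixtures", {
  c1 <- published_comparison(1)
  expect_equal(c1$friedman$k, 11)
  expect_equal(c1$friedman$df, 10)
  expect_lt(abs(c1$friedman$statistic - 93.29), 0.05)
  expect_lt(c1$friedman$p.value, 1e-10)
  c3 <- published_comparison(3)
  expect_equal(c3$friedman$k, 9)
  expect_lt(abs(c3$friedman$statistic - 42.98), 0.05)
})

test_that("Nemenyi critical difference matches its closed form and table values", {
  # k = 2 limit: q / sqrt(2) is the two-sided normal quantile 1.960
  n2 <- nemenyi_cd(k = 2, n = 25)
  expect_equal(n2$q / sqrt(2), qnorm(0.975), tolerance = 1e-4)
  expect_equal(n2$cd, 1.960 * sqrt(1 / 25), tolerance = 1e-3)
  # independent studentized-range table: q(0.05; k = 11, df = inf) = 4.55
  n11 <- nemenyi_cd(k = 11, n = 10)
  expect_equal(n11$q, 4.55, tolerance = 0.005)
  expect_equal(n11$cd, 4.55 / sqrt(2) * sqrt(11 * 12 / 60), tolerance = 0.005)
  # CD shrinks as blocks accumulate
  cds <- vapply(c(5, 10, 20, 40), function(n) nemenyi_cd(k = 6, n = n)$cd,
                numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_error(nemenyi_cd(k = 6, n = 10, alpha = 1.2), "alpha")
})

test_that("Nemenyi pairwise matrix flags mean-rank gaps beyond the CD", {
  set.seed(25)
  m <- cbind(rnorm(10), rnorm(10) + 3, rnorm(10) + 6)
  fr <- friedman_test(m)
  ne <- nemenyi_cd(fr)
  expect_true(ne$significant[1, 3])
  expect_false(any(diag(ne$significant)))
  expect_equal(ne$significant, t(ne$significant))
})

test_that("residual whiteness accepts Gaussian noise and rejects structure", {
  set.seed(26)
  pvals <- replicate(100, residual_whiteness(rnorm(1e4))$p.value)
  expect_gte(mean(pvals > 0.01), 0.95)
  ramp <- residual_whiteness(seq(0, 1, length.out = 5000))
  expect_lt(ramp$p.value, 0.01)
  k <- residual_whiteness(rnorm(50))$statistic
  expect_gte(k, 0)
  expect_lte(k, 1)
  expect_error(residual_whiteness(rep(1, 20)), "degenerate")
  expect_error(residual_whiteness(rnorm(5)), "at least 10")
})
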