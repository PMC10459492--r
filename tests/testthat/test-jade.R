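test_that("population initialisation is uniform within the box", {
  set.seed(1)
  pop <- jadestack:::init_population(c(2), c(4), 50L)
  expect_true(all(pop >= 2 & pop <= 4))
  set.seed(2)
  pop <- jadestack:::init_population(-1, 3, 10000L)
  # Monte-Carlo oracle: mean of U(-1, 3) is 1
  expect_lt(abs(mean(pop) - 1), 0.05)
})

test_that("mutation-factor sampling resamples non-positive and truncates at 1", {
  expect_equal(jadestack:::jade_sample_F(0.5, draws = 1.7), 1)
  expect_equal(jadestack:::jade_sample_F(0.5, draws = c(-0.2, 0.3)), 0.3)
  # Monte-Carlo oracle: independent Cauchy sampler with the same
  # resample/truncate rules
  set.seed(3)
  draws <- replicate(1e5, jadestack:::jade_sample_F(0.9))
  expect_true(all(draws > 0 & draws <= 1))
  set.seed(4)
  oracle <- rcauchy(4e5, 0.9, 0.1)
  oracle <- pmin(oracle[oracle > 0], 1)
  expect_lt(abs(median(draws) - median(oracle)), 0.01)
  expect_gte(median(draws), 0.80)
  expect_lte(median(draws), 1.00)
})

test_that("crossover-probability sampling clips Normal draws into [0,1]", {
  expect_equal(jadestack:::jade_sample_CR(0.5, draw = 1.3), 1)
  expect_equal(jadestack:::jade_sample_CR(0.5, draw = -0.1), 0)
  set.seed(5)
  draws <- replicate(1e5, jadestack:::jade_sample_CR(0.5))
  expect_lt(abs(mean(draws) - 0.5), 0.01)  # symmetric clipping keeps the mean
})

test_that("current-to-pbest mutation and midpoint bound repair follow their formulas", {
  xi <- c(0, 0)
  expect_equal(jadestack:::pbest_mutant(xi, c(1, 1), c(2, 0), c(0, 2), 0), xi)
  expect_equal(jadestack:::pbest_mutant(xi, c(1, 1), c(2, 0), c(0, 2), 0.5),
               c(1.5, -0.5))
  # hand oracle: midpoint between violated bound and parent coordinate
  expect_equal(jadestack:::midpoint_repair(1.3, 0.9, 0, 1), (1 + 0.9) / 2)
  expect_equal(jadestack:::midpoint_repair(-0.4, 0.2, 0, 1), (0 + 0.2) / 2)
  expect_equal(jadestack:::midpoint_repair(0.5, 0.9, 0, 1), 0.5)
})

test_that("binomial crossover takes mutant coordinates at rand <= CR or j_rand", {
  target <- c(10, 20, 30)
  mutant <- c(1, 2, 3)
  expect_equal(jadestack:::binomial_crossover(target, mutant, 1,
                                              jrand = 2, u = runif(3)),
               mutant)
  u0 <- c(0.5, 0.5, 0.5)
  expect_equal(jadestack:::binomial_crossover(target, mutant, 0,
                                              jrand = 2, u = u0),
               c(10, 2, 30))
  # scripted-RNG oracle
  expect_equal(jadestack:::binomial_crossover(target, mutant, 0.5,
                                              jrand = 2,
                                              u = c(0.2, 0.9, 0.4)),
               c(1, 2, 3))
})

test_that("adaptive location parameters blend Lehmer and arithmetic means", {
  expect_equal(jadestack:::update_mu_lehmer(0.5, numeric(0), 0.1), 0.5)
  expect_equal(jadestack:::update_mu_lehmer(0.5, 0.5, 0.1), 0.5)
  expect_equal(jadestack:::update_mu_lehmer(0.5, c(1, 0.5), 0.1),
               0.9 * 0.5 + 0.1 * (1.25 / 1.5))
  expect_equal(jadestack:::update_mu_arith(0.5, numeric(0), 0.1), 0.5)
  expect_equal(jadestack:::update_mu_arith(0.7, c(0.2, 0.4), 1), 0.3)
  expect_equal(jadestack:::update_mu_arith(0.5, 0.9, 0.1), 0.54)
})

test_that("archive trimming caps cardinality by uniform random removal", {
  a <- matrix(seq_len(26), ncol = 2)
  expect_identical(jadestack:::trim_archive(a, 13L), a)
  set.seed(6)
  tr <- jadestack:::trim_archive(rbind(a, matrix(100 + 1:6, ncol = 2)), 13L)
  expect_equal(nrow(tr), 13L)
  expect_true(all(tr[, 1] %in% c(a[, 1], 100 + 1:3)))
  set.seed(7); t1 <- jadestack:::trim_archive(a, 5L)
  set.seed(7); t2 <- jadestack:::trim_archive(a, 5L)
  expect_identical(t1, t2)
})

test_that("JADE minimises the sphere and keeps its contracts", {
  lower <- rep(-5, 2); upper <- rep(5, 2)
  violated <- FALSE
  sphere <- function(x) {
    if (any(x < lower - 1e-9 | x > upper + 1e-9)) violated <<- TRUE
    sum(x^2)
  }
  fit <- jade(sphere, lower, upper, np = 20, generations = 100, seed = 1)
  expect_lt(fit$value, 1e-6)
  expect_false(violated)  # every evaluated candidate satisfied the bounds
  expect_equal(fit$evaluations, 20 * 101)
  expect_true(all(diff(fit$history$best) <= 0))  # monotone best-so-far
  expect_true(all(fit$history$mu_F >= 0 & fit$history$mu_F <= 1))
  expect_true(all(fit$history$mu_CR >= 0 & fit$history$mu_CR <= 1))
  expect_true(all(fit$history$archive_size <= 20))
  fit2 <- jade(sphere, lower, upper, np = 20, generations = 100, seed = 1)
  expect_identical(fit$history, fit2$history)  # seeded determinism
})

test_that("constant objectives give a flat history and adaptation can be frozen", {
  fit <- jade(function(x) 7, c(0, 0), c(1, 1), np = 10, generations = 20,
              seed = 2)
  expect_true(all(fit$history$best == 7))
  frozen <- jade(function(x) sum(x^2), c(-1, -1), c(1, 1), np = 10,
                 generations = 30, c = 0, seed = 3)
  expect_true(all(frozen$history$mu_F == 0.5))
  expect_true(all(frozen$history$mu_CR == 0.5))
})

test_that("integer dimensions are rounded at evaluation time", {
  expect_equal(jadestack:::round_half_away(c(2.5, -2.5, 0.4)), c(3, -3, 0))
  f <- function(x) (x - 3.4)^2
  fit <- jade(f, 0, 10, np = 15, generations = 40, integer = TRUE, seed = 4)
  # brute force over the integers 0..10: 3 minimises (x - 3.4)^2
  expect_equal(fit$par, 3)
  expect_equal(fit$value, f(3))
})

test_that("non-finite objective values are treated as worst, not fatal", {
  f <- function(x) if (x[1] > 0) NaN else sum(x^2)
  fit <- jade(f, c(-2, -2), c(2, 2), np = 12, generations = 40, seed = 5)
  expect_true(is.finite(fit$value))
  expect_lte(fit$par[1], 0)
})

test_that("classic DE (rand/1/bin) converges, is deterministic, and errors on bad input", {
  fit <- de_classic(function(x) sum(x^2), rep(-5, 2), rep(5, 2), np = 30,
                    generations = 150, seed = 1)
  expect_lt(fit$value, 1e-4)
  expect_true(all(diff(fit$history$best) <= 0))
  fit2 <- de_classic(function(x) sum(x^2), rep(-5, 2), rep(5, 2), np = 30,
                     generations = 150, seed = 1)
  expect_identical(fit$history, fit2$history)
  expect_error(de_classic(function(x) x, 1, 0), "bounds")
  expect_error(jade(function(x) x, 0, 1, np = 3), "at least 4")
})

test_that("maximisation mirrors minimisation with a non-decreasing history", {
  fit <- jade(function(x) -sum((x - 0.3)^2), c(-1, -1), c(1, 1), np = 15,
              generations = 60, maximize = TRUE, seed = 6)
  expect_true(all(diff(fit$history$best) >= 0))
  expect_lt(sum((fit$par - 0.3)^2), 1e-4)
})
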