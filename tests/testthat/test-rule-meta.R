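test_that("constant targets give a single constant rule", {
  x <- matrix(runif(60), ncol = 2)
  m <- cubist_rules(x, rep(4.2, 30))
  expect_equal(length(m$members[[1]]$rules), 1L)
  expect_equal(unname(predict(m, x)), rep(4.2, 30))
  cf <- m$members[[1]]$rules[[1]]$coef
  expect_true(all(cf[-1] == 0))
})

test_that("an exactly linear target is recovered by the rule model", {
  set.seed(31)
  x <- matrix(runif(400), ncol = 2)
  y <- 3 * x[, 1] + 1
  m <- cubist_rules(x, y)
  expect_lt(rmse(y, predict(m, x)), 0.02 * sd(y))
})

test_that("piecewise structure yields several rules and small held-out error", {
  set.seed(32)
  x <- matrix(runif(2000, -1, 1), ncol = 2)
  y <- ifelse(x[, 1] < 0, x[, 1], 2 * x[, 1]) + rnorm(1000, 0, 0.02)
  m <- cubist_rules(x, y)
  expect_gte(length(m$members[[1]]$rules), 2L)
  ho <- matrix(runif(600, -1, 1), ncol = 2)
  y_ho <- ifelse(ho[, 1] < 0, ho[, 1], 2 * ho[, 1])
  expect_lt(rmse(y_ho, predict(m, ho)), 0.05)
})

test_that("committees = 0 and committees = 1 are the same single member", {
  set.seed(33)
  x <- matrix(runif(300), ncol = 3)
  y <- x[, 1] - 2 * x[, 2] + rnorm(100, 0, 0.05)
  m0 <- cubist_rules(x, y, committees = 0)
  m1 <- cubist_rules(x, y, committees = 1)
  expect_equal(predict(m0, x), predict(m1, x))
  expect_equal(length(m0$members), 1L)
})

test_that("a perfect first member makes later committee members identical", {
  set.seed(34)
  x <- matrix(runif(300), ncol = 2)
  y <- rep(2, 150)  # member 1 is exact, so every pseudo-target equals y
  m <- cubist_rules(x, y, committees = 4)
  preds <- vapply(m$members, function(rm)
    jadestack:::predict_rule_model(rm, x), numeric(150))
  expect_equal(preds[, 1], preds[, 2])
  expect_equal(preds[, 1], preds[, 4])
})

test_that("committees do not hurt held-out error on noisy piecewise data", {
  err1 <- err5 <- numeric(10)
  for (s in 1:10) {
    set.seed(400 + s)
    x <- matrix(runif(600, -1, 1), ncol = 2)
    y <- ifelse(x[, 1] < 0, -x[, 1], 2 * x[, 1]) + rnorm(300, 0, 0.1)
    ho <- matrix(runif(400, -1, 1), ncol = 2)
    y_ho <- ifelse(ho[, 1] < 0, -ho[, 1], 2 * ho[, 1])
    err1[s] <- rmse(y_ho, predict(cubist_rules(x, y, committees = 1), ho))
    err5[s] <- rmse(y_ho, predict(cubist_rules(x, y, committees = 5), ho))
  }
  expect_lte(mean(err5), mean(err1) + 0.02)
})

test_that("neighbors = 0 returns the committee average exactly", {
  set.seed(35)
  x <- matrix(runif(200), ncol = 2)
  y <- x[, 1] + rnorm(100, 0, 0.05)
  m <- cubist_rules(x, y, committees = 3, neighbors = 5)
  P <- vapply(m$members, function(rm) jadestack:::predict_rule_model(rm, x),
              numeric(100))
  expect_equal(predict(m, x, neighbors = 0), rowMeans(P))
})

test_that("a training-row query with one neighbor blends its own target", {
  set.seed(36)
  x <- matrix(runif(200), ncol = 2)
  y <- 2 * x[, 1] + rnorm(100, 0, 0.2)
  m <- cubist_rules(x, y, neighbors = 0)
  q <- x[17, , drop = FALSE]
  mq <- predict(m, q, neighbors = 0)
  # the adjustment y_n + m(x) - m(x_n) collapses to y_n at distance zero
  expect_equal(unname(predict(m, q, neighbors = 1)),
               unname(0.5 * (mq + y[17])))
})

test_that("the neighbor correction matches a direct reimplementation", {
  set.seed(37)
  x <- matrix(runif(160), ncol = 2)
  y <- x[, 1] - x[, 2] + rnorm(80, 0, 0.1)
  m <- cubist_rules(x, y, committees = 2)
  newx <- matrix(runif(20), ncol = 2)
  for (k in c(2, 5)) {
    got <- predict(m, newx, neighbors = k)
    # independent oracle: recompute from the stored training state
    mq <- predict(m, newx, neighbors = 0)
    xs_tr <- m$train_x_std
    xs_new <- scale(newx, m$center, m$scale)
    want <- numeric(nrow(newx))
    for (i in seq_len(nrow(newx))) {
      d <- sqrt(colSums((t(xs_tr) - xs_new[i, ])^2))
      nn <- order(d)[seq_len(k)]
      v <- y[nn] + mq[i] - m$train_pred[nn]
      w <- 1 / (d[nn] + 0.5)
      want[i] <- 0.5 * (mq[i] + sum(w * v) / sum(w))
    }
    expect_equal(unname(got), want)
  }
})

test_that("an oversized neighbor count is clamped with a message", {
  x <- matrix(runif(24), ncol = 2)
  y <- x[, 1] + x[, 2]
  m <- cubist_rules(x, y, min_leaf = 2)
  expect_message(p <- predict(m, x[1:2, ], neighbors = 20), "clamped")
  expect_true(all(is.finite(p)))
})

test_that("fitted models are total on finite inputs", {
  set.seed(38)
  x <- matrix(rnorm(300), ncol = 3)
  y <- sin(x[, 1]) + 0.2 * x[, 2]^2 + rnorm(100, 0, 0.1)
  m <- cubist_rules(x, y, committees = 3, neighbors = 4)
  probe <- matrix(rnorm(60, sd = 25), ncol = 3)  # far outside training
  expect_true(all(is.finite(predict(m, probe))))
})

test_that("hyperparameters outside their boxes are rejected", {
  x <- matrix(runif(40), ncol = 2)
  y <- x[, 1]
  expect_error(cubist_rules(x, y, committees = 61), "committees")
  expect_error(cubist_rules(x, y, neighbors = 21), "neighbors")
})

test_that("rules export as readable text blocks", {
  set.seed(39)
  x <- matrix(runif(2000, -1, 1), ncol = 2)
  y <- ifelse(x[, 1] < 0, x[, 1], 3 * x[, 1]) + rnorm(1000, 0, 0.02)
  m <- cubist_rules(x, y)
  txt <- rules_text(m)
  expect_true(any(grepl("^== member 1 ==$", txt)))
  expect_true(any(grepl("cover \\d+", txt)))
  expect_true(any(grepl("(<=|>)", txt)))
})

test_that("an external backend drives fitting and prediction unchanged", {
  stub <- list(
    fit = function(x, y, committees) {
      cf <- stats::lm.fit(cbind(1, x), y)$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    predict = function(object, newdata, neighbors)
      drop(cbind(1, newdata) %*% object$coef))
  set.seed(40)
  x <- matrix(runif(200), ncol = 2)
  y <- 1 + x[, 1] - x[, 2]
  m <- cubist_rules(x, y, committees = 7, neighbors = 3, backend = stub)
  expect_lt(max(abs(predict(m, x) - y)), 1e-8)
  # the tuner runs against the backend seam too
  tm <- tune_meta(x, y, folds = rep(1:2, 50), tuner = "jade", np = 4,
                  generations = 2, committees_max = 5, neighbors_max = 2,
                  backend = stub, seed = 1)
  expect_gte(tm$cv_vaf, 99.99)
  expect_true(tm$committees %in% 0:5)
})
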