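test_that("one component recovers an exactly linear response", {
  set.seed(1)
  X <- cbind(a = rnorm(10))
  y <- 2 * X[, "a"] + 1
  fit <- fit_pls(X, y, 1)
  expect_equal(predict(fit, X), y, tolerance = 1e-10)
  st <- fit_statistics(fit, X, y)
  expect_equal(st$r2, 1.0, tolerance = 1e-10)
})

test_that("full-rank PLS equals the ordinary least-squares fit", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 8; p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_pls(X, y, p)
    ols <- stats::lm.fit(cbind(1, X), y)  # independent oracle
    expect_equal(predict(fit, X), unname(ols$fitted.values), tolerance = 1e-8)
  }
})

test_that("a constant response yields an intercept-only model", {
  X <- matrix(rnorm(12), 6, 2)
  fit <- suppressWarnings(fit_pls(X, rep(3.5, 6), 2))
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(predict(fit, X), rep(3.5, 6))
  # zero-variance input row predicts the training mean
  set.seed(3)
  y <- rnorm(6)
  fit2 <- fit_pls(X, y, 2)
  expect_equal(predict(fit2, fit2$xbar), mean(y))
})

test_that("LOO predictions match a per-fold regression oracle", {
  # single descriptor: PLS with 1 component is simple linear regression,
  # so each fold can be checked against lm() refit by hand
  X <- matrix(c(1, 2, 3, 5), ncol = 1)
  y <- c(1.1, 1.9, 3.2, 4.8)
  cv <- loo_crossvalidate(X, y, max_components = 1)
  press_oracle <- sum(vapply(1:4, function(i) {
    f <- stats::lm(yy ~ xx, data.frame(xx = X[-i, 1], yy = y[-i]))
    (y[i] - stats::predict(f, data.frame(xx = X[i, 1])))^2
  }, numeric(1)))
  expect_equal(cv$press[1], press_oracle, tolerance = 1e-10)
  sst_oracle <- sum(vapply(1:4, function(i) (y[i] - mean(y[-i]))^2, numeric(1)))
  expect_equal(cv$q2[1], 1 - press_oracle / sst_oracle, tolerance = 1e-10)
  expect_equal(cv$sep[1], sqrt(press_oracle / (4 - 1 - 1)), tolerance = 1e-10)
})

test_that("q2 approaches 1 for a noiseless linear response", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, -2, 0.5)
  cv <- loo_crossvalidate(X, drop(y), max_components = 3)
  expect_gte(max(cv$q2), 0.999)
})

test_that("q2 stays low when the response is pure noise", {
  set.seed(5)
  q2s <- vapply(1:25, function(r) {
    X <- matrix(rnorm(12 * 4), 12, 4)
    y <- rnorm(12)
    max(loo_crossvalidate(X, y, max_components = 2)$q2)
  }, numeric(1))
  expect_lt(stats::median(q2s), 0.2)
})

test_that("q2 never exceeds r2 on the same training data", {
  set.seed(6)
  for (rep in 1:10) {
    X <- matrix(rnorm(14 * 5), 14, 5)
    y <- drop(X %*% rnorm(5)) + rnorm(14, 0, 0.5)
    cv <- loo_crossvalidate(X, y, max_components = 4)
    for (k in cv$n_components) {
      fit <- fit_pls(X, y, k)
      st <- fit_statistics(fit, X, y)
      expect_lte(cv$q2[k], st$r2 + 1e-10)
    }
  }
})

test_that("adding a pure-noise column does not inflate q2", {
  set.seed(7)
  gains <- vapply(1:20, function(r) {
    X <- matrix(rnorm(15 * 3), 15, 3)
    y <- drop(X %*% c(1, 1, -1)) + rnorm(15, 0, 0.3)
    base <- max(loo_crossvalidate(X, y, max_components = 3)$q2)
    aug <- max(loo_crossvalidate(cbind(X, rnorm(15)), y, max_components = 3)$q2)
    aug - base
  }, numeric(1))
  expect_lt(stats::quantile(gains, 0.9), 0.05)
})

test_that("component selection follows the stated policies", {
  curve <- data.frame(n_components = 1:5,
                      q2 = c(0.2, 0.5, 0.49, 0.5, 0.3))
  expect_identical(select_components(curve), 2L)  # tie broken small
  curve2 <- data.frame(n_components = 1:5,
                       q2 = c(0.2, 0.50, 0.49, 0.52, 0.53))
  expect_identical(select_components(curve2), 5L)
  expect_identical(select_components(curve2, policy = "parsimony", tol = 0.05),
                   2L)
  rising <- data.frame(n_components = 1:8, q2 = seq(0.1, 0.8, 0.1))
  expect_identical(select_components(rising, cap = 4L), 4L)
})

test_that("fit statistics agree with explicit sum-of-squares arithmetic", {
  set.seed(8)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- drop(X %*% c(1, 2)) + rnorm(10, 0, 0.2)
  fit <- fit_pls(X, y, 2)
  st <- fit_statistics(fit, X, y)
  yhat <- predict(fit, X)
  ssr <- sum((y - yhat)^2); sst <- sum((y - mean(y))^2)
  expect_equal(st$r2, 1 - ssr / sst)
  expect_equal(st$see, sqrt(ssr / (10 - 2 - 1)))
  expect_equal(st$f_value, ((sst - ssr) / 2) / (ssr / 7))
  expect_error(fit_statistics(fit, X[1:3, ], y[1:3]), "degrees of freedom")
})

test_that("external Q2 has its fixed points and hand-checked value", {
  y <- c(0.2, 0.5, 0.9)
  expect_equal(external_q2(y, y, 0.4)$q2_ext, 1.0)
  expect_equal(external_q2(y, rep(0.4, 3), 0.4)$q2_ext, 0.0)
  # 3-point toy by hand: PRESS = 0.01+0.04+0.01, SS = 0.04+0.01+0.25
  out <- external_q2(c(0.2, 0.5, 0.9), c(0.3, 0.7, 1.0), 0.4)
  expect_equal(out$q2_ext, 1 - 0.06 / 0.30, tolerance = 1e-12)
  expect_equal(out$r2_pred, stats::cor(c(0.2, 0.5, 0.9), c(0.3, 0.7, 1.0))^2)
  expect_error(external_q2(c(0.4, 0.4), c(0.1, 0.2), 0.4), "variance")
})

test_that("progressive scrambling collapses q2 and has unit slope on linear data", {
  set.seed(9)
  X <- matrix(rnorm(16 * 4), 16, 4)
  y <- drop(X %*% c(1, -1, 0.5, 0.2)) + rnorm(16, 0, 0.1)
  ps <- progressive_scrambling(X, y, n_components = 2, reps = 10,
                               levels = 5, seed = 21)
  cv <- loo_crossvalidate(X, y, max_components = 2)
  expect_equal(ps$q2_0, cv$q2[2], tolerance = 1e-10)  # zero perturbation
  full <- ps$table[ps$table$level == 1, ]
  expect_lt(mean(full$q2), 0.3)        # full permutation collapses q2
  expect_lt(mean(full$r2_yy), 0.3)
  expect_gt(ps$dq2_dr2yy, 0.6)         # stability slope near 1
  expect_lt(ps$dq2_dr2yy, 1.4)
  expect_error(progressive_scrambling(X, y, reps = 5), "reps")
})

test_that("field contributions split as the coefficient mass dictates", {
  pipe <- synthetic_pipeline()
  fc <- field_contributions(pipe$fit, pipe$table)
  expect_equal(sum(fc), 100, tolerance = 0.01)
  expect_identical(names(fc), c("steric", "electrostatic"))
  # duplicated blocks share the mass equally
  tab2 <- pipe$table
  ns <- sum(tab2$columns$field == "steric")
  Xs <- tab2$X[, tab2$columns$field == "steric", drop = FALSE]
  tab2$X <- cbind(Xs, Xs)
  tab2$columns <- data.frame(
    field = rep(c("steric", "electrostatic"), each = ns),
    point = rep(tab2$columns$point[tab2$columns$field == "steric"], 2))
  fit2 <- fit_pls(tab2$X, tab2$y, 2)
  fc2 <- field_contributions(fit2, tab2)
  expect_equal(unname(fc2["steric"]), 50, tolerance = 1e-6)
})

test_that("splits are seeded, exhaustive, and keep the template in both roles", {
  ids <- sprintf("c%02d", 1:29)
  s1 <- make_split(ids, train_size = 22, seed = 5, template = "c18")
  s2 <- make_split(ids, train_size = 22, seed = 5, template = "c18")
  expect_identical(s1, s2)
  expect_length(s1$train, 22L)
  expect_setequal(union(s1$train, s1$test), ids)
  expect_true("c18" %in% s1$train && "c18" %in% s1$test)
  s3 <- make_split(ids, train_size = 28, seed = 1)
  expect_length(s3$test, 1L)
  expect_error(make_split(ids, train_size = 29), "train_size")
})
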