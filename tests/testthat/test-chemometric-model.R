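test_that("correlation matrix matches the brute-force pairwise formula", {
  d <- fruit_dataset("x", L = c(10, 20, 30, 40, 50, 60),
                     a = c(1, 3, 2, 5, 4, 6), b = c(9, 7, 8, 5, 6, 4),
                     content = c(100, 140, 120, 180, 160, 190))
  m <- correlation_matrix(d)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= -1 & m <= 1))

  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  cols <- list(content = d$content, L = d$L, a = d$a, b = d$b)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(m[i, j], pearson(cols[[i]], cols[[j]]), tolerance = 1e-12)
  }
})

test_that("correlation matrix flags exact dependence and independence", {
  L <- seq(1, 50)
  d <- fruit_dataset("x", L = L, a = rnorm(50), b = rnorm(50), content = 2 * L)
  expect_equal(correlation_matrix(d)["content", "L"], 1)

  set.seed(23)
  n <- 10000
  d2 <- fruit_dataset("x", L = runif(n, 0, 100), a = rnorm(n), b = rnorm(n),
                      content = rnorm(n))
  m <- correlation_matrix(d2)
  expect_lt(max(abs(m[upper.tri(m)])), 0.05)

  d3 <- fruit_dataset("x", L = rep(50, 6), a = rnorm(6), b = rnorm(6),
                      content = rnorm(6))
  expect_error(correlation_matrix(d3), "constant column.*L")
})

test_that("normal equations reproduce the univariate quadratic layout", {
  # exact linear points (0,2), (1,5), (2,8): quadratic fit A x^2 + B x + C
  x <- c(0, 1, 2); y <- c(2, 5, 8)
  design <- cbind(x^2, x, 1)
  sol <- solve_normal_equations(design, y)
  expect_equal(unname(sol$coefficients), c(0, 3, 2), tolerance = 1e-10)
})

test_that("constant response with an intercept gives the pure-intercept solution", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(40), ncol = 4))
  sol <- solve_normal_equations(X, rep(7.5, 10))
  expect_equal(unname(sol$coefficients), c(7.5, 0, 0, 0, 0), tolerance = 1e-10)
})

test_that("normal-equations solver agrees with an independent least-squares oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:200, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), ncol = p - 1))
    y <- rnorm(n, sd = 3)
    sol <- solve_normal_equations(X, y)
    oracle <- qr.coef(qr(X), y)  # QR decomposition, not normal equations
    expect_equal(unname(sol$coefficients), unname(oracle), tolerance = 1e-8)
    expect_equal(sol$xtx_inverse %*% crossprod(X), diag(p), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("rank-deficient designs raise a singular-system error", {
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(solve_normal_equations(X, rnorm(10)), "rank deficient")
  expect_error(solve_normal_equations(matrix(1:6, ncol = 3), rnorm(2)),
               "at least as many rows")
})

test_that("the color model recovers exact coefficients on noiseless data", {
  spec <- make_spec(true_coefficients = c(10, 1, -2, 0.5), noise_sd = 0,
                    seed = 2)
  fit <- fit_linear_model(generate_fruit_dataset(spec))
  expect_equal(unname(coef(fit)), c(10, 1, -2, 0.5), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$dof, 41L)
})

test_that("pure-noise responses give near-zero R^2 at large n", {
  set.seed(13)
  n <- 5000
  d <- fruit_dataset("x", L = runif(n, 0, 100), a = rnorm(n, sd = 3),
                     b = rnorm(n, sd = 3), content = rnorm(n, 100, 10))
  expect_lt(fit_linear_model(d)$r_squared, 0.01)
})

test_that("OLS identities hold: residuals sum to zero, mean maps to mean", {
  spec <- make_spec(noise_sd = 50, seed = 17)
  d <- generate_fruit_dataset(spec)
  fit <- fit_linear_model(d)
  expect_lt(abs(sum(residuals(fit))), 1e-8 * sqrt(sum(d$content^2)))
  pred_at_mean <- suppressWarnings(
    predict_content(fit, mean(d$L), mean(d$a), mean(d$b)))
  expect_equal(pred_at_mean, mean(d$content), tolerance = 1e-10)
})

test_that("R^2 never decreases when a predictor is added on the same rows", {
  set.seed(41)
  n <- 30
  L <- runif(n, 0, 100); a <- rnorm(n, sd = 4); y <- 5 + 0.2 * L + rnorm(n)
  r2_of <- function(X) {
    b <- solve_normal_equations(X, y)$coefficients
    1 - sum((y - X %*% b)^2) / sum((y - mean(y))^2)
  }
  expect_gte(r2_of(cbind(1, L, a)) + 1e-12, r2_of(cbind(1, L)))
})

test_that("coefficient recovery from noisy fixture stays within 3 standard errors", {
  spec <- make_spec(noise_sd = 50, seed = 1)
  fit <- fit_linear_model(generate_fruit_dataset(spec))
  se <- sqrt(fit$pii * fit$s2)
  expect_true(all(abs(coef(fit) - blackberry_tac_truth) <= 3 * se))
})

test_that("t statistics match the reference linear-model implementation", {
  set.seed(55)
  d <- fruit_dataset("x", L = runif(20, 0, 100), a = rnorm(20, sd = 4),
                     b = rnorm(20, sd = 4),
                     content = 100 + 2 * runif(20, 0, 1) + rnorm(20, sd = 5))
  fit <- fit_linear_model(d)
  tt <- coefficient_t_statistics(fit)
  ref <- summary(lm(content ~ L + a + b, data = as.data.frame(d)))$coefficients
  expect_equal(tt$estimate, unname(ref[, "Estimate"]), tolerance = 1e-10)
  expect_equal(tt$t, unname(ref[, "t value"]), tolerance = 1e-10)
  expect_equal(tt$p, unname(ref[, "Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("t statistics on a hand-computed 6-row instance", {
  d <- fruit_dataset("x", L = c(12, 25, 37, 51, 66, 80),
                     a = c(2, -1, 4, 0, 3, -2), b = c(5, 8, 2, 9, 4, 7),
                     content = c(30, 52, 71, 95, 120, 151))
  fit <- fit_linear_model(d)
  X <- cbind(1, d$L, d$a, d$b); y <- d$content
  binv <- solve(t(X) %*% X)
  bhat <- binv %*% t(X) %*% y
  s2 <- sum((y - X %*% bhat)^2) / 2
  t_oracle <- drop(bhat) / sqrt(diag(binv) * s2)
  expect_equal(coefficient_t_statistics(fit)$t, t_oracle, tolerance = 1e-10)
})

test_that("exact fits flag infinite (or zero) t rather than failing", {
  set.seed(61)
  d <- fruit_dataset("x", L = c(10, 20, 30, 40, 55, 70), a = rnorm(6),
                     b = rnorm(6), content = 3 + 2 * c(10, 20, 30, 40, 55, 70))
  fit <- fit_linear_model(d)
  expect_lt(fit$s2, 1e-18)
  # force the exactly-zero residual-variance branch
  fit$s2 <- 0
  fit$coefficients[3:4] <- 0
  tt <- coefficient_t_statistics(fit)
  expect_true(all(is.infinite(tt$t[tt$estimate != 0])))
  expect_true(all(tt$t[tt$estimate == 0] == 0))
  expect_true(all(tt$p[tt$estimate == 0] == 1))
})

test_that("residual filtering keeps clean rows and drops a gross outlier", {
  spec <- make_spec(noise_sd = 0, seed = 30)
  d <- generate_fruit_dataset(spec)
  fit <- fit_linear_model(d)
  rep0 <- filter_by_residuals(fit, d)
  expect_equal(rep0$kept_indices, 1:45)  # all residuals zero
  expect_length(rep0$dropped_indices, 0)

  spec2 <- make_spec(noise_sd = 50, seed = 30)
  d2 <- generate_fruit_dataset(spec2)
  rep_big_k <- filter_by_residuals(fit_linear_model(d2), d2, k = 1e6)
  expect_equal(rep_big_k$kept_indices, 1:45)

  # one injected 10-sigma outlier is exactly what gets dropped
  d3 <- d2
  d3$content[17] <- d3$content[17] + 10 * 50
  fit3 <- fit_linear_model(d3)
  rep3 <- filter_by_residuals(fit3, d3)
  expect_equal(rep3$dropped_indices, 17L)
  expect_setequal(union(rep3$kept_indices, rep3$dropped_indices), 1:45)
  expect_length(intersect(rep3$kept_indices, rep3$dropped_indices), 0)

  expect_error(filter_by_residuals(fit3, d3, k = 0), "k")
  expect_error(filter_by_residuals(fit3, d3, k = -2), "k")
})

test_that("refitting after filtering improves recovery of the truth", {
  spec <- make_spec(noise_sd = 50, seed = 30)
  d <- generate_fruit_dataset(spec)
  d$content[c(5, 23)] <- d$content[c(5, 23)] + c(10, -12) * 50
  fit0 <- fit_linear_model(d)
  report <- filter_by_residuals(fit0, d)
  refit <- refit_filtered(d, report)
  err0 <- sqrt(sum((coef(fit0) - blackberry_tac_truth)^2))
  err1 <- sqrt(sum((coef(refit) - blackberry_tac_truth)^2))
  expect_lt(err1, err0)
  expect_equal(refit$n_used, length(report$kept_indices))
  expect_identical(refit$provenance$filter, report)

  # nothing dropped -> refit is the identity on coefficients
  clean <- generate_fruit_dataset(make_spec(noise_sd = 0, seed = 30))
  fit_c <- fit_linear_model(clean)
  rep_c <- filter_by_residuals(fit_c, clean)
  expect_equal(coef(refit_filtered(clean, rep_c)), coef(fit_c))
})

test_that("prediction evaluates the linear polynomial and flags negatives", {
  expect_equal(predict_content(c(42, 0, 0, 0), L = 55, a = -3, b = 12), 42)
  expect_equal(predict_content(c(1, 2, 3, 4), L = 1, a = 1, b = 1), 10)
  expect_warning(p <- predict_content(c(-100, 0, 0, 0), L = 1, a = 1, b = 1),
                 "negative")
  expect_equal(p, -100)  # unclamped
  expect_error(predict_content(c(1, 2, 3), L = 1, a = 1, b = 1), "length 4")
})

test_that("fits with fewer than five rows are refused", {
  d <- fruit_dataset("x", L = c(1, 2, 3, 4), a = rnorm(4), b = rnorm(4),
                     content = rnorm(4))
  expect_error(fit_linear_model(d), "at least 5 rows")
})
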