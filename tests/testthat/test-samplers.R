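test_that("moment-based sampling reproduces degenerate and exact cases", {
  X <- sample_from_moments(c(a = 5, b = -2), matrix(0, 2, 2), n = 7, seed = 1)
  expect_equal(unname(X), matrix(rep(c(5, -2), each = 7), 7))
  expect_identical(colnames(X), c("a", "b"))
  expect_identical(sample_from_moments(c(a = 0), diag(1), 10, seed = 3),
                   sample_from_moments(c(a = 0), diag(1), 10, seed = 3))
})

test_that("moment-based sampling converges to its moments", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  X <- sample_from_moments(c(a = 0, b = 0), S, n = 1e5, seed = 2)
  v <- apply(X, 2, var)
  expect_true(all(v > 0.98 & v < 1.02))
  expect_lt(abs(cov(X)[1, 2] - 0.4), 0.02)
  # convergence rate ~ 1/sqrt(n): the small-n moment error is larger
  Xs <- sample_from_moments(c(a = 0, b = 0), S, n = 400, seed = 2)
  err_small <- abs(var(Xs[, 1]) - 1)
  err_big <- abs(v[1] - 1)
  expect_lt(err_big, err_small + 0.02)
})

test_that("indefinite covariances are caught with the offending eigenvalue", {
  S <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sample_from_moments(c(a = 0, b = 0), S, 10, seed = 1),
               "not positive semi-definite.*-1")
  # a numerically indefinite matrix is projected, not rejected
  S2 <- matrix(c(1, 1, 1, 1), 2) - diag(1e-10, 2)
  expect_silent(sample_from_moments(c(a = 0, b = 0), S2, 5, seed = 1))
})

test_that("affine calibration matches reported moments exactly", {
  set.seed(5)
  base <- cbind(u = rnorm(200), v = runif(200))
  cal <- calibrate_sampler(base, target_mean = c(u = 10, v = 0),
                           target_var = c(u = 4, v = 1))
  out <- apply_calibration(base, cal)
  expect_equal(unname(colMeans(out)), c(10, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out, 2, var)), c(4, 1), tolerance = 1e-12)
  expect_equal(cor(base[, "u"], base[, "v"], method = "spearman"),
               cor(out[, "u"], out[, "v"], method = "spearman"))
  # identity transform when targets equal base moments
  cal0 <- calibrate_sampler(base, target_mean = colMeans(base),
                            target_var = apply(base, 2, var))
  expect_equal(unname(cal0$shift), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(cal0$scale), c(1, 1), tolerance = 1e-12)
  # closed form on standardized input
  z <- cbind(a = as.numeric(scale(rnorm(100))))
  calz <- calibrate_sampler(z, c(a = 10), c(a = 4))
  expect_equal(unname(calz$scale), 2, tolerance = 1e-10)
  expect_equal(unname(calz$shift), 10, tolerance = 1e-10)
  expect_error(calibrate_sampler(cbind(c = rep(1, 10)), c(c = 0), c(c = 1)),
               "zero variance")
})

test_that("measurement noise is scaled, isolated, and seed-stable", {
  set.seed(8)
  X <- cbind(a = rnorm(1e5, sd = 3), b = rnorm(1e5))
  expect_identical(add_measurement_noise(X, c(a = 0), seed = 1), X)
  out <- add_measurement_noise(X, c(a = 0.5), seed = 2)
  expect_identical(out[, "b"], X[, "b"])
  out1 <- add_measurement_noise(X, c(a = 1), seed = 3)
  ratio <- var(out1[, "a"] - X[, "a"]) / var(X[, "a"])
  expect_lt(abs(ratio - 1), 0.03)
  expect_error(add_measurement_noise(X, c(zz = 0.1)), "unknown column")
  expect_error(add_measurement_noise(X, c(a = -0.1)), "non-negative")
})

test_that("study moments pool across overlapping covariate subsets", {
  s1 <- prior_study("a", 50, "ols", covariate_subset = c("x1", "x2"),
                    covariate_moments = list(mean = c(x1 = 0, x2 = 0),
                                             cov = diag(2)))
  s2 <- prior_study("b", 50, "ols", covariate_subset = c("x2", "x3"),
                    covariate_moments = list(
                      mean = c(x2 = 2, x3 = 1),
                      cov = matrix(c(2, 0.5, 0.5, 1), 2,
                                   dimnames = list(c("x2", "x3"), c("x2", "x3")))))
  pooled <- pool_study_moments(list(s1, s2), c("x1", "x2", "x3"))
  expect_equal(unname(pooled$mean), c(0, 1, 1))       # x2 averaged over studies
  expect_equal(pooled$cov["x2", "x2"], 1.5)           # averaged variance
  expect_equal(pooled$cov["x2", "x3"], 0.5)           # only study b reports it
  expect_equal(pooled$cov["x1", "x3"], 0)             # never co-observed
  expect_error(pool_study_moments(list(s1), c("x1", "x4")), "x4")
})
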