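test_that("OLS replicator matches hand-computed normal equations", {
  X <- cbind(x = c(0, 1, 2))
  r <- ols_signatures(X, c(1, 3, 5), "x", include = c("coefs", "mse", "r2"))
  expect_equal(unname(r$signatures), c(1, 2, 0, 1), tolerance = 1e-12)
  r2 <- ols_signatures(X, c(1, 3, 6), "x", include = c("coefs", "mse"))
  expect_equal(unname(r2$signatures), c(5 / 6, 5 / 2, 1 / 6), tolerance = 1e-12)
  expect_identical(names(r2$signatures), c("intercept", "b:x", "mse"))
  # constant outcome: zero slope, R-squared defined as 0
  rc <- ols_signatures(X, c(2, 2, 2), "x", include = c("coefs", "r2"))
  expect_equal(unname(rc$signatures), c(2, 0, 0))
  # n-denominator option
  rn <- ols_signatures(X, c(1, 3, 6), "x", include = "mse", mse_df = "n")
  expect_equal(unname(rn$signatures), 1 / 18, tolerance = 1e-12)
})

test_that("rank-deficient OLS designs do not converge silently", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  r <- ols_signatures(X, rnorm(4), c("a", "b"))
  expect_false(r$converged)
  expect_null(r$signatures)
  expect_match(r$notes, "rank")
})

test_that("logistic replicator solves the saturated 2x2 closed form", {
  X <- cbind(x = rep(c(0, 1), each = 20))
  y <- c(rep(1, 10), rep(0, 10), rep(1, 15), rep(0, 5))
  r <- logistic_signatures(X, y, "x")
  expect_equal(unname(r$signatures), c(0, log(3)), tolerance = 1e-6)
  # independence: slope near zero at large n
  set.seed(1)
  Xn <- cbind(x = rnorm(1e4))
  yn <- rbinom(1e4, 1, 0.5)
  rn <- logistic_signatures(Xn, yn, "x")
  expect_lt(abs(rn$signatures[["b:x"]]), 0.06)
  # relabeling equivariance
  set.seed(2)
  X2 <- cbind(a = rnorm(80), b = rnorm(80))
  y2 <- rbinom(80, 1, plogis(X2[, 1] - X2[, 2]))
  rab <- logistic_signatures(X2, y2, c("a", "b"))$signatures
  rba <- logistic_signatures(X2, y2, c("b", "a"))$signatures
  expect_equal(rab[["b:a"]], rba[["b:a"]], tolerance = 1e-8)
  expect_equal(rab[["b:b"]], rba[["b:b"]], tolerance = 1e-8)
})

test_that("separation and one-class outcomes are flagged, never zero-filled", {
  X <- cbind(x = c(-2, -1, 1, 2))
  expect_false(logistic_signatures(X, c(0, 0, 1, 1), "x")$converged)
  r1 <- logistic_signatures(X, rep(1, 4), "x")
  expect_false(r1$converged)
  expect_null(r1$signatures)
})

test_that("replicators agree with textbook implementations on random data", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(20:40, 1)
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    y <- 0.5 + X[, 1] - 0.5 * X[, 2] + rnorm(n)
    ours <- ols_signatures(X, y, c("x1", "x2"), include = "coefs")$signatures
    expect_equal(unname(ours), oracle_ols(X, y), tolerance = 1e-8)
    yb <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1]))
    rb <- logistic_signatures(X, yb, c("x1", "x2"))
    if (rb$converged) {
      expect_equal(unname(rb$signatures), oracle_logit(X, yb), tolerance = 1e-8)
    }
  }
})

test_that("percentile discretization uses the left-closed convention", {
  lev <- discretize(1:100, c(33, 66))
  expect_equal(as.vector(table(lev)), c(33, 33, 34))
  expect_equal(discretize(c(1, 2, 3, 4), 50), c(1, 1, 2, 2))
  # rank invariance under a monotone transform
  set.seed(3)
  v <- rnorm(97)
  expect_identical(discretize(v, c(25, 50, 75)), discretize(exp(v), c(25, 50, 75)))
  expect_error(discretize(rep(1, 10), 50), "identical")
  expect_error(discretize(1:10, c(60, 40)))
})

test_that("one-way ANOVA signatures reproduce the classical table", {
  y <- rep(c(0, 1, 2), each = 4)
  X <- cbind(f = rep(c(10, 20, 30), each = 4))
  r <- anova_signatures(X, y, list(list(column = "f", cutpoints = c(33, 66))))
  s <- r$signatures
  expect_equal(s[["grand_mean"]], 1)
  expect_equal(unname(s[grep("^eff:", names(s))]), c(-1, 0, 1))
  expect_equal(s[["mse"]], 0)
  expect_equal(s[["mst:f"]], 4)  # = sum n_j (m_j - gm)^2 / (k - 1) = 8 / 2
  # constant outcome: everything collapses to the mean
  rc <- anova_signatures(X, rep(7, 12), list(list(column = "f", cutpoints = c(33, 66))))
  expect_equal(unname(rc$signatures), c(7, 0, 0, 0, 0, 0))
})

test_that("one-way ANOVA agrees with stats::aov on random unbalanced data", {
  set.seed(9)
  X <- cbind(x = rnorm(83))
  y <- 1 + X[, 1] + rnorm(83)
  r <- anova_signatures(X, y, list(list(column = "x", cutpoints = c(33, 66))))
  g <- factor(discretize(X[, "x"], c(33, 66)))
  a <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(r$signatures[["mst:x"]], a["g", "Mean Sq"], tolerance = 1e-10)
  expect_equal(r$signatures[["mse"]], a["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("two-factor additive ANOVA yields the published signature inventory", {
  set.seed(10)
  X <- cbind(x1 = rnorm(100), x2 = rnorm(100))
  y <- 1 + X[, 1] + X[, 2] + X[, 1] * X[, 2] + rnorm(100)
  facs <- list(list(column = "x1", cutpoints = c(33, 66)),
               list(column = "x2", cutpoints = c(25, 50, 75)))
  r <- anova_signatures(X, y, facs)
  expect_equal(length(r$signatures), 11)  # 1 + 3 + 4 + 2 MST + 1 MSE
  # sum-to-zero coding of the level effects
  expect_equal(sum(r$signatures[grep("^eff:x1", names(r$signatures))]), 0,
               tolerance = 1e-10)
  expect_equal(sum(r$signatures[grep("^eff:x2", names(r$signatures))]), 0,
               tolerance = 1e-10)
  # sequential mean squares match the classical lm ANOVA table
  f1 <- factor(discretize(X[, "x1"], c(33, 66)))
  f2 <- factor(discretize(X[, "x2"], c(25, 50, 75)))
  a <- stats::anova(stats::lm(y ~ f1 + f2))
  expect_equal(r$signatures[["mst:x1"]], a["f1", "Mean Sq"], tolerance = 1e-10)
  expect_equal(r$signatures[["mst:x2"]], a["f2", "Mean Sq"], tolerance = 1e-10)
  expect_equal(r$signatures[["mse"]], a["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("ANOVA replication on matching zero-noise data returns the truth", {
  # a purely additive group-mean structure is recovered exactly
  set.seed(11)
  g <- sample(1:3, 90, replace = TRUE)
  X <- cbind(x = c(-2, 0, 2)[g] + runif(90, -0.4, 0.4))
  y <- c(5, 7, 9)[discretize(X[, "x"], c(33, 66))]
  r <- anova_signatures(X, y, list(list(column = "x", cutpoints = c(33, 66))))
  expect_equal(r$signatures[["mse"]], 0, tolerance = 1e-20)
})

test_that("effect-size packaging and between-study statistics", {
  sigs <- effect_size_signatures(c(0.1, 0.3, 0.5), c(0.01, 0.02, 0.01))
  expect_length(sigs, 3)
  expect_equal(sum(lengths(sigs)), 6)
  expect_identical(names(sigs[[1]]), c("effect", "within_var"))
  expect_error(effect_size_signatures(numeric(0), numeric(0)), "no effect sizes")
  expect_error(effect_size_signatures(0.3, 0), "positive")
  expect_equal(sum(lengths(effect_size_signatures(rnorm(5), rep(1, 5)))), 10)

  spec <- between_study_spec(v = list(stat = "var", label = "effect"))
  expect_equal(unname(between_study_statistics(sigs, spec)), 0.04)
  same <- effect_size_signatures(rep(0.2, 4), rep(1, 4))
  expect_equal(unname(between_study_statistics(same, spec)), 0)
  expect_error(between_study_statistics(sigs[1], spec), "single study")
  bad <- between_study_spec(v = list(stat = "var", label = "nope"))
  expect_error(between_study_statistics(sigs, bad), "absent")
})

test_that("study declarations validate signature labels and sample size", {
  expect_error(prior_study("s", 2, "ols", covariate_subset = c("x1", "x2")),
               "below the dimension")
  expect_error(prior_study("s", 50, "ols", covariate_subset = "x1",
                           empirical_signatures = c(wrong = 1)),
               "do not match")
  st <- prior_study("s", 50, "anova",
                    options = list(factors = list(
                      list(column = "x1", cutpoints = c(33, 66)),
                      list(column = "x2", cutpoints = c(25, 50, 75)))))
  expect_length(study_signature_labels(st), 11)
})
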