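# A small shared fit: two mis-specified single-predictor OLS studies of the
# two-predictor linear truth (6 signatures, 4 parameters, 2 dof).
fix_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- fix_linear_model()
      s1 <- fix_ols_study("a", n = 80, subset = "x1", seed = 31)
      s2 <- fix_ols_study("b", n = 80, subset = "x2", seed = 32)
      cache <<- list(model = m, studies = list(s1, s2),
                     fit = gma_fit(m, list(s1, s2), plan = fix_fast_plan(seed = 6)))
    }
    cache
  }
})

test_that("the signature Jacobian is the identity map for full OLS coefficients", {
  m0 <- polynomial_meta_model(list(character(0), "x1", "x2"),
                              predictors = c("x1", "x2"))
  st <- fix_ols_study(include = c("coefs", "mse"))
  beta <- c(b0 = 1, b_x1 = 0.5, b_x2 = -0.5, sigma = 1)
  D <- gma_jacobian(m0, beta, list(st), fix_fast_plan(seed = 3))
  cf <- 1:3  # intercept and two coefficient rows; columns b0, b_x1, b_x2
  expect_equal(unname(D[cf, cf]), diag(3), tolerance = 1e-6)
  expect_equal(attr(D, "rank"), 4L)
  # halving the step barely changes the smooth-surface derivative
  D2 <- gma_jacobian(m0, beta, list(st), fix_fast_plan(seed = 3), rel_step = 5e-4)
  expect_lt(max(abs(D2[cf, cf] - D[cf, cf])), 0.01)
})

test_that("signatures insensitive to a parameter trigger an identification warning", {
  m <- polynomial_meta_model(list(character(0), "x1"), predictors = c("x1", "x2"),
                             extra_params = "ghost")
  st <- fix_ols_study(subset = "x1", include = "coefs")
  expect_warning(
    D <- gma_jacobian(m, c(b0 = 1, b_x1 = 1, sigma = 1, ghost = 0),
                      list(st), fix_fast_plan(seed = 3)),
    "ghost")
  expect_equal(unname(D[, "ghost"]), rep(0, nrow(D)))
})

test_that("the parameter covariance is the simulated-moments sandwich", {
  set.seed(12)
  D <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("p1", "p2")))
  Sg <- crossprod(matrix(rnorm(60), 10, 6))
  W <- solve(Sg)
  V <- parameter_covariance(D, W, Sg)
  # at the efficient weighting the sandwich collapses to (D' Sigma^-1 D)^-1
  expect_equal(V, solve(crossprod(D, W %*% D)), tolerance = 1e-8)
  # homogeneity: scaling the signature covariance scales the parameter covariance
  V2 <- parameter_covariance(D, solve(3 * Sg), 3 * Sg)
  expect_equal(V2, 3 * V, tolerance = 1e-8)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_error(parameter_covariance(cbind(D[, 1], D[, 1]), W, Sg), "singular")
})

test_that("goodness of fit behaves at its edge cases", {
  f <- fix_small_fit()$fit
  fake <- f
  fake$e[] <- 0
  a <- chi0_statistic(fake)
  expect_equal(a$chi0, 0)
  expect_equal(a$p_value, 1)
  expect_equal(a$dof, 2)
  # the simulation prefactor S/(1+S) approaches 1
  fake$e[] <- f$e
  a1 <- chi0_statistic(fake)
  fake$S_final <- 1e9
  a2 <- chi0_statistic(fake)
  expect_gt(a2$chi0, a1$chi0)
  expect_equal(a2$chi0 / a1$chi0, (1e9 / (1e9 + 1)) / (60 / 61), tolerance = 1e-9)
  # diagonal-weight fits carry no chi-square statistic
  noW <- f
  attr(noW$W, "provenance") <- "initial-diagonal"
  expect_error(chi0_statistic(noW), "rounds >= 2")
})

test_that("goodness of fit is invariant to a signature's units", {
  # reporting a signature in different units scales its error and its
  # row/column of the signature covariance together; the weighted
  # quadratic form is unchanged
  f <- fix_small_fit()$fit
  sc <- rep(1, length(f$e)); sc[3] <- 10
  f2 <- f
  f2$e <- f$e * sc
  Sg2 <- diag(sc) %*% f$Sigma_hat %*% diag(sc)
  f2$W <- chol2inv(chol(Sg2 + 1e-8 * diag(diag(Sg2))))
  attr(f2$W, "provenance") <- "simulated-inverse-covariance"
  base <- f
  base$W <- chol2inv(chol(f$Sigma_hat + 1e-8 * diag(diag(f$Sigma_hat))))
  attr(base$W, "provenance") <- "simulated-inverse-covariance"
  expect_equal(chi0_statistic(f2)$chi0, chi0_statistic(base)$chi0,
               tolerance = 1e-6)
})

test_that("the model selection criterion penalizes parameters", {
  expect_equal(msc(10, 3), 16)
  expect_lt(msc(5, 2), msc(5, 3))
  expect_error(msc(NaN, 2))
})

test_that("Wald tests are centered and sign-symmetric", {
  f <- fix_small_fit()$fit
  at_hat <- wald_test(f, c(b_x1 = 1), null_value = f$beta_hat[["b_x1"]])
  expect_equal(at_hat$statistic, 0)
  expect_equal(at_hat$p_value, 1)
  wplus <- wald_test(f, c(b_x1 = 1, b_x2 = -1), 0)
  wminus <- wald_test(f, c(b_x1 = -1, b_x2 = 1), 0)
  expect_equal(wplus$p_value, wminus$p_value)
  expect_equal(wplus$statistic, -wminus$statistic)
  expect_error(wald_test(f, c(nope = 1)), "unknown parameter")
})

test_that("parametric bootstrap intervals bracket the estimate", {
  f <- fix_small_fit()$fit
  bs <- bootstrap_ci(f, B = 40, seed = 9)
  expect_identical(dim(bs$draws), c(40L, 4L))
  est <- f$beta_hat
  expect_true(all(bs$intervals[, 1] <= est + 1e-8))
  expect_true(all(bs$intervals[, 2] >= est - 1e-8))
  # spread roughly consistent with the analytical standard errors
  expect_equal(unname(apply(bs$draws, 2, sd) / f$se), rep(1, 4), tolerance = 0.6)
})

test_that("leave-one-study-out needs enough studies and reports dof changes", {
  fx <- fix_small_fit()
  expect_error(loo_influence(fx$model, fx$studies[1], plan = fix_fast_plan()),
               "at least two")
  tab <- loo_influence(fx$model, fx$studies, plan = fix_fast_plan(seed = 6),
                       fit = fx$fit)
  expect_identical(sort(tab$study_id), c("a", "b"))
  expect_equal(tab$dof_change, c(3L, 3L))
  # removing a study from a 4-parameter model leaves 3 signatures: refusal
  expect_true(all(!tab$assessable))
})

test_that("confidence intervals shrink with study sample size", {
  m <- fix_linear_model()
  widths <- sapply(c(60, 960), function(n) {
    s1 <- fix_ols_study("a", n = n, subset = "x1", seed = 51)
    s2 <- fix_ols_study("b", n = n, subset = "x2", seed = 52)
    f <- gma_fit(m, list(s1, s2), plan = fix_fast_plan(seed = 6, S_final = 100))
    mean(confint(f)[, 2] - confint(f)[, 1])
  })
  # a 16-fold sample-size increase should shrink widths about 4-fold
  expect_lt(widths[2], widths[1] / 2.5)
})
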