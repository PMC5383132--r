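test_that("signature errors average the simulated replicates", {
  sim <- matrix(c(1, 1, 3, 3), 2, dimnames = list(c("s:a", "s:b"), NULL))
  e <- signature_error(c("s:a" = 2, "s:b" = 2), sim)
  expect_equal(unname(e), c(0, 0))
  sim2 <- matrix(c(0.5, 2.5), 2, dimnames = list(c("s:a", "s:b"), NULL))
  expect_equal(unname(signature_error(c("s:a" = 1, "s:b" = 2), sim2)), c(0.5, -0.5))
  expect_error(signature_error(c("s:a" = 1, "s:zz" = 2), sim), "labels")
})

test_that("the weighted objective is a quadratic form", {
  expect_equal(gma_objective(c(0, 0), diag(2)), 0)
  expect_equal(gma_objective(c(1, 2), diag(2)), 5)
  expect_equal(gma_objective(c(1, 1), diag(c(4, 9))), 13)
  expect_error(gma_objective(c(1, 1), matrix(c(1, 2, 0, 1), 2)), "symmetric")
  # invariant under simultaneous permutation of error and weight
  set.seed(1)
  e <- rnorm(5)
  A <- crossprod(matrix(rnorm(25), 5))
  p <- sample(5)
  expect_equal(gma_objective(e, A), gma_objective(e[p], A[p, p]))
})

test_that("the initial weight matrix follows the reciprocal-square rule", {
  W <- initial_weight(c(a = 2, b = 0.5), floor = 1e-6)
  expect_equal(diag(W), c(a = 0.25, b = 4))
  expect_equal(attr(W, "provenance"), "initial-diagonal")
  W0 <- initial_weight(c(a = 0, b = 1), floor = 1e-6)
  expect_equal(W0[1, 1], 1e12)
  expect_equal(diag(initial_weight(c(a = 1, b = -1), floor = 1e-6)),
               c(a = 1, b = 1))
  # the adaptive floor caps the weight of a near-zero signature
  Wa <- initial_weight(c(a = 1e-5, b = 1, c = 2))
  expect_lt(Wa[1, 1], 1 / (0.05 * 1)^2 + 1e-6)
})

test_that("simulation is deterministic and respects common random numbers", {
  m <- fix_linear_model()
  st <- fix_ols_study()
  plan <- fix_fast_plan(seed = 7)
  beta <- c(b0 = 1, b_x1 = 1, b_x2 = 1, sigma = 1)
  M1 <- simulate_signatures(m, beta, list(st), plan)
  M2 <- simulate_signatures(m, beta, list(st), plan)
  expect_identical(M1, M2)
  expect_identical(dim(M1), c(4L, 20L))
  # zero-noise linear model + full OLS replicator: coefficients exact per replicate
  m0 <- polynomial_meta_model(list(character(0), "x1", "x2"),
                              predictors = c("x1", "x2"), error_sd_param = NULL)
  st0 <- fix_ols_study(include = "coefs")
  M0 <- simulate_signatures(m0, c(b0 = 2, b_x1 = -1, b_x2 = 0.5), list(st0), plan)
  expect_equal(unname(M0), matrix(rep(c(2, -1, 0.5), 20), 3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("simulated signature means approach published values under the truth", {
  beta <- c(b0 = 1, b_x1 = 1, b_x2 = 1, sigma = 1)
  m <- fix_linear_model()
  st <- fix_ols_study(n = 4000, beta = beta, seed = 3)
  M <- simulate_signatures(m, beta, list(st), fix_fast_plan(seed = 8), S = 500)
  dev <- abs(rowMeans(M) - unlist(st$empirical_signatures))
  expect_true(all(dev < 0.15))
})

test_that("weight updating approaches the inverse signature covariance", {
  # two intercept-only OLS studies reporting only their coefficient:
  # var(mean) = sigma^2 / n, designed to give variances 4 and 1
  m <- polynomial_meta_model(list(character(0)), predictors = c("x1"),
                             coef_names = "b0", name = "intercept-only")
  mk <- function(id, n) {
    prior_study(id, n, "ols", covariate_subset = character(),
                empirical_signatures = c(intercept = 0),
                covariate_moments = list(mean = c(x1 = 0),
                                         cov = matrix(1, dimnames = list("x1", "x1"))),
                options = list(include = "coefs"))
  }
  studies <- list(mk("a", 25), mk("b", 100))
  plan <- fix_fast_plan(seed = 2)
  W <- update_weight(m, c(b0 = 0, sigma = 10), studies, plan, n_reps = 4000)
  expect_equal(attr(W, "provenance"), "simulated-inverse-covariance")
  Sg <- attr(W, "Sigma_hat")
  expect_equal(Sg[1, 1], 4, tolerance = 0.15)
  expect_equal(Sg[2, 2], 1, tolerance = 0.15)
  expect_equal(W[1, 1], 0.25, tolerance = 0.2)
  expect_equal(W[2, 2], 1, tolerance = 0.2)
})

test_that("a perfectly collinear signature set cannot be inverted at zero ridge", {
  # a between-study "mean" of a single study's intercept duplicates that
  # signature row exactly
  m <- fix_linear_model()
  st <- fix_ols_study()
  bt <- between_study_spec(m_int = list(stat = "mean", label = "intercept"),
                           empirical = c(m_int = 1))
  plan <- fix_fast_plan(seed = 4)
  beta <- c(b0 = 1, b_x1 = 1, b_x2 = 1, sigma = 1)
  expect_error(update_weight(m, beta, list(st), plan, between = bt,
                             n_reps = 100, ridge = 0), "ridge")
  # the default relative ridge restores invertibility
  W <- update_weight(m, beta, list(st), plan, between = bt, n_reps = 100,
                     ridge = 1e-6)
  expect_true(is.matrix(W))
})

test_that("noiseless exactly identified aggregation recovers the generator", {
  # one study containing every predictor, coefficient signatures produced
  # from a known parameter vector without noise
  m0 <- polynomial_meta_model(list(character(0), "x1", "x2"),
                              predictors = c("x1", "x2"), error_sd_param = NULL)
  truth <- c(b0 = 0.7, b_x1 = -1.2, b_x2 = 2.5)
  set.seed(21)
  X <- cbind(x1 = rnorm(80), x2 = rnorm(80))
  y <- truth[["b0"]] + truth[["b_x1"]] * X[, 1] + truth[["b_x2"]] * X[, 2]
  sig <- ols_signatures(X, y, c("x1", "x2"), include = "coefs")$signatures
  st <- prior_study("all", 80, "ols", covariate_subset = c("x1", "x2"),
                    empirical_signatures = sig,
                    covariate_moments = list(mean = colMeans(X), cov = cov(X)),
                    options = list(include = "coefs"))
  fit <- gma_fit(m0, list(st), plan = fix_fast_plan(seed = 5, rounds = 1),
                 compute_inference = FALSE)
  expect_equal(fit$beta_hat, truth, tolerance = 1e-6)
  expect_lt(fit$objective, 1e-10)
})

test_that("under-identified problems are refused with an explanation", {
  m <- fix_linear_model()  # 4 parameters
  st <- fix_ols_study(include = "coefs")  # 3 signatures
  expect_error(gma_fit(m, list(st), plan = fix_fast_plan()), "under-identified")
})

test_that("efficient weighting does not inflate the estimator's spread", {
  # compare the spread of estimates across replications under the initial
  # diagonal weighting (rounds = 1) and the simulated-inverse-covariance
  # weighting (rounds = 2)
  truth <- c(b0 = 1, b_x1 = 1, b_x2 = 1, sigma = 1)
  m <- fix_linear_model()
  est1 <- est2 <- matrix(NA_real_, 30, 4)
  for (r in 1:30) {
    s1 <- fix_ols_study("a", n = 50, seed = 100 + r, subset = "x1",
                        include = c("coefs", "mse"))
    s2 <- fix_ols_study("b", n = 50, seed = 300 + r, subset = "x2",
                        include = c("coefs", "mse"))
    plan <- fix_fast_plan(seed = r, S = 30, S_final = 30, n_weight_reps = 300)
    f1 <- gma_fit(m, list(s1, s2), plan = plan, rounds = 1, compute_inference = FALSE)
    f2 <- gma_fit(m, list(s1, s2), plan = plan, rounds = 2, compute_inference = FALSE)
    est1[r, ] <- f1$beta_hat
    est2[r, ] <- f2$beta_hat
  }
  spread1 <- mean(apply(est1, 2, sd))
  spread2 <- mean(apply(est2, 2, sd))
  expect_lt(spread2, spread1 * 1.15)
})
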