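# Shared fixtures: small meta-models, studies and plans built in code.

# A linear 2-predictor meta-model y = b0 + b1 x1 + b2 x2 + N(0, sigma)
fix_linear_model <- function() {
  polynomial_meta_model(list(character(0), "x1", "x2"),
                        predictors = c("x1", "x2"), name = "toy linear")
}

# Draw a toy "published" OLS study from the linear truth
fix_ols_study <- function(id = "s1", n = 60, beta = c(b0 = 1, b_x1 = 1, b_x2 = 1, sigma = 1),
                          subset = c("x1", "x2"), seed = 1,
                          include = c("coefs", "mse")) {
  set.seed(seed)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- beta[["b0"]] + beta[["b_x1"]] * X[, 1] + beta[["b_x2"]] * X[, 2] +
    beta[["sigma"]] * rnorm(n)
  sig <- ols_signatures(X, y, subset, include = include)$signatures
  prior_study(id, n, "ols", covariate_subset = subset,
              empirical_signatures = sig,
              covariate_moments = list(mean = colMeans(X), cov = cov(X)),
              options = list(include = include))
}

fix_fast_plan <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(S = 20, S_final = 60, n_weight_reps = 200, seed = seed,
         rounds = 2, n_starts = 1),
    list(...))
  do.call(simulation_plan, args)
}

# Textbook logistic MLE by Newton-Raphson with hand-coded score and
# Hessian — the independent oracle for the package's logistic replicator.
oracle_logit <- function(X, y) {
  Xd <- cbind(1, X)
  b <- rep(0, ncol(Xd))
  for (i in 1:60) {
    p <- 1 / (1 + exp(-drop(Xd %*% b)))
    score <- crossprod(Xd, y - p)
    hess <- crossprod(Xd, Xd * (p * (1 - p)))
    step <- solve(hess, score)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  unname(b)
}

# Textbook OLS via the normal equations — oracle for the OLS replicator.
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  unname(drop(solve(crossprod(Xd), crossprod(Xd, y))))
}
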