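# Meta-model declaration and evaluation: the data-generating process
# y = f(x, eps; beta) whose parameters the aggregation estimator recovers.

#' Declare a meta-model (data-generating process)
#'
#' A meta-model is the candidate data-generating function whose parameters
#' are estimated by matching simulated study signatures against published
#' ones. It couples a deterministic mean function of the covariates with an
#' error model. For continuous outcomes the error is additive normal and its
#' standard deviation is itself an element of the parameter vector (it is
#' estimated, like any other parameter). Binary-outcome models interpret the
#' mean function as `Pr(y = 1)` and carry no error parameter. An optional
#' study-level random-intercept standard deviation supports random-effects
#' meta-models.
#'
#' Meta-models are declared through builders ([polynomial_meta_model()],
#' [logistic_meta_model()], [random_effects_meta_model()]) or directly with
#' a user closure `mean_function(X, beta)` that maps a covariate table and a
#' named parameter vector to one value per row.
#'
#' @param name model label used in reports.
#' @param param_names character vector naming every entry of the parameter
#'   vector, including error-model parameters.
#' @param predictor_names character vector naming the explanatory variables
#'   the mean function reads from the covariate table.
#' @param mean_function function `(X, beta) -> numeric(nrow(X))`; must be
#'   deterministic (pure) in its inputs.
#' @param outcome `"continuous"` or `"binary"`.
#' @param error_sd_param name of the parameter holding the additive-normal
#'   error standard deviation, or `NULL` for a noiseless (or binary) model.
#' @param study_effect_sd_param name of the parameter holding the
#'   between-study random-intercept standard deviation, or `NULL`.
#' @param bounds named list of `c(lower, upper)` per parameter. Scale
#'   parameters default to `(0, Inf)`.
#' @return an object of class `meta_model`.
#' @export
meta_model <- function(name, param_names, predictor_names, mean_function,
                       outcome = c("continuous", "binary"),
                       error_sd_param = NULL, study_effect_sd_param = NULL,
                       bounds = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(is.character(param_names), length(param_names) >= 1,
            is.character(predictor_names), is.function(mean_function))
  if (anyDuplicated(param_names)) {
    stop("param_names must be unique", call. = FALSE)
  }
  if (outcome == "binary" && (!is.null(error_sd_param) || !is.null(study_effect_sd_param))) {
    stop("binary-outcome models carry no error-scale parameters", call. = FALSE)
  }
  for (nm in c(error_sd_param, study_effect_sd_param)) {
    if (!nm %in% param_names) {
      stop(sprintf("error-model parameter '%s' is not in param_names", nm), call. = FALSE)
    }
  }
  b <- resolve_bounds(param_names, bounds)
  for (nm in c(error_sd_param, study_effect_sd_param)) {
    if (is.null(bounds) || !nm %in% names(bounds)) b[, nm] <- c(0, Inf)
  }
  structure(list(
    name = name,
    param_names = param_names,
    predictor_names = predictor_names,
    mean_function = mean_function,
    outcome = outcome,
    error_sd_param = error_sd_param,
    study_effect_sd_param = study_effect_sd_param,
    bounds = b
  ), class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("Meta-model '%s' (%s outcome)\n", x$name, x$outcome))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat("  predictors:", if (length(x$predictor_names)) paste(x$predictor_names, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$error_sd_param)) cat("  error sd parameter:", x$error_sd_param, "\n")
  if (!is.null(x$study_effect_sd_param)) cat("  study-effect sd parameter:", x$study_effect_sd_param, "\n")
  invisible(x)
}

# Term-product mean function shared by the polynomial and logistic builders.
# `terms` is a list of character vectors of predictor names; the empty
# vector denotes the intercept and a repeated name a power (e.g. c("t","t")
# is t^2). Interactions and transforms live inside the mean function so the
# covariate table stays raw and can serve several candidate models.
build_term_function <- function(terms, param_names, link = identity) {
  force(terms); force(param_names); force(link)
  function(X, beta) {
    n <- nrow(X)
    out <- numeric(n)
    for (k in seq_along(terms)) {
      tk <- terms[[k]]
      if (length(tk) == 0) {
        out <- out + beta[[param_names[k]]]
      } else {
        v <- X[, tk[1]]
        if (length(tk) > 1) for (nm in tk[-1]) v <- v * X[, nm]
        out <- out + beta[[param_names[k]]] * v
      }
    }
    as.vector(link(out))
  }
}

default_term_names <- function(terms) {
  vapply(terms, function(tk) {
    if (length(tk) == 0) "b0" else paste0("b_", paste(tk, collapse = "."))
  }, character(1))
}

#' Polynomial (linear-in-parameters) meta-model builder
#'
#' Declares a continuous-outcome meta-model whose mean is a sum of
#' coefficient-weighted products of raw predictors:
#' `c()` is the intercept, `"x1"` a main effect, `c("x1","x2")` an
#' interaction, `c("t","t")` a quadratic term. An additive-normal error term
#' with estimated standard deviation is appended unless
#' `error_sd_param = NULL`.
#'
#' @param terms list of character vectors of predictor names (see above).
#' @param predictors character vector of all predictor names.
#' @param coef_names optional names for the term coefficients (defaults to
#'   `b0`, `b_x1`, `b_x1.x2`, ...).
#' @param error_sd_param name of the error standard-deviation parameter
#'   (default `"sigma"`), or `NULL` for a noiseless model.
#' @param extra_params additional parameter names carried by the model but
#'   not used by the mean function (e.g. measurement-noise fractions).
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param name model label.
#' @return a `meta_model`.
#' @examples
#' m <- polynomial_meta_model(list(character(0), "x1", "x2", c("x1", "x2")),
#'                            predictors = c("x1", "x2"))
#' evaluate_mean(m, c(b0 = 1, b_x1 = 1, b_x2 = 1, b_x1.x2 = 1, sigma = 1),
#'               data.frame(x1 = 2, x2 = 3))  # 12
#' @export
polynomial_meta_model <- function(terms, predictors, coef_names = NULL,
                                  error_sd_param = "sigma",
                                  extra_params = character(),
                                  bounds = NULL, name = "polynomial") {
  coef_names <- coef_names %||% default_term_names(terms)
  stopifnot(length(coef_names) == length(terms))
  params <- c(coef_names, error_sd_param, extra_params)
  meta_model(
    name = name, param_names = params, predictor_names = predictors,
    mean_function = build_term_function(terms, coef_names),
    outcome = "continuous", error_sd_param = error_sd_param, bounds = bounds
  )
}

#' Logistic (binary-outcome) meta-model builder
#'
#' As [polynomial_meta_model()] but the linear predictor is passed through
#' the inverse-logit link and outcomes are Bernoulli draws; no error-scale
#' parameter is carried.
#'
#' @inheritParams polynomial_meta_model
#' @return a `meta_model`.
#' @export
logistic_meta_model <- function(terms, predictors, coef_names = NULL,
                                extra_params = character(),
                                bounds = NULL, name = "logistic") {
  coef_names <- coef_names %||% default_term_names(terms)
  stopifnot(length(coef_names) == length(terms))
  meta_model(
    name = name, param_names = c(coef_names, extra_params),
    predictor_names = predictors,
    mean_function = build_term_function(terms, coef_names, link = stats::plogis),
    outcome = "binary", bounds = bounds
  )
}

#' Normal-normal random-effects meta-model builder
#'
#' Declares the hierarchical data-generating process of classical
#' random-effects meta-analysis: observation `j` of study `l` is
#' `y_lj = mu + b_l + e_lj` with `b_l ~ N(0, tau^2)` shared within a study
#' and `e_lj ~ N(0, sigma^2)` independent. Replicating a prior study then
#' reproduces its reported effect size (the study mean) and within-study
#' variance of the mean.
#'
#' @param mu,tau,sigma parameter names for the summary effect, the
#'   between-study standard deviation, and the within-study residual
#'   standard deviation.
#' @param name model label.
#' @return a `meta_model`.
#' @export
random_effects_meta_model <- function(mu = "mu", tau = "tau", sigma = "sigma",
                                      name = "random-effects") {
  meta_model(
    name = name, param_names = c(mu, tau, sigma),
    predictor_names = character(),
    mean_function = local({
      mu_name <- mu
      function(X, beta) rep(beta[[mu_name]], nrow(X))
    }),
    outcome = "continuous",
    error_sd_param = sigma, study_effect_sd_param = tau
  )
}

#' Evaluate a meta-model's mean function
#'
#' Deterministically evaluates `f(x; beta)` row by row; for binary models the
#' result is the success probability and is checked to lie in `[0, 1]`.
#'
#' @param model a [meta_model()].
#' @param beta named numeric parameter vector (complete).
#' @param X covariate table (data frame or matrix) whose columns include
#'   `model$predictor_names`.
#' @return numeric vector with one value per row of `X`.
#' @export
evaluate_mean <- function(model, beta, X) {
  stopifnot(inherits(model, "meta_model"))
  beta <- check_beta(model, beta)
  X <- check_covariates(model, X)
  out <- model$mean_function(X, beta)
  if (length(out) != nrow(X)) {
    stop("mean_function must return one value per covariate row", call. = FALSE)
  }
  bad <- which(!is.finite(out))
  if (length(bad)) {
    stop(sprintf("mean_function returned a non-finite value at row %d", bad[1]), call. = FALSE)
  }
  if (model$outcome == "binary" && (any(out < 0) || any(out > 1))) {
    stop("binary-outcome mean_function must return probabilities in [0, 1]", call. = FALSE)
  }
  out
}

check_beta <- function(model, beta) {
  if (!is_named_numeric(beta)) stop("beta must be a named numeric vector", call. = FALSE)
  missing <- setdiff(model$param_names, names(beta))
  if (length(missing)) {
    stop(sprintf("beta is missing parameter(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  beta <- beta[model$param_names]
  lo <- model$bounds[1, ]; hi <- model$bounds[2, ]
  viol <- which(beta < lo | beta > hi)
  if (length(viol)) {
    stop(sprintf("parameter '%s' violates its bounds [%g, %g]",
                 model$param_names[viol[1]], lo[viol[1]], hi[viol[1]]), call. = FALSE)
  }
  beta
}

check_covariates <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) stop("X must be a matrix or data frame", call. = FALSE)
  missing <- setdiff(model$predictor_names, colnames(X))
  if (length(missing)) {
    stop(sprintf("covariate table is missing predictor column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X
}

#' Simulate responses from a meta-model
#'
#' Draws one outcome per covariate row: mean plus additive-normal error (and
#' an optional study-level random intercept, drawn once per call) for
#' continuous models, Bernoulli draws at the evaluated probability for
#' binary models. With the error standard deviation equal to zero the output
#' equals [evaluate_mean()] exactly; identical seeds give bit-identical
#' output.
#'
#' @inheritParams evaluate_mean
#' @param seed mandatory integer seed.
#' @return numeric outcome vector of length `nrow(X)`.
#' @export
simulate_response <- function(model, beta, X, seed) {
  stopifnot(inherits(model, "meta_model"))
  if (missing(seed)) stop("seed is mandatory for simulate_response", call. = FALSE)
  beta <- check_beta(model, beta)
  mu <- evaluate_mean(model, beta, X)
  n <- length(mu)
  set.seed(seed)
  if (model$outcome == "binary") {
    return(as.numeric(stats::runif(n) < mu))
  }
  y <- mu
  if (!is.null(model$study_effect_sd_param)) {
    tau <- beta[[model$study_effect_sd_param]]
    if (tau < 0) stop("study-effect standard deviation must be non-negative", call. = FALSE)
    y <- y + tau * stats::rnorm(1)
  }
  if (!is.null(model$error_sd_param)) {
    sd <- beta[[model$error_sd_param]]
    if (sd < 0) stop("error standard deviation must be non-negative", call. = FALSE)
    y <- y + sd * stats::rnorm(n)
  }
  y
}
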