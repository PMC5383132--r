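# Inference on an aggregation fit: signature Jacobian, parameter
# covariance, goodness of fit, model selection, bootstrap intervals, Wald
# tests, and the leave-one-study-out outlier diagnostic.

# Central finite differences of the S-averaged simulated signatures with
# respect to beta, on a fixed common-random-numbers context, so the
# difference quotient differentiates a smooth deterministic surface.
jacobian_from_context <- function(ctx, beta, model, rel_step = 1e-3) {
  p <- length(beta)
  labels <- ctx$stacked_labels
  D <- matrix(NA_real_, length(labels), p, dimnames = list(labels, names(beta)))
  steps <- numeric(p)
  lo <- model$bounds[1, ]; hi <- model$bounds[2, ]
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(beta[j]), 1)
    bp <- beta; bm <- beta
    bp[j] <- min(beta[j] + h, hi[j])
    bm[j] <- max(beta[j] - h, lo[j])
    if (bp[j] == bm[j]) {  # parameter pinned at a point bound
      D[, j] <- 0; steps[j] <- 0; next
    }
    gp <- rowMeans(ctx_signature_matrix(ctx, bp), na.rm = TRUE)
    gm <- rowMeans(ctx_signature_matrix(ctx, bm), na.rm = TRUE)
    D[, j] <- (gp - gm) / (bp[j] - bm[j])
    steps[j] <- h
  }
  zero_cols <- names(beta)[colSums(abs(D)) == 0]
  if (length(zero_cols)) {
    warning(sprintf("signatures are insensitive to parameter(s) %s (identification hazard)",
                    paste(zero_cols, collapse = ", ")), call. = FALSE)
  }
  attr(D, "steps") <- steps
  attr(D, "rank") <- qr(D)$rank
  D
}

#' Jacobian of simulated signatures with respect to parameters
#'
#' Central finite differences of the simulation-averaged signatures around
#' `beta_hat`, evaluated under common random numbers (the same draws on
#' both sides of every difference), with step `rel_step * max(|beta_j|, 1)`
#' per parameter. A parameter to which no signature responds is reported
#' with a warning — it cannot be identified from these studies.
#'
#' @inheritParams simulate_signatures
#' @param beta_hat parameter vector at which to differentiate.
#' @param rel_step relative finite-difference step.
#' @return signature-by-parameter matrix with attributes `steps` and
#'   `rank`.
#' @export
gma_jacobian <- function(model, beta_hat, studies, plan = simulation_plan(),
                         between = NULL, source = NULL, rel_step = 1e-3) {
  beta_hat <- check_beta(model, beta_hat)
  ctx <- build_sim_context(model, studies, plan, S = plan$S,
                           seed = derive_seed(plan$seed, "opt"),
                           between = between, source = source)
  jacobian_from_context(ctx, beta_hat, model, rel_step)
}

#' Parameter covariance of the aggregation estimator
#'
#' The simulated-moments sandwich
#' `(D'WD)^{-1} D'W Sigma W D (D'WD)^{-1}`, scaled by `(1 + 1/S)` to account
#' for the residual simulation noise in the S-averaged signatures. At the
#' efficient weighting `W = solve(Sigma)` this reduces to
#' `(D' solve(Sigma) D)^{-1}`.
#'
#' @param D signature Jacobian (rows = signatures, columns = parameters).
#' @param W weight matrix used at the optimum.
#' @param Sigma_hat estimated covariance of the signature estimators at the
#'   studies' actual sample sizes.
#' @param S simulation replicates behind the final error evaluation
#'   (`Inf` for the pure asymptotic formula).
#' @return symmetric positive semi-definite parameter covariance matrix.
#' @export
parameter_covariance <- function(D, W, Sigma_hat, S = Inf) {
  G <- crossprod(D, W %*% D)
  Ginv <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(Ginv)) {
    ev <- eigen(G, symmetric = TRUE)
    pn <- colnames(D) %||% paste0("parameter ", seq_len(ncol(D)))
    worst <- pn[which.max(abs(ev$vectors[, which.min(ev$values)]))]
    stop(sprintf(paste("D'WD is singular: the signature set cannot identify the",
                       "parameter combination dominated by '%s'"), worst), call. = FALSE)
  }
  B <- crossprod(D, W %*% Sigma_hat %*% W %*% D)
  V <- Ginv %*% B %*% Ginv * (1 + 1 / S)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(D), colnames(D))
  V
}

#' Goodness of fit of an aggregation fit
#'
#' The simulation-corrected quadratic form
#' `chi0 = S/(1+S) * t(e) W* e` at the optimum, where `W*` is the inverse
#' covariance of the signature estimators at the studies' actual sample
#' sizes (estimated by simulation). Under the hypothesis that the
#' meta-model is the true data-generating process, `chi0` asymptotically
#' follows a chi-square distribution with
#' `dof = n_signatures - n_parameters` degrees of freedom. Because the
#' studies' heterogeneous sample sizes are absorbed into `W*`, no separate
#' sample-size factor appears. Also returns the model-selection criterion
#' ([msc()]).
#'
#' @param fit a [gma_fit()] whose final weight matrix has provenance
#'   `"simulated-inverse-covariance"`.
#' @return list with `chi0`, `dof`, `p_value` (`NA` for a saturated model
#'   with `dof = 0`), and `msc`.
#' @export
chi0_statistic <- function(fit) {
  stopifnot(inherits(fit, "gma_fit"))
  prov <- attr(fit$W, "provenance") %||% "user"
  if (!identical(prov, "simulated-inverse-covariance")) {
    stop("chi0 requires the simulated-inverse-covariance weight matrix; fit with rounds >= 2",
         call. = FALSE)
  }
  S <- fit$S_final
  chi0 <- S / (1 + S) * gma_objective(fit$e, fit$W)
  dof <- fit$dof
  p <- if (dof >= 1) stats::pchisq(chi0, dof, lower.tail = FALSE) else NA_real_
  list(chi0 = chi0, dof = dof, p_value = p,
       msc = msc(chi0, length(fit$beta_hat)))
}

#' Model selection criterion
#'
#' `MSC = chi0 + 2 * dim(beta)`: goodness of fit penalized by parameter
#' count; the candidate meta-model with the smallest MSC is preferred.
#'
#' @param chi0 goodness-of-fit statistic.
#' @param n_params number of meta-model parameters.
#' @return the criterion value.
#' @export
msc <- function(chi0, n_params) {
  stopifnot(is.finite(chi0), is.finite(n_params))
  chi0 + 2 * n_params
}

#' Wald test of a linear parameter combination
#'
#' Tests `c' beta = v0` against the two-sided alternative using the
#' asymptotic normality of the aggregation estimator.
#'
#' @param fit a [gma_fit()] with a parameter covariance.
#' @param constraint named numeric vector of coefficients `c` (missing
#'   parameters count as 0).
#' @param null_value hypothesized value `v0`.
#' @return list with `statistic` (z) and `p_value`.
#' @export
wald_test <- function(fit, constraint, null_value = 0) {
  stopifnot(inherits(fit, "gma_fit"), !is.null(fit$covariance))
  cc <- stats::setNames(numeric(length(fit$beta_hat)), names(fit$beta_hat))
  unknown <- setdiff(names(constraint), names(cc))
  if (length(unknown)) {
    stop(sprintf("constraint references unknown parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cc[names(constraint)] <- constraint
  v <- drop(crossprod(cc, fit$covariance %*% cc))
  if (v <= 0) stop("the constrained combination has zero estimated variance", call. = FALSE)
  z <- (sum(cc * fit$beta_hat) - null_value) / sqrt(v)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Parametric bootstrap confidence intervals
#'
#' In the aggregation setting the prior studies' raw data are unavailable
#' by construction, so the bootstrap is parametric: `B` pseudo-published
#' signature sets are simulated from the fitted meta-model at each study's
#' actual sample size, each is refitted (holding the fitted weight matrix
#' fixed), and percentile intervals are taken over the refitted parameters.
#'
#' @param fit a converged [gma_fit()].
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed for the bootstrap branch.
#' @param max_fail_frac error out if more than this fraction of refits do
#'   not converge.
#' @return list with `intervals` (parameter x (lower, upper) matrix),
#'   `draws` (the B x dim(beta) refit table), and `n_failed`.
#' @export
bootstrap_ci <- function(fit, B = 500, level = 0.95,
                         seed = derive_seed(fit$plan$seed, "bootstrap"),
                         max_fail_frac = 0.1) {
  stopifnot(inherits(fit, "gma_fit"))
  if (!fit$converged) stop("refusing to bootstrap a non-converged fit", call. = FALSE)
  model <- fit$model; studies <- fit$studies; plan <- fit$plan
  pseudo <- simulate_signatures(model, fit$beta_hat, studies, plan,
                                between = fit$between, source = fit$source,
                                S = B, seed = seed)
  ctx <- build_sim_context(model, studies, plan, S = plan$S,
                           seed = derive_seed(plan$seed, "opt"),
                           between = fit$between, source = fit$source)
  draws <- matrix(NA_real_, B, length(fit$beta_hat),
                  dimnames = list(NULL, names(fit$beta_hat)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    emp_b <- pseudo[, b]
    if (anyNA(emp_b)) { n_failed <- n_failed + 1L; next }
    e_fun <- function(beta) {
      M <- ctx_signature_matrix(ctx, beta)
      list(e = emp_b - rowMeans(M, na.rm = TRUE), failures = attr(M, "failures"))
    }
    opt <- minimize_objective(e_fun, fit$W, fit$beta_hat, model$bounds, plan,
                              smooth = model$outcome != "binary", n_starts = 1,
                              warm = TRUE)
    if (!opt$converged) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- opt$beta
  }
  if (n_failed > max_fail_frac * B) {
    stop(sprintf("%d of %d bootstrap refits failed to converge", n_failed, B), call. = FALSE)
  }
  a <- (1 - level) / 2
  ints <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  list(intervals = ints, draws = draws, n_failed = n_failed)
}

#' Leave-one-study-out outlier diagnostic
#'
#' Refits the meta-model with each prior study excluded and ranks studies
#' by the drop in the goodness-of-fit statistic their exclusion induces: a
#' study whose removal improves the fit far more than the chi-square
#' degrees of freedom it takes with it reported signatures inconsistent
#' with the remaining literature.
#'
#' @inheritParams simulate_signatures
#' @param beta0 starting values for the reduced refits (defaults to the
#'   full-fit estimate).
#' @param fit optional pre-computed full fit (avoids refitting).
#' @param rounds weight-iteration rounds for each refit.
#' @return data frame with one row per study: `chi0_without`,
#'   `delta_chi0`, `dof_change`, `assessable`; sorted by `delta_chi0`
#'   descending. Attribute `chi0_full` carries the all-study statistic.
#' @export
loo_influence <- function(model, studies, plan = simulation_plan(),
                          between = NULL, source = NULL, beta0 = NULL,
                          fit = NULL, rounds = plan$rounds) {
  if (length(studies) < 2) {
    stop("leave-one-study-out needs at least two studies", call. = FALSE)
  }
  if (is.null(fit)) {
    fit <- gma_fit(model, studies, between = between, plan = plan,
                   beta0 = beta0, source = source, rounds = rounds)
  }
  npar <- length(model$param_names)
  ids <- vapply(studies, function(s) s$study_id, character(1))
  out <- data.frame(study_id = ids, chi0_without = NA_real_,
                    delta_chi0 = NA_real_, dof_change = NA_integer_,
                    assessable = TRUE)
  for (l in seq_along(studies)) {
    reduced <- studies[-l]
    n_sig <- sum(vapply(reduced, function(s) length(s$empirical_signatures), integer(1))) +
      if (is.null(between)) 0L else length(between$definitions)
    out$dof_change[l] <- length(studies[[l]]$empirical_signatures)
    if (n_sig < npar) { out$assessable[l] <- FALSE; next }
    refit <- gma_fit(model, reduced, between = between, plan = plan,
                     beta0 = fit$beta_hat, source = source, rounds = rounds)
    out$chi0_without[l] <- refit$chi0
    out$delta_chi0[l] <- fit$chi0 - refit$chi0
  }
  out <- out[order(-out$delta_chi0, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "chi0_full") <- fit$chi0
  out
}
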