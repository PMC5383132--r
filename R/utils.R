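# Internal helpers: seed derivation, PSD projection, bound transforms.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic components of a run (covariate sampling, error draws,
#' replicator retries, weight-matrix simulation, bootstrap, scenario
#' replications) draw their seeds from a single master seed through this
#' deterministic fold, so every sub-computation is independently
#' reproducible. Keys may be integers or strings.
#'
#' @param seed master integer seed.
#' @param ... integer or character keys naming the branch.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  s <- as.double(abs(as.integer(seed)) %% 2147483647L)
  for (p in parts) {
    k <- if (is.character(p)) {
      v <- utf8ToInt(p)
      sum(v * seq_along(v))
    } else {
      as.double(p)
    }
    s <- (s * 69069 + (abs(k) %% 65537) * 40503 + 12345) %% 2147483629
  }
  as.integer(s) + 1L
}

# Symmetrize and project a nearly-PSD matrix onto the PSD cone; error on
# clearly indefinite input, reporting the most negative eigenvalue.
project_psd <- function(S, tol = 1e-8, what = "covariance matrix") {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  scale <- max(abs(lam), 1)
  if (min(lam) < -tol * scale) {
    stop(sprintf("%s is not positive semi-definite (most negative eigenvalue: %.4g)",
                 what, min(lam)), call. = FALSE)
  }
  if (min(lam) < 0) {
    lam[lam < 0] <- 0
    S <- ev$vectors %*% (lam * t(ev$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

# Bounds bookkeeping -----------------------------------------------------

# `bounds` is a 2 x p matrix (rows "lower", "upper", columns = param names).
resolve_bounds <- function(param_names, bounds = NULL) {
  b <- matrix(c(-Inf, Inf), nrow = 2, ncol = length(param_names),
              dimnames = list(c("lower", "upper"), param_names))
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (!nm %in% param_names) {
        stop(sprintf("bounds given for unknown parameter '%s'", nm), call. = FALSE)
      }
      b[, nm] <- as.numeric(bounds[[nm]])
    }
  }
  b
}

# Map a parameter vector to an unconstrained optimization scale:
# (lower, Inf) -> log, finite (lower, upper) -> logit, otherwise identity.
par_to_theta <- function(beta, bounds) {
  theta <- beta
  for (j in seq_along(beta)) {
    lo <- bounds[1, j]; hi <- bounds[2, j]
    if (is.finite(lo) && !is.finite(hi)) {
      theta[j] <- log(max(beta[j] - lo, 1e-12))
    } else if (is.finite(lo) && is.finite(hi)) {
      p <- (beta[j] - lo) / (hi - lo)
      theta[j] <- stats::qlogis(min(max(p, 1e-10), 1 - 1e-10))
    }
  }
  theta
}

theta_to_par <- function(theta, bounds) {
  beta <- theta
  for (j in seq_along(theta)) {
    lo <- bounds[1, j]; hi <- bounds[2, j]
    if (is.finite(lo) && !is.finite(hi)) {
      beta[j] <- lo + exp(theta[j])
    } else if (is.finite(lo) && is.finite(hi)) {
      beta[j] <- lo + (hi - lo) * stats::plogis(theta[j])
    }
  }
  beta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_named_numeric <- function(x) {
  is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x)))
}
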