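# The aggregation estimator core: simulate every prior study's signatures
# under a candidate parameter vector, stack the empirical-minus-simulated
# errors, minimize the weighted quadratic objective, and iterate the weight
# matrix toward the inverse signature covariance.

#' Declare a simulation plan
#'
#' Controls the Monte-Carlo effort and reproducibility of one fit. All
#' draws (covariates, errors, replicator retries, weight-update and final
#' evaluation streams) are derived deterministically from the master seed,
#' and — crucially — are common random numbers: the draws are functions of
#' (seed, replicate, study) only, never of the candidate parameters, so the
#' map from parameters to simulated signatures is deterministic and smooth
#' wherever the replicators are.
#'
#' @param S simulation replications per objective evaluation during
#'   optimization.
#' @param S_final replications for the final signature evaluation entering
#'   the goodness-of-fit statistic.
#' @param n_weight_reps independently simulated signature vectors used to
#'   estimate the signature covariance for each weight update.
#' @param ridge relative ridge added to the diagonal of the estimated
#'   signature covariance before inversion.
#' @param seed master integer seed, fixed for the lifetime of one fit.
#' @param rounds weight-iteration rounds (minimize, re-estimate W, repeat);
#'   the final round's W is the one used for inference.
#' @param n_starts optimizer starts in the first round (the declared start
#'   plus jittered restarts).
#' @param jitter standard deviation of start jitter on the transformed
#'   parameter scale.
#' @param nm_maxit Nelder-Mead iteration cap (used for binary-outcome
#'   models, whose simulated surface is only piecewise smooth).
#' @param lm_maxit Levenberg-Marquardt iteration cap for the least-squares
#'   refinement on the whitened residuals.
#' @param retry_limit times a non-converged replicator replicate is
#'   resimulated with a shifted sub-seed before it is counted as failed.
#' @param penalty objective penalty per failed replicate.
#' @param weight_floor floor protecting the initial diagonal weights from
#'   near-zero signatures (`NULL` = adaptive, see [initial_weight()]).
#' @param weight_at_start simulate the first weight matrix at the starting
#'   parameter values instead of using the diagonal reciprocal-square rule
#'   (useful when moment-based starting values are trustworthy).
#' @return an object of class `simulation_plan`.
#' @export
simulation_plan <- function(S = 50, S_final = 500, n_weight_reps = 1000,
                            ridge = 1e-6, seed = 1, rounds = 3,
                            n_starts = 2, jitter = 0.5,
                            nm_maxit = 400, lm_maxit = 50,
                            retry_limit = 5, penalty = 1000,
                            weight_floor = NULL, weight_at_start = FALSE) {
  stopifnot(S >= 1, S_final >= 1, rounds >= 1, n_weight_reps >= 10)
  structure(list(S = S, S_final = S_final, n_weight_reps = n_weight_reps,
                 ridge = ridge, seed = as.integer(seed), rounds = rounds,
                 n_starts = n_starts, jitter = jitter,
                 nm_maxit = nm_maxit, lm_maxit = lm_maxit,
                 retry_limit = retry_limit, penalty = penalty,
                 weight_floor = weight_floor,
                 weight_at_start = weight_at_start),
            class = "simulation_plan")
}

# ---------------------------------------------------------------------------
# Simulation context: all draws and per-replicate precomputations for one
# (model, studies, S, seed) combination. Built once, evaluated many times.

build_sim_context <- function(model, studies, plan, S, seed, between = NULL,
                              source = NULL) {
  sampler <- resolve_covariate_source(source, studies, model$predictor_names)
  L <- length(studies)
  labels <- lapply(studies, study_signature_labels)
  n_between <- if (is.null(between)) 0L else length(between$definitions)
  stacked <- c(
    if (n_between) paste0("between:", names(between$definitions)),
    unlist(lapply(seq_len(L), function(l) {
      paste0(studies[[l]]$study_id, ":", labels[[l]])
    }))
  )
  idx <- vector("list", L)
  off <- n_between
  for (l in seq_len(L)) {
    idx[[l]] <- off + seq_along(labels[[l]])
    off <- off + length(labels[[l]])
  }
  study_ctx <- vector("list", L)
  for (l in seq_len(L)) {
    st <- studies[[l]]
    reps <- vector("list", S)
    for (s in seq_len(S)) {
      set.seed(derive_seed(seed, "draw", l, s))
      rc <- NULL
      for (try in 0:plan$retry_limit) {
        X <- sampler(st, st$n_obs)
        prep <- make_rep_context(st, X)
        if (!is.null(prep)) break
        # degenerate design (e.g. empty discretized cell): redraw covariates
        set.seed(derive_seed(seed, "redraw", l, s, try))
      }
      if (is.null(prep)) {
        stop(sprintf("study '%s': could not draw a non-degenerate design for replicate %d",
                     st$study_id, s), call. = FALSE)
      }
      n <- st$n_obs
      rc <- list(X = X, prep = prep)
      if (model$outcome == "binary") {
        rc$u <- stats::runif(n)
      } else {
        rc$z <- stats::rnorm(n)
        if (!is.null(model$study_effect_sd_param)) rc$b <- stats::rnorm(1)
      }
      if (!is.null(st$noise_channels)) {
        k <- length(st$noise_channels)
        rc$eta <- matrix(stats::rnorm(n * k), n, k)
        rc$col_sd <- apply(X[, names(st$noise_channels), drop = FALSE], 2, stats::sd)
      }
      reps[[s]] <- rc
    }
    study_ctx[[l]] <- reps
  }
  list(model = model, studies = studies, between = between, plan = plan,
       S = S, seed = seed, labels = labels, stacked_labels = stacked,
       n_between = n_between, idx = idx, study_ctx = study_ctx,
       n_sig = length(stacked))
}

# Per-replicate fast replicator closures; returns NULL when the fixed
# design itself is degenerate (caller redraws covariates). These paths are
# algebraically identical to the public replicator operations (the test
# suite asserts agreement); they precompute everything that depends only on
# the fixed covariate draw so that the per-evaluation cost is a few matrix
# products.
make_rep_context <- function(study, X) {
  force(study); force(X)
  noisy <- !is.null(study$noise_channels)
  if (study$replicator == "ols" && !noisy) {
    Xd <- cbind(1, X[, study$covariate_subset, drop = FALSE])
    p <- ncol(Xd)
    XtX <- crossprod(Xd)
    A <- tryCatch(solve(XtX, t(Xd)), error = function(e) NULL)
    if (is.null(A)) return(NULL)
    include <- study$options$include
    dfr <- if (study$options$mse_df == "n-p") nrow(Xd) - p else nrow(Xd)
    labs <- study_signature_labels(study)
    function(y) {
      coefs <- A %*% y
      fitted <- Xd %*% coefs
      out <- numeric(0)
      if ("coefs" %in% include) out <- drop(coefs)
      if ("mse" %in% include) out <- c(out, sum((y - fitted)^2) / dfr)
      if ("r2" %in% include) {
        sst <- sum((y - mean(y))^2)
        out <- c(out, if (sst > 0) 1 - sum((y - fitted)^2) / sst else 0)
      }
      names(out) <- labs
      list(sig = out, ok = TRUE)
    }
  } else if (study$replicator == "anova" && !noisy) {
    facs <- study$options$factors
    levels_list <- lapply(facs, function(f) discretize(X[, f$column], f$cutpoints))
    k <- vapply(levels_list, max, integer(1))
    for (f in seq_along(levels_list)) {
      if (length(unique(levels_list[[f]])) < k[f]) return(NULL)
    }
    fac_names <- vapply(facs, function(f) f$column, character(1))
    inter <- isTRUE(study$options$include_interaction)
    labs <- study_signature_labels(study)
    n <- nrow(X)
    if (length(facs) == 1) {
      # one-way table: group-mean algebra on a precomputed indicator matrix
      g <- levels_list[[1]]
      G <- matrix(0, n, k[1]); G[cbind(seq_len(n), g)] <- 1
      nj <- colSums(G)
      function(y) {
        m <- drop(crossprod(G, y)) / nj
        gm <- mean(y)
        eff <- m - gm
        sse <- sum((y - m[g])^2)
        sig <- c(gm, eff, sum(nj * eff^2) / (k[1] - 1), sse / (n - k[1]))
        names(sig) <- labs
        list(sig = sig, ok = TRUE)
      }
    } else {
      # additive (or interacted) two-factor design: precomputed QR of the
      # sum-to-zero design in sequential column order
      C1 <- stats::contr.sum(k[1]); C2 <- stats::contr.sum(k[2])
      Z1 <- C1[levels_list[[1]], , drop = FALSE]
      Z2 <- C2[levels_list[[2]], , drop = FALSE]
      Zd <- cbind(1, Z1, Z2)
      df_int <- 0L
      if (inter) {
        ZI <- matrix(0, n, (k[1] - 1) * (k[2] - 1))
        cc <- 0
        for (j in seq_len(k[2] - 1)) for (i in seq_len(k[1] - 1)) {
          cc <- cc + 1
          ZI[, cc] <- Z1[, i] * Z2[, j]
        }
        Zd <- cbind(Zd, ZI)
        df_int <- ncol(ZI)
      }
      qr_d <- qr(Zd)
      if (qr_d$rank < ncol(Zd)) return(NULL)
      Q <- qr.Q(qr_d)
      Rinv <- backsolve(qr.R(qr_d), diag(ncol(Zd)))
      i1 <- 1 + seq_len(k[1] - 1)
      i2 <- 1 + (k[1] - 1) + seq_len(k[2] - 1)
      iI <- if (inter) 1 + (k[1] - 1) + (k[2] - 1) + seq_len(df_int)
      dfe <- n - ncol(Zd)
      function(y) {
        qy <- drop(crossprod(Q, y))
        coefs <- drop(Rinv %*% qy)
        proj2 <- qy^2
        sse <- sum(y^2) - sum(proj2)
        sig <- c(coefs[1], drop(C1 %*% coefs[i1]), drop(C2 %*% coefs[i2]),
                 sum(proj2[i1]) / (k[1] - 1), sum(proj2[i2]) / (k[2] - 1),
                 sse / dfe)
        if (inter) sig <- c(sig, sum(proj2[iI]) / df_int)
        names(sig) <- labs
        list(sig = sig, ok = TRUE)
      }
    }
  } else if (study$replicator == "logistic" && !noisy) {
    # Newton-Raphson maximum likelihood on the precomputed design; the
    # public glm.fit route is the cross-checked reference for this path.
    # Successive objective evaluations differ little under common random
    # numbers, so the iteration warm-starts from the previous solution
    # (the converged MLE does not depend on the start).
    Xd <- cbind(1, X[, study$covariate_subset, drop = FALSE])
    p <- ncol(Xd)
    labs <- study_signature_labels(study)
    b_warm <- numeric(p)
    newton <- function(y, b) {
      for (it in seq_len(25)) {
        mu <- 1 / (1 + exp(-drop(Xd %*% b)))
        w <- mu * (1 - mu)
        step <- drop(solve(crossprod(Xd, Xd * w), crossprod(Xd, y - mu)))
        if (any(!is.finite(step))) return(NULL)
        b <- b + step
        if (max(abs(step)) < 1e-9) return(b)
        if (max(abs(b)) > 30) return(NULL)  # diverging: separated data
      }
      NULL
    }
    function(y) {
      if (all(y == y[1])) return(list(sig = NULL, ok = FALSE))
      b <- newton(y, b_warm)
      if (is.null(b) && any(b_warm != 0)) b <- newton(y, numeric(p))
      if (is.null(b) || max(abs(b)) > 15) return(list(sig = NULL, ok = FALSE))
      b_warm <<- b
      list(sig = stats::setNames(b, labs), ok = TRUE)
    }
  } else if (study$replicator == "ols" && noisy) {
    # measurement-noise path: the design changes with the noise parameters,
    # so only the labels and options can be fixed in advance
    include <- study$options$include
    labs <- study_signature_labels(study)
    subset <- study$covariate_subset
    np <- length(subset) + 1L
    dfr_np <- study$options$mse_df == "n-p"
    function(y, Xobs) {
      Xd <- cbind(1, Xobs[, subset, drop = FALSE])
      f <- stats::.lm.fit(Xd, y)
      if (f$rank < np) return(list(sig = NULL, ok = FALSE))
      out <- numeric(0)
      if ("coefs" %in% include) out <- f$coefficients
      sse <- sum(f$residuals^2)
      if ("mse" %in% include) {
        out <- c(out, sse / if (dfr_np) length(y) - np else length(y))
      }
      if ("r2" %in% include) {
        sst <- sum((y - mean(y))^2)
        out <- c(out, if (sst > 0) 1 - sse / sst else 0)
      }
      names(out) <- labs
      list(sig = out, ok = TRUE)
    }
  } else if (study$replicator == "effect_size") {
    n <- nrow(X)
    function(y) {
      list(sig = c(effect = mean(y), within_var = stats::var(y) / n), ok = TRUE)
    }
  } else {
    # generic path: logistic, and any replicator under measurement noise
    function(y, Xobs = X) {
      r <- replicate_study(study, Xobs, y)
      if (!r$converged) return(list(sig = NULL, ok = FALSE))
      list(sig = r$signatures, ok = TRUE)
    }
  }
}

# Evaluate one replicate of one study at beta; returns named signature
# vector or NULL after exhausting the retry budget.
eval_rep <- function(ctx, l, s, beta) {
  model <- ctx$model
  st <- ctx$studies[[l]]
  rc <- ctx$study_ctx[[l]][[s]]
  X <- rc$X
  mu <- model$mean_function(X, beta)
  Xobs <- X
  if (!is.null(rc$eta)) {
    d <- beta[st$noise_channels]
    cols <- names(st$noise_channels)
    Xobs[, cols] <- X[, cols] +
      rc$eta * rep(d * rc$col_sd, each = nrow(X))
  }
  noisy <- !is.null(rc$eta)
  if (model$outcome == "binary") {
    y <- as.numeric(rc$u < mu)
    r <- if (noisy) rc$prep(y, Xobs) else rc$prep(y)
    k <- 0
    while (!r$ok && k < ctx$plan$retry_limit) {
      k <- k + 1
      set.seed(derive_seed(ctx$seed, "retry", l, s, k))
      y <- as.numeric(stats::runif(length(mu)) < mu)
      r <- if (noisy) rc$prep(y, Xobs) else rc$prep(y)
    }
  } else {
    y <- mu
    if (!is.null(model$error_sd_param)) {
      y <- y + beta[[model$error_sd_param]] * rc$z
    }
    if (!is.null(model$study_effect_sd_param)) {
      y <- y + beta[[model$study_effect_sd_param]] * rc$b
    }
    if (!is.finite(sum(y))) return(NULL)  # numerically exploded candidate
    r <- if (noisy) rc$prep(y, Xobs) else rc$prep(y)
  }
  if (!r$ok) return(NULL)
  r$sig
}

# Stacked signature matrix (n_sig x S); failed replicates give NA columns in
# the affected study block and are counted.
ctx_signature_matrix <- function(ctx, beta) {
  S <- ctx$S; L <- length(ctx$studies)
  M <- matrix(NA_real_, ctx$n_sig, S, dimnames = list(ctx$stacked_labels, NULL))
  failures <- 0L
  need_between <- ctx$n_between > 0
  for (s in seq_len(S)) {
    per_study <- if (need_between) vector("list", L)
    for (l in seq_len(L)) {
      sig <- eval_rep(ctx, l, s, beta)
      if (is.null(sig)) {
        failures <- failures + 1L
      } else {
        M[ctx$idx[[l]], s] <- sig
        if (need_between) per_study[[l]] <- sig
      }
    }
    if (need_between && !any(vapply(per_study, is.null, logical(1)))) {
      M[seq_len(ctx$n_between), s] <-
        between_study_statistics(per_study, ctx$between)
    }
  }
  attr(M, "failures") <- failures
  M
}

#' Simulate stacked study signatures under a candidate parameter vector
#'
#' Draws `S` independent simulation replicates — per study: a covariate
#' table consistent with the study's reported moments, simulated responses
#' from the meta-model, and a re-run of the study's replicator — and stacks
#' the resulting signature vectors (between-study block first, then study
#' by study). Identical plans give identical output; under common random
#' numbers the draws do not depend on `beta`.
#'
#' @param model a [meta_model()].
#' @param beta named parameter vector.
#' @param studies list of [prior_study()] objects.
#' @param plan a [simulation_plan()]; `plan$S` replicates are drawn unless
#'   `S` overrides.
#' @param between optional [between_study_spec()].
#' @param source optional [covariate_source()].
#' @param S,seed optional overrides of the plan's replicate count and seed.
#' @return an `n_sig x S` matrix of stacked signatures with labeled rows;
#'   attribute `failures` counts replicates whose replicator never
#'   converged.
#' @export
simulate_signatures <- function(model, beta, studies, plan = simulation_plan(),
                                between = NULL, source = NULL,
                                S = plan$S, seed = plan$seed) {
  beta <- check_beta(model, beta)
  ctx <- build_sim_context(model, studies, plan, S = S, seed = seed,
                           between = between, source = source)
  ctx_signature_matrix(ctx, beta)
}

#' Stacked signature error
#'
#' The aggregation error vector: published signatures minus the mean of the
#' simulated ones, per label, between-study block first.
#'
#' @param empirical named stacked vector of published signatures.
#' @param simulated matrix of simulated stacked signatures (rows = labels,
#'   columns = replicates), as from [simulate_signatures()].
#' @return named error vector `e`.
#' @export
signature_error <- function(empirical, simulated) {
  if (is.null(rownames(simulated)) || !identical(names(empirical), rownames(simulated))) {
    off <- union(setdiff(names(empirical), rownames(simulated)),
                 setdiff(rownames(simulated), names(empirical)))
    stop(sprintf("signature labels of empirical and simulated vectors do not align%s",
                 if (length(off)) paste0(" (offending: ", paste(off, collapse = ", "), ")")
                 else " (ordering differs)"), call. = FALSE)
  }
  empirical - rowMeans(simulated, na.rm = TRUE)
}

#' Weighted quadratic aggregation objective
#'
#' @param e stacked error vector.
#' @param W symmetric positive semi-definite weight matrix.
#' @return the scalar `t(e) %*% W %*% e`.
#' @export
gma_objective <- function(e, W) {
  stopifnot(length(e) == nrow(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8 * max(abs(W), 1)) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  drop(crossprod(e, W %*% e))
}

#' Initial diagonal weight matrix
#'
#' Diagonal weights proportional to the reciprocal of the squared published
#' signatures, `1 / max(signature^2, floor^2)`, putting the heterogeneous
#' signature scales on a relative-error footing before any covariance
#' information is available. By default the floor is 5% of the median
#' absolute signature, so a published value that happens to sit near zero
#' cannot dominate the first estimation round (its reciprocal square would
#' otherwise act as a near-exact constraint); pass an explicit small
#' `floor` to protect exact zeros only.
#'
#' @param empirical named stacked vector of published signatures.
#' @param floor weight floor; `NULL` for the adaptive default.
#' @return diagonal weight matrix with attribute
#'   `provenance = "initial-diagonal"`.
#' @export
initial_weight <- function(empirical, floor = NULL) {
  if (is.null(floor)) {
    floor <- max(0.05 * stats::median(abs(empirical)), 1e-6)
  }
  W <- diag(1 / pmax(empirical^2, floor^2), nrow = length(empirical))
  dimnames(W) <- list(names(empirical), names(empirical))
  attr(W, "provenance") <- "initial-diagonal"
  W
}

#' Re-estimate the weight matrix from simulated signature covariance
#'
#' Simulates `n_reps` independent stacked signature vectors at the studies'
#' actual sample sizes under the current estimate, takes their sample
#' covariance `Sigma_hat`, and returns
#' `W = solve(Sigma_hat + ridge * diag(diag(Sigma_hat)))` — the estimated
#' inverse covariance of the signature estimators, the efficient weighting.
#'
#' @inheritParams simulate_signatures
#' @param beta_hat parameter estimate from the previous round.
#' @param n_reps simulated signature vectors.
#' @param ridge relative diagonal ridge.
#' @return weight matrix with attributes
#'   `provenance = "simulated-inverse-covariance"` and `Sigma_hat` (the
#'   unridged covariance estimate).
#' @export
update_weight <- function(model, beta_hat, studies, plan = simulation_plan(),
                          between = NULL, source = NULL,
                          n_reps = plan$n_weight_reps, ridge = plan$ridge,
                          seed = derive_seed(plan$seed, "weight")) {
  M <- simulate_signatures(model, beta_hat, studies, plan, between = between,
                           source = source, S = n_reps, seed = seed)
  ok <- colSums(is.na(M)) == 0
  Sigma <- stats::cov(t(M[, ok, drop = FALSE]))
  Sr <- Sigma + ridge * diag(diag(Sigma), nrow = nrow(Sigma))
  W <- tryCatch(chol2inv(chol(Sr)), error = function(e) NULL)
  if (is.null(W)) {
    stop(paste("simulated signature covariance is not invertible;",
               "increase the ridge or prune collinear signatures"), call. = FALSE)
  }
  dimnames(W) <- dimnames(Sigma)
  attr(W, "provenance") <- "simulated-inverse-covariance"
  attr(W, "Sigma_hat") <- Sigma
  W
}

# ---------------------------------------------------------------------------
# Optimization

minimize_objective <- function(e_fun, W, beta0, bounds, plan, smooth,
                               n_starts = 1, start_seed = 0, warm = FALSE,
                               extra_starts = NULL) {
  Wp <- project_psd(W, what = "weight matrix")
  Lw <- chol(Wp + diag(1e-10 * max(diag(Wp), 1), nrow(Wp)))
  pen <- plan$penalty
  res_fun <- function(theta) {
    beta <- theta_to_par(theta, bounds)
    names(beta) <- colnames(bounds)
    ef <- e_fun(beta)
    c(drop(Lw %*% ef$e), sqrt(pen * ef$failures))
  }
  obj_fun <- function(theta) sum(res_fun(theta)^2)
  theta0 <- par_to_theta(beta0, bounds)
  starts <- list(theta0)
  for (b in extra_starts) {
    th <- par_to_theta(b, bounds)
    if (max(abs(th - theta0)) > 1e-8) starts <- c(starts, list(th))
  }
  if (n_starts > 1) {
    set.seed(derive_seed(start_seed, "starts"))
    for (k in seq_len(n_starts - 1)) {
      starts <- c(starts, list(theta0 + stats::rnorm(length(theta0), sd = plan$jitter)))
    }
  }
  best <- NULL
  for (th in starts) {
    th1 <- th
    if (!smooth && !warm) {
      nm <- stats::optim(th1, obj_fun, method = "Nelder-Mead",
                         control = list(maxit = plan$nm_maxit, reltol = 1e-8))
      th1 <- nm$par
    }
    lm <- suppressWarnings(minpack.lm::nls.lm(
      par = th1, fn = res_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = plan$lm_maxit, ptol = 1e-9, ftol = 1e-9,
        epsfcn = if (smooth) 1e-9 else 1e-3)))
    val <- sum(lm$fvec^2)
    if (is.null(best) || val < best$value) {
      best <- list(theta = lm$par, value = val,
                   converged = lm$info %in% 1:4, info = lm$message)
    }
  }
  beta <- theta_to_par(best$theta, bounds)
  names(beta) <- colnames(bounds)
  list(beta = beta, value = best$value, converged = best$converged,
       message = best$info)
}

default_beta0 <- function(model) {
  b <- numeric(length(model$param_names))
  names(b) <- model$param_names
  for (j in seq_along(b)) {
    lo <- model$bounds[1, j]; hi <- model$bounds[2, j]
    b[j] <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
            else if (is.finite(lo)) lo + 1 else 0
  }
  b
}

# Literature-informed starting values: where a meta-model coefficient has a
# directly corresponding published signature (a `b:<predictor>` regression
# coefficient for a `b_<predictor>` parameter, the intercepts for `b0`, the
# root mean published MSE for the error sd, mean effects for a summary
# effect), start from the average published value — the prior studies'
# (possibly attenuated) estimates are almost always in the basin of the
# aggregated optimum. Parameters with no published counterpart keep the
# neutral default.
informed_beta0 <- function(model, emp, studies = NULL) {
  b <- default_beta0(model)
  lab <- sub("^[^:]*:", "", names(emp))
  mean_of <- function(l) if (any(lab == l)) mean(emp[lab == l]) else NULL
  for (p in names(b)) {
    v <- NULL
    if (grepl("^b_", p)) {
      v <- mean_of(paste0("b:", sub("^b_", "", p)))
    } else if (p == "b0") {
      v <- mean_of("intercept") %||% mean_of("grand_mean")
    } else if (!is.null(model$study_effect_sd_param) &&
               p == model$study_effect_sd_param) {
      # moment start for the between-study sd: between-study variance of
      # effects minus the mean reported within-study variance
      bv <- if (any(startsWith(names(emp), "between:"))) {
        emp[startsWith(names(emp), "between:")][1]
      }
      wv <- mean_of("within_var")
      if (!is.null(bv) && !is.null(wv)) {
        v <- sqrt(max(bv - wv, 1e-4))
      }
    } else if (!is.null(model$error_sd_param) && p == model$error_sd_param) {
      m <- mean_of("mse")
      if (!is.null(m) && m > 0) {
        v <- sqrt(m)
      } else if (!is.null(studies) && any(lab == "within_var")) {
        # within-study sd from reported variances of study means
        wv <- emp[lab == "within_var"]
        ns <- vapply(studies, function(s) s$n_obs, numeric(1))
        if (length(wv) == length(ns)) v <- sqrt(mean(wv * ns))
      }
    } else if (!is.null(model$study_effect_sd_param) && p == "mu") {
      v <- mean_of("effect")
    }
    if (!is.null(v) && is.finite(v) &&
        v >= model$bounds[1, p] && v <= model$bounds[2, p]) {
      b[p] <- v
    }
  }
  b
}

# ---------------------------------------------------------------------------

#' Fit a meta-model by generalized model aggregation
#'
#' The estimation core: alternates minimization of the weighted quadratic
#' objective `t(e) W e` (where `e` stacks the published-minus-simulated
#' signature errors) with re-estimation of `W` as the inverse of the
#' simulated signature covariance, for `rounds` rounds. The final round's
#' weight matrix — the estimated efficient weighting — is the one used for
#' the goodness-of-fit statistic and the parameter covariance.
#'
#' Optimization runs on a transformed scale (log for scale parameters,
#' logit for doubly-bounded parameters) with a Levenberg-Marquardt
#' least-squares refinement of the Cholesky-whitened residuals; for
#' binary-outcome models, whose simulated surface is piecewise constant at
#' fine scales, a Nelder-Mead pass precedes the refinement and the
#' refinement uses wide finite-difference steps.
#'
#' @inheritParams simulate_signatures
#' @param beta0 named starting parameter vector (defaults to a neutral
#'   point: 0 for unbounded parameters, 1 above a zero lower bound, the
#'   interval midpoint for doubly-bounded parameters).
#' @param rounds weight-iteration rounds (overrides the plan).
#' @param W_init optional starting weight matrix (defaults to
#'   [initial_weight()] on the published signatures).
#' @param compute_inference estimate the signature Jacobian, parameter
#'   covariance, goodness of fit and model-selection criterion (default
#'   `TRUE`).
#' @return an object of class `gma_fit` with elements `beta_hat`,
#'   `covariance`, `se`, `chi0`, `dof`, `p_value`, `msc`, `e` (stacked
#'   final error), `per_study_errors`, `W`, `Sigma_hat`, `D`, `objective`,
#'   `trace`, and the resolved inputs.
#' @export
gma_fit <- function(model, studies, between = NULL, plan = simulation_plan(),
                    beta0 = NULL, source = NULL, rounds = plan$rounds,
                    W_init = NULL, compute_inference = TRUE) {
  stopifnot(inherits(model, "meta_model"), length(studies) >= 1)
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) stop("study ids must be unique", call. = FALSE)
  for (st in studies) {
    if (is.null(st$empirical_signatures)) {
      stop(sprintf("study '%s' carries no empirical signatures", st$study_id), call. = FALSE)
    }
  }
  if (!is.null(between) && is.null(between$empirical)) {
    stop("between-study spec carries no empirical values", call. = FALSE)
  }
  emp <- c(
    if (!is.null(between)) {
      stats::setNames(between$empirical, paste0("between:", names(between$empirical)))
    },
    unlist(lapply(studies, function(st) {
      stats::setNames(st$empirical_signatures,
                      paste0(st$study_id, ":", names(st$empirical_signatures)))
    }))
  )
  npar <- length(model$param_names)
  if (length(emp) < npar) {
    stop(sprintf(paste("under-identified problem: %d signatures cannot identify %d",
                       "parameters; add studies or signatures, or simplify the meta-model"),
                 length(emp), npar), call. = FALSE)
  }
  beta0 <- if (is.null(beta0)) informed_beta0(model, emp, studies) else check_beta(model, beta0)

  ctx_opt <- build_sim_context(model, studies, plan, S = plan$S,
                               seed = derive_seed(plan$seed, "opt"),
                               between = between, source = source)
  ctx_fin <- build_sim_context(model, studies, plan, S = plan$S_final,
                               seed = derive_seed(plan$seed, "final"),
                               between = between, source = source)
  stopifnot(identical(names(emp), ctx_opt$stacked_labels))

  e_fun <- function(beta) {
    M <- ctx_signature_matrix(ctx_opt, beta)
    list(e = emp - rowMeans(M, na.rm = TRUE), failures = attr(M, "failures"))
  }

  W <- if (!is.null(W_init)) {
    W_init
  } else if (isTRUE(plan$weight_at_start)) {
    # with trustworthy starting values (e.g. moment estimators), the first
    # weighting can already be the simulated inverse covariance at the
    # start instead of the diagonal reciprocal-square rule
    update_weight(model, beta0, studies, plan, between = between,
                  source = source, seed = derive_seed(plan$seed, "weight", 0))
  } else {
    initial_weight(emp, plan$weight_floor)
  }
  smooth <- model$outcome != "binary"
  trace <- list()
  beta_hat <- beta0
  Sigma_hat <- NULL
  for (r in seq_len(rounds)) {
    opt <- minimize_objective(e_fun, W, beta_hat, model$bounds, plan,
                              smooth = smooth,
                              n_starts = if (r == 1) plan$n_starts else 1,
                              start_seed = derive_seed(plan$seed, "start", r),
                              warm = r > 1,
                              extra_starts = if (r > 1 && smooth) list(beta0))
    beta_hat <- opt$beta
    trace[[r]] <- list(round = r, objective = opt$value,
                       converged = opt$converged,
                       weight = attr(W, "provenance") %||% "user")
    if (r < rounds) {
      # The covariance used for the next round's weighting must be
      # estimated at a sensible point: an optimizer basin where the
      # simulated signatures disperse far beyond the published values'
      # own scale is degenerate, and inverting its covariance would give
      # a near-zero weight matrix that makes every subsequent candidate
      # look like a perfect fit. Re-optimize this round from fresh
      # jittered starts (same weight matrix, so objectives stay
      # comparable) before accepting such a point.
      scale_ref <- pmax(abs(emp), stats::median(abs(emp)))
      for (attempt in seq_len(3)) {
        Wnew <- update_weight(model, beta_hat, studies, plan, between = between,
                              source = source,
                              seed = derive_seed(plan$seed, "weight", r))
        disp <- stats::median(sqrt(diag(attr(Wnew, "Sigma_hat"))) / scale_ref)
        if (disp <= 3 || attempt == 3) break
        opt2 <- minimize_objective(e_fun, W, beta_hat, model$bounds, plan,
                                   smooth = smooth, n_starts = plan$n_starts + 1,
                                   start_seed = derive_seed(plan$seed, "rescue", r, attempt),
                                   warm = TRUE, extra_starts = list(beta0))
        if (opt2$value < opt$value) {
          opt <- opt2
          beta_hat <- opt2$beta
          trace[[r]]$objective <- opt2$value
          trace[[r]]$rescued <- attempt
        }
      }
      W <- Wnew
      Sigma_hat <- attr(W, "Sigma_hat")
    }
  }

  Mfin <- ctx_signature_matrix(ctx_fin, beta_hat)
  e_fin <- emp - rowMeans(Mfin, na.rm = TRUE)
  per_study_errors <- lapply(seq_along(studies), function(l) e_fin[ctx_fin$idx[[l]]])
  names(per_study_errors) <- ids

  fit <- structure(list(
    model = model, studies = studies, between = between, plan = plan,
    source = source, beta_hat = beta_hat, bounds = model$bounds,
    empirical = emp, e = e_fin, per_study_errors = per_study_errors,
    W = W, Sigma_hat = Sigma_hat, objective = gma_objective(e_fin, W),
    S_final = plan$S_final, rounds = rounds, trace = trace,
    converged = trace[[rounds]]$converged,
    failures = attr(Mfin, "failures"),
    dof = length(emp) - npar
  ), class = "gma_fit")

  if (compute_inference) {
    if (is.null(Sigma_hat)) {
      Wtmp <- update_weight(model, beta_hat, studies, plan, between = between,
                            source = source,
                            seed = derive_seed(plan$seed, "weight", "post"))
      fit$Sigma_hat <- attr(Wtmp, "Sigma_hat")
      if (identical(attr(W, "provenance") %||% "", "simulated-inverse-covariance")) {
        fit$W <- Wtmp
      }
    }
    fit$D <- jacobian_from_context(ctx_opt, beta_hat, model)
    fit$covariance <- parameter_covariance(fit$D, fit$W, fit$Sigma_hat,
                                           S = plan$S_final)
    fit$se <- sqrt(pmax(diag(fit$covariance), 0))
    assess <- chi0_statistic(fit)
    fit$chi0 <- assess$chi0
    fit$p_value <- assess$p_value
    fit$msc <- assess$msc
  }
  fit
}

#' @export
print.gma_fit <- function(x, ...) {
  cat(sprintf("Generalized model aggregation fit: '%s'\n", x$model$name))
  cat(sprintf("  %d studies, %d signatures, %d parameters (dof = %d)\n",
              length(x$studies), length(x$empirical),
              length(x$beta_hat), x$dof))
  est <- data.frame(estimate = x$beta_hat)
  if (!is.null(x$se)) {
    est$se <- x$se
    ci <- stats::confint(x)
    est$`2.5 %` <- ci[, 1]; est$`97.5 %` <- ci[, 2]
  }
  print(round(est, 4))
  if (!is.null(x$chi0)) {
    cat(sprintf("  chi0 = %.3f on %d dof (p = %.3g); MSC = %.3f\n",
                x$chi0, x$dof, x$p_value, x$msc))
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$failures > 0) {
    cat(sprintf("  %d replicator replicates failed during final evaluation\n", x$failures))
  }
  invisible(x)
}

#' @export
coef.gma_fit <- function(object, ...) object$beta_hat

#' @export
vcov.gma_fit <- function(object, ...) object$covariance

#' @export
confint.gma_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$covariance)) {
    stop("fit carries no parameter covariance (compute_inference = FALSE?)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$beta_hat
  se <- object$se
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
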