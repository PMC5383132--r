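# Synthetic validation scenarios: self-contained generators that draw raw
# data from a known truth, run each "prior" study's procedure once to
# produce its published signatures, and score the aggregation estimator's
# recovery of that truth. Seven scenarios cover mis-specified linear and
# logistic prior studies, ANOVA priors of a continuous interacting truth,
# two mis-specified linear priors of a nonlinear surface, and a
# random-effects comparison against DerSimonian-Laird, plus a
# measurement-error extension.

#' Configure a validation scenario
#'
#' Returns the scenario's study conditions with their defaults:
#' \describe{
#'   \item{1}{truth `y = 1 + x1 + x2 + x3 + e`, `e ~ N(0,1)`; three OLS
#'     prior studies each using two of the three (equicorrelated,
#'     `rho = 0.5`) predictors; signatures = 3 coefficients + MSE each
#'     (12 total).}
#'   \item{2}{as 1 but one predictor per prior study (9 signatures).}
#'   \item{3}{binary truth `Pr(y=1) = plogis(1 + x1 + x2 + x3)`; three
#'     two-predictor logistic prior studies (9 signatures).}
#'   \item{4}{as 3 with one predictor per study (6 signatures).}
#'   \item{5}{truth `y = 1 + x1 + x2 + x1*x2 + e`; three ANOVA prior
#'     studies on factors discretized at the 33rd/66th percentiles (x1)
#'     and quartiles (x2): two one-way studies and one additive two-way
#'     study (6, 7, 11 signatures).}
#'   \item{6}{nonlinear fluid-leakage truth, quadratic in time with a
#'     time-temperature interaction; two mis-specified linear prior
#'     studies (time-only; time + temperature), signatures = 3 + 2
#'     coefficients + two R-squared values (7 total).}
#'   \item{7}{normal-normal random-effects truth; five prior effect sizes
#'     with reported within-study variances plus the between-study
#'     variance of effects as signatures.}
#' }
#'
#' @param id scenario id, 1-7.
#' @param R replications for [run_scenario()].
#' @param seed master seed.
#' @param ... overrides of any default listed below (e.g. `n_obs`, `rho`,
#'   `beta_true`, `delta_true`, `tau2`, `S`, `rounds`).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(id, R = 1, seed = 1, ...) {
  stopifnot(id %in% 1:7)
  cfg <- list(
    id = id, R = R, seed = as.integer(seed),
    # estimation effort (scaled for replication loops)
    S = if (id == 7) 60 else 50,
    S_final = if (id == 7) 200 else 300,
    n_weight_reps = if (id == 7) 800 else 800,
    rounds = if (id == 7) 1 else 2,
    n_starts = if (id %in% c(5, 6)) 3 else 1, jitter = 1,
    lm_maxit = if (id == 7) 25 else 50,
    weight_at_start = id == 7,
    # regression scenarios
    n_obs = if (id %in% c(3, 4)) 300L else 100L,
    rho = 0.5,
    delta_true = 0, estimate_delta = FALSE,
    # scenario 7
    mu_true = 0.3, tau2 = 0.05, sigma_within = 1,
    n_within = c(20L, 35L, 50L, 80L, 120L)
  )
  cfg$beta_true <- switch(as.character(id),
    "1" = , "2" = c(b0 = 1, b_x1 = 1, b_x2 = 1, b_x3 = 1, sigma = 1),
    "3" = , "4" = c(b0 = 1, b_x1 = 1, b_x2 = 1, b_x3 = 1),
    "5" = c(b0 = 1, b_x1 = 1, b_x2 = 1, b_x1.x2 = 1, sigma = 1),
    "6" = c(rate0 = 3, lin_time = 0.3, quad_time = 0.05,
            exp_temp = 0.02, sigma = 0.5),
    "7" = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "beta_true"))
  if (length(unknown)) {
    stop(sprintf("unknown scenario setting(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$id == 7) {
    cfg$beta_true <- c(mu = cfg$mu_true, tau = sqrt(cfg$tau2),
                       sigma = cfg$sigma_within)
  }
  structure(cfg, class = "scenario_config")
}

scenario_meta_model <- function(cfg) {
  switch(as.character(cfg$id),
    "1" = , "2" = polynomial_meta_model(
      list(character(0), "x1", "x2", "x3"), predictors = c("x1", "x2", "x3"),
      name = sprintf("linear scenario %d", cfg$id)),
    "3" = , "4" = logistic_meta_model(
      list(character(0), "x1", "x2", "x3"), predictors = c("x1", "x2", "x3"),
      name = sprintf("logistic scenario %d", cfg$id)),
    "5" = polynomial_meta_model(
      list(character(0), "x1", "x2", c("x1", "x2")), predictors = c("x1", "x2"),
      name = "interaction scenario 5"),
    "6" = meta_model(
      name = "nonlinear leakage scenario 6",
      param_names = c("rate0", "lin_time", "quad_time", "exp_temp", "sigma"),
      predictor_names = c("time", "temp"),
      # quadratic-in-time base rate modulated exponentially by temperature
      # (centred at the mean operating temperature); the positive leading
      # rate keeps the surface family one-signed
      mean_function = function(X, beta) {
        t <- X[, "time"]; Tc <- X[, "temp"] - 30
        as.vector(beta[["rate0"]] *
                    (1 + beta[["lin_time"]] * t + beta[["quad_time"]] * t^2) *
                    exp(beta[["exp_temp"]] * Tc))
      },
      outcome = "continuous", error_sd_param = "sigma",
      bounds = list(rate0 = c(0, Inf))),
    "7" = random_effects_meta_model(name = "random-effects scenario 7"))
}

scenario_study_skeletons <- function(cfg) {
  switch(as.character(cfg$id),
    "1" = , "3" = list(c("x1", "x2"), c("x2", "x3"), c("x1", "x3")),
    "2" = , "4" = list("x1", "x2", "x3"),
    NULL)
}

scenario_covariate_moments <- function(cfg) {
  p <- if (cfg$id == 6) 2L else if (cfg$id == 5) 2L else 3L
  nm <- if (cfg$id == 6) c("time", "temp") else paste0("x", seq_len(p))
  if (cfg$id == 6) {
    sds <- c(2, 10)
    Sg <- diag(sds) %*% matrix(c(1, 0.3, 0.3, 1), 2) %*% diag(sds)
    mu <- c(5, 30)
  } else {
    Sg <- matrix(cfg$rho, p, p); diag(Sg) <- 1
    mu <- rep(0, p)
  }
  dimnames(Sg) <- list(nm, nm)
  list(mean = stats::setNames(mu, nm), cov = Sg)
}

#' Generate a validation scenario
#'
#' Draws raw data from the scenario's true data-generating process, runs
#' each prior study's replicator once on its own raw draw to produce the
#' study's "published" signature vector (imitating the literature, with an
#' independent seed branch per study), packages each study's sample
#' covariate moments for the samplers, and records the truth for scoring.
#'
#' @param config a [scenario_config()].
#' @return list with `model`, `studies` (carrying freshly published
#'   signatures and moments), optional `between`, and `truth`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  model <- scenario_meta_model(cfg)
  if (cfg$id == 7) return(generate_scenario7(cfg, model))
  truth_mom <- scenario_covariate_moments(cfg)
  beta_true <- cfg$beta_true

  skeletons <- switch(as.character(cfg$id),
    "5" = list(
      list(factors = list(list(column = "x1", cutpoints = c(33, 66)))),
      list(factors = list(list(column = "x2", cutpoints = c(25, 50, 75)))),
      list(factors = list(list(column = "x1", cutpoints = c(33, 66)),
                          list(column = "x2", cutpoints = c(25, 50, 75))))),
    "6" = list(
      list(subset = "time", include = c("coefs", "r2")),
      list(subset = c("time", "temp"), include = c("coefs", "r2"))),
    lapply(scenario_study_skeletons(cfg), function(ss) list(subset = ss)))

  replicator <- switch(as.character(cfg$id),
                       "3" = , "4" = "logistic",
                       "5" = "anova", "ols")
  studies <- vector("list", length(skeletons))
  for (l in seq_along(skeletons)) {
    sk <- skeletons[[l]]
    id <- sprintf("study%d", l)
    published <- NULL
    for (try in 0:20) {
      set.seed(derive_seed(cfg$seed, "publish", l, try))
      X <- sample_from_moments(truth_mom$mean, truth_mom$cov, cfg$n_obs)
      Xobs <- X
      if (cfg$delta_true > 0) {
        d <- stats::setNames(rep(cfg$delta_true, ncol(X)), colnames(X))
        Xobs <- add_measurement_noise(X, d)
      }
      mu <- model$mean_function(X, beta_true)
      y <- if (model$outcome == "binary") {
        as.numeric(stats::runif(cfg$n_obs) < mu)
      } else {
        mu + beta_true[[model$error_sd_param]] * stats::rnorm(cfg$n_obs)
      }
      opts <- if (replicator == "anova") {
        list(factors = sk$factors)
      } else if (replicator == "ols") {
        list(include = sk$include %||% c("coefs", "mse"))
      } else list()
      probe <- prior_study(id, cfg$n_obs, replicator,
                           covariate_subset = sk$subset %||% character(),
                           options = opts)
      res <- replicate_study(probe, Xobs, y)
      if (res$converged) {
        published <- res$signatures
        moments <- list(mean = colMeans(X), cov = stats::cov(X))
        break
      }
    }
    if (is.null(published)) {
      stop(sprintf("scenario %d: study %d never produced a converged publication",
                   cfg$id, l), call. = FALSE)
    }
    noise_ch <- NULL
    if (cfg$delta_true > 0 || isTRUE(cfg$estimate_delta)) {
      noise_ch <- stats::setNames(paste0("delta_", colnames(X)), colnames(X))
    }
    studies[[l]] <- prior_study(
      id, cfg$n_obs, replicator,
      covariate_subset = sk$subset %||% character(),
      empirical_signatures = published,
      covariate_moments = moments,
      options = opts, noise_channels = noise_ch)
  }
  fit_model <- model
  if (cfg$delta_true > 0 || isTRUE(cfg$estimate_delta)) {
    fit_model <- augment_measurement_error(cfg, model)
  }
  list(model = fit_model, studies = studies, between = NULL,
       truth = list(beta = beta_true, moments = truth_mom,
                    delta = cfg$delta_true))
}

# Meta-model for the measurement-error extension: one noise-fraction
# parameter per predictor, bounded to [0, 1], appended to the base
# parameter vector. The mean function ignores them; the replication step
# perturbs the studies' simulated covariates with them.
augment_measurement_error <- function(cfg, model) {
  preds <- model$predictor_names
  terms <- switch(as.character(cfg$id),
    "1" = , "2" = list(character(0), "x1", "x2", "x3"),
    stop("the measurement-error extension targets the linear scenarios", call. = FALSE))
  deltas <- paste0("delta_", preds)
  bounds <- stats::setNames(rep(list(c(0, 1)), length(deltas)), deltas)
  polynomial_meta_model(terms, predictors = preds,
                        extra_params = deltas, bounds = bounds,
                        name = paste0(model$name, " + measurement error"))
}

generate_scenario7 <- function(cfg, model) {
  L <- length(cfg$n_within)
  tau <- sqrt(cfg$tau2); sig <- cfg$sigma_within
  effects <- numeric(L); wvars <- numeric(L)
  for (l in seq_len(L)) {
    set.seed(derive_seed(cfg$seed, "publish", l))
    theta <- cfg$mu_true + tau * stats::rnorm(1)
    y <- theta + sig * stats::rnorm(cfg$n_within[l])
    effects[l] <- mean(y)
    wvars[l] <- stats::var(y) / cfg$n_within[l]
  }
  sigs <- effect_size_signatures(effects, wvars)
  studies <- lapply(seq_len(L), function(l) {
    prior_study(sprintf("study%d", l), cfg$n_within[l], "effect_size",
                empirical_signatures = sigs[[l]])
  })
  between <- between_study_spec(
    var_effect = list(stat = "var", label = "effect"),
    empirical = c(var_effect = stats::var(effects)))
  list(model = model, studies = studies, between = between,
       truth = list(beta = cfg$beta_true, effects = effects,
                    within_vars = wvars))
}

scenario_plan <- function(cfg, rep) {
  simulation_plan(S = cfg$S, S_final = cfg$S_final,
                  n_weight_reps = cfg$n_weight_reps,
                  seed = derive_seed(cfg$seed, "fit", rep),
                  rounds = cfg$rounds, n_starts = cfg$n_starts,
                  jitter = cfg$jitter, lm_maxit = cfg$lm_maxit,
                  weight_at_start = cfg$weight_at_start)
}

#' Run a scenario's generate-fit-score replications
#'
#' Repeats `R` independent cycles of [generate_scenario()], [gma_fit()] and
#' scoring against the recorded truth, and aggregates per-parameter bias,
#' empirical standard deviation, mean analytical 95% confidence-interval
#' half-width, and coverage.
#'
#' @param config a [scenario_config()].
#' @return an object of class `recovery_report`: `summary` data frame (one
#'   row per parameter), `estimates` and `half_widths` matrices, `chi0`
#'   vector, `R`, `R_effective`, `truth`, and `flagged` (`TRUE` when more
#'   than 20% of fits failed).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  probe <- generate_scenario(`[[<-`(cfg, "seed", derive_seed(cfg$seed, "probe")))
  pn <- probe$model$param_names
  truth <- c(probe$truth$beta,
             if (cfg$delta_true >= 0 && length(setdiff(pn, names(probe$truth$beta)))) {
               stats::setNames(rep(cfg$delta_true,
                                   length(setdiff(pn, names(probe$truth$beta)))),
                               setdiff(pn, names(probe$truth$beta)))
             })[pn]
  R <- cfg$R
  est <- hw <- cov_ind <- matrix(NA_real_, R, length(pn), dimnames = list(NULL, pn))
  chi0 <- rep(NA_real_, R)
  conv <- rep(FALSE, R)
  for (r in seq_len(R)) {
    cfg_r <- `[[<-`(cfg, "seed", derive_seed(cfg$seed, "rep", r))
    out <- tryCatch({
      gen <- generate_scenario(cfg_r)
      fit <- gma_fit(gen$model, gen$studies, between = gen$between,
                     plan = scenario_plan(cfg, r))
      ci <- stats::confint(fit)
      list(beta = fit$beta_hat, hw = (ci[, 2] - ci[, 1]) / 2,
           cover = truth >= ci[, 1] & truth <= ci[, 2],
           chi0 = fit$chi0, conv = fit$converged)
    }, error = function(e) NULL)
    if (is.null(out)) next
    est[r, ] <- out$beta
    hw[r, ] <- out$hw
    cov_ind[r, ] <- out$cover
    chi0[r] <- out$chi0
    conv[r] <- out$conv
  }
  ok <- stats::complete.cases(est)
  summary <- data.frame(
    parameter = pn,
    truth = truth,
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    empirical_sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
    mean_ci_half_width = colMeans(hw[ok, , drop = FALSE]),
    coverage = colMeans(cov_ind[ok, , drop = FALSE]),
    row.names = NULL
  )
  structure(list(summary = summary, estimates = est, half_widths = hw,
                 chi0 = chi0, R = R, R_effective = sum(ok),
                 converged = conv, truth = truth,
                 flagged = sum(ok) < 0.8 * R, config = cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Scenario %d recovery over %d/%d successful replications\n",
              x$config$id, x$R_effective, x$R))
  print(transform(x$summary,
                  truth = round(truth, 3), mean_estimate = round(mean_estimate, 3),
                  bias = round(bias, 4), empirical_sd = round(empirical_sd, 4),
                  mean_ci_half_width = round(mean_ci_half_width, 4),
                  coverage = round(coverage, 3)))
  if (x$flagged) cat("  WARNING: more than 20% of fits failed\n")
  invisible(x)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' The classical moment estimator used as the scenario-7 comparator:
#' with inverse-variance weights `w_i = 1/v_i` and weighted mean `yw`,
#' `Q = sum w_i (y_i - yw)^2`,
#' `tau2 = max(0, (Q - (L-1)) / (sum w - sum w^2 / sum w))`, and the
#' summary effect is the `1/(v_i + tau2)`-weighted mean with standard
#' error from the summed random-effects weights.
#'
#' @param effects reported per-study effect sizes (at least two).
#' @param within_vars positive reported within-study variances.
#' @return list with `mu_hat`, `tau2_hat`, `se_mu`.
#' @export
dersimonian_laird <- function(effects, within_vars) {
  L <- length(effects)
  if (L < 2) stop("DerSimonian-Laird needs at least two studies", call. = FALSE)
  stopifnot(length(within_vars) == L, all(within_vars > 0))
  w <- 1 / within_vars
  yw <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - yw)^2)
  tau2 <- max(0, (Q - (L - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (within_vars + tau2)
  list(mu_hat = sum(wr * effects) / sum(wr),
       tau2_hat = tau2,
       se_mu = sqrt(1 / sum(wr)))
}

#' Compare the aggregation estimator with DerSimonian-Laird
#'
#' For each between-study variance level, generates `R` replications of the
#' scenario-7 random-effects truth (normally distributed within- and
#' between-study errors — the classical method's home turf), estimates the
#' summary effect and heterogeneity with both methods on the same published
#' effects, and reports paired root-mean-square errors.
#'
#' @param tau2_levels true between-study variances to sweep.
#' @param R replications per level.
#' @param seed master seed.
#' @param ... scenario-7 setting overrides (see [scenario_config()]).
#' @return data frame with one row per level: RMSEs for the summary effect
#'   and heterogeneity under both methods, their ratio, and the paired
#'   standard error of the mean squared-error difference for the summary
#'   effect.
#' @export
run_random_effects_comparison <- function(tau2_levels = c(0, 0.01, 0.025, 0.05, 0.1),
                                          R = 200, seed = 1, ...) {
  rows <- lapply(seq_along(tau2_levels), function(i) {
    t2 <- tau2_levels[i]
    cfg <- scenario_config(7, R = R, seed = derive_seed(seed, "level", i),
                           tau2 = t2, ...)
    err_g <- err_d <- errt_g <- errt_d <- rep(NA_real_, R)
    for (r in seq_len(R)) {
      cfg_r <- `[[<-`(cfg, "seed", derive_seed(cfg$seed, "rep", r))
      gen <- generate_scenario(cfg_r)
      dl <- dersimonian_laird(gen$truth$effects, gen$truth$within_vars)
      fit <- tryCatch(
        gma_fit(gen$model, gen$studies, between = gen$between,
                plan = scenario_plan(cfg, r), compute_inference = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      err_g[r] <- fit$beta_hat[["mu"]] - cfg$mu_true
      err_d[r] <- dl$mu_hat - cfg$mu_true
      errt_g[r] <- fit$beta_hat[["tau"]]^2 - t2
      errt_d[r] <- dl$tau2_hat - t2
    }
    ok <- !is.na(err_g)
    d <- err_g[ok]^2 - err_d[ok]^2
    data.frame(
      tau2 = t2,
      rmse_mu_gma = sqrt(mean(err_g[ok]^2)),
      rmse_mu_dl = sqrt(mean(err_d[ok]^2)),
      ratio_mu = sqrt(mean(err_g[ok]^2) / mean(err_d[ok]^2)),
      rmse_tau2_gma = sqrt(mean(errt_g[ok]^2)),
      rmse_tau2_dl = sqrt(mean(errt_d[ok]^2)),
      se_mse_diff_mu = stats::sd(d) / sqrt(sum(ok)),
      R_effective = sum(ok)
    )
  })
  do.call(rbind, rows)
}

#' Fit-versus-truth surface comparison for the nonlinear scenario
#'
#' Generates scenario 6 once, fits the nonlinear meta-model from the two
#' mis-specified linear prior studies' signatures, and correlates each
#' model's predicted surface with the true mean surface on a covariate
#' grid: the aggregated meta-model should track the truth better than
#' either linear prior.
#'
#' @param config a scenario-6 [scenario_config()].
#' @param grid_points grid resolution per axis.
#' @return list with `cor_meta`, `cor_priors` (per prior study), `fit`,
#'   and the generated scenario.
#' @export
scenario6_surface_comparison <- function(config = scenario_config(6),
                                         grid_points = 21) {
  stopifnot(config$id == 6)
  gen <- generate_scenario(config)
  fit <- gma_fit(gen$model, gen$studies, plan = scenario_plan(config, 1),
                 compute_inference = FALSE)
  mom <- gen$truth$moments
  sds <- sqrt(diag(mom$cov))
  gr <- expand.grid(
    time = seq(mom$mean[1] - 2 * sds[1], mom$mean[1] + 2 * sds[1],
               length.out = grid_points),
    temp = seq(mom$mean[2] - 2 * sds[2], mom$mean[2] + 2 * sds[2],
               length.out = grid_points))
  G <- as.matrix(gr)
  f_true <- gen$model$mean_function(G, gen$truth$beta)
  f_meta <- gen$model$mean_function(G, fit$beta_hat)
  if (stats::sd(f_meta) == 0) {
    # a degenerate flat fit tracks nothing
    f_meta <- f_meta + seq(0, 1e-12, length.out = length(f_meta))
  }
  cor_priors <- vapply(gen$studies, function(st) {
    cf <- st$empirical_signatures
    pred <- cf[["intercept"]]
    for (v in st$covariate_subset) pred <- pred + cf[[paste0("b:", v)]] * G[, v]
    stats::cor(pred, f_true)
  }, numeric(1))
  names(cor_priors) <- vapply(gen$studies, function(s) s$study_id, character(1))
  list(cor_meta = stats::cor(f_meta, f_true), cor_priors = cor_priors,
       fit = fit, scenario = gen)
}

#' Measurement-error extension of the linear scenario
#'
#' Sweeps a grid of true measurement-noise fractions `delta` (the same
#' fraction on every predictor), augments the meta-model with one
#' `[0, 1]`-bounded noise parameter per predictor, and reports how estimate
#' spread, confidence-interval width, coverage of the structural
#' coefficients, and the recovered noise fractions respond.
#'
#' @param delta_grid true noise fractions to sweep.
#' @param R replications per grid point.
#' @param seed master seed.
#' @param ... scenario-1 setting overrides.
#' @return data frame with one row per `delta`: mean CI half-width and
#'   empirical sd averaged over the structural coefficients, their joint
#'   coverage, and the median recovered `delta`.
#' @export
run_measurement_error_extension <- function(delta_grid = c(0, 0.25, 0.5),
                                            R = 30, seed = 1, ...) {
  rows <- lapply(seq_along(delta_grid), function(i) {
    d <- delta_grid[i]
    cfg <- scenario_config(1, R = R, seed = derive_seed(seed, "delta", i),
                           delta_true = d, estimate_delta = TRUE, ...)
    rep <- run_scenario(cfg)
    struct <- c("b0", "b_x1", "b_x2", "b_x3")
    deltas <- grep("^delta_", rep$summary$parameter, value = TRUE)
    s <- rep$summary
    data.frame(
      delta = d,
      mean_ci_half_width = mean(s$mean_ci_half_width[s$parameter %in% struct]),
      mean_empirical_sd = mean(s$empirical_sd[s$parameter %in% struct]),
      coverage = mean(s$coverage[s$parameter %in% struct]),
      median_delta_hat = stats::median(rep$estimates[, deltas], na.rm = TRUE),
      R_effective = rep$R_effective
    )
  })
  do.call(rbind, rows)
}
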