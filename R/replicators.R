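# Replicators: faithful re-runs of a prior study's statistical procedure
# (the signature functions h_l) on real or simulated data, plus the
# between-study statistics block.

# Coefficient labels for an intercept + subset design (guards the
# zero-length-recycling of paste0 for intercept-only studies).
coef_labels <- function(subset) {
  c("intercept", if (length(subset)) paste0("b:", subset))
}

#' Construct a replicator result
#'
#' @param signatures named numeric signature vector (`NULL` when the
#'   replication did not converge — never silently zero-filled).
#' @param converged logical flag.
#' @param notes diagnostic text (e.g. "separation detected").
#' @return an object of class `replicator_result`.
#' @export
replicator_result <- function(signatures = NULL, converged = TRUE, notes = "") {
  if (!converged && !is.null(signatures)) {
    stop("a non-converged replicator result must not carry signatures", call. = FALSE)
  }
  if (converged && !is_named_numeric(signatures)) {
    stop("signatures must be a named numeric vector", call. = FALSE)
  }
  structure(list(signatures = signatures, converged = converged, notes = notes),
            class = "replicator_result")
}

#' Ordinary-least-squares replicator
#'
#' Re-runs a prior study's linear regression of `y` on an intercept and the
#' selected columns and packages the statistics the study reported.
#' Coefficients are the least-squares solution; `mse = SSE / (n - p)` (the
#' residual mean square, i.e. the study's estimate of the error variance;
#' set `mse_df = "n"` for the uncorrected version); `r2` is the ordinary
#' coefficient of determination, defined as 0 for a constant outcome.
#'
#' @param X covariate table.
#' @param y numeric response vector.
#' @param subset ordered character vector of columns the study used.
#' @param include which statistics the study reported: any of `"coefs"`,
#'   `"mse"`, `"r2"`.
#' @param mse_df `"n-p"` (default) or `"n"` denominator for the MSE.
#' @return a [replicator_result()] with labels `intercept`, `b:<col>`, and
#'   optionally `mse`, `r2`; rank-deficient designs give a non-converged
#'   result.
#' @export
ols_signatures <- function(X, y, subset = colnames(X),
                           include = c("coefs", "mse"), mse_df = c("n-p", "n")) {
  X <- as.matrix(X)
  mse_df <- match.arg(mse_df)
  include <- match.arg(include, c("coefs", "mse", "r2"), several.ok = TRUE)
  Xd <- cbind(1, X[, subset, drop = FALSE])
  n <- length(y); p <- ncol(Xd)
  if (n <= p) {
    return(replicator_result(converged = FALSE, notes = "too few observations"))
  }
  qr_d <- qr(Xd)
  if (qr_d$rank < p) {
    return(replicator_result(converged = FALSE, notes = "rank-deficient design"))
  }
  coefs <- qr.coef(qr_d, y)
  resid <- y - Xd %*% coefs
  sse <- sum(resid^2)
  out <- numeric(0)
  if ("coefs" %in% include) {
    out <- c(out, stats::setNames(coefs, coef_labels(subset)))
  }
  if ("mse" %in% include) {
    out <- c(out, mse = sse / if (mse_df == "n-p") n - p else n)
  }
  if ("r2" %in% include) {
    sst <- sum((y - mean(y))^2)
    out <- c(out, r2 = if (sst > 0) 1 - sse / sst else 0)
  }
  replicator_result(out)
}

#' Logistic-regression replicator
#'
#' Re-runs a prior study's maximum-likelihood logistic regression of a
#' binary outcome on an intercept and the selected columns. Complete or
#' quasi-complete separation, a one-class outcome, or IRLS non-convergence
#' give a non-converged result with a note.
#'
#' @inheritParams ols_signatures
#' @param y binary (0/1) response vector.
#' @return a [replicator_result()] with labels `intercept`, `b:<col>`.
#' @export
logistic_signatures <- function(X, y, subset = colnames(X)) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) {
    return(replicator_result(converged = FALSE, notes = "single outcome class"))
  }
  Xd <- cbind(1, X[, subset, drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial(),
                                    control = stats::glm.control(epsilon = 1e-12,
                                                                 maxit = 50))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
    return(replicator_result(converged = FALSE, notes = "IRLS did not converge"))
  }
  coefs <- fit$coefficients
  if (max(abs(coefs)) > 15) {
    return(replicator_result(converged = FALSE, notes = "separation detected"))
  }
  replicator_result(stats::setNames(coefs, coef_labels(subset)))
}

#' Discretize a continuous variable at within-sample percentiles
#'
#' Assigns levels `1..k+1` by cutting at the sample percentiles named in
#' `cutpoints`; boundary values fall in the lower bin (left-closed
#' convention), and the assignment is invariant to monotone transforms of
#' the values.
#'
#' @param values numeric vector.
#' @param cutpoints strictly increasing percentiles in `(0, 100)`.
#' @return integer level vector.
#' @export
discretize <- function(values, cutpoints) {
  stopifnot(length(cutpoints) >= 1, all(cutpoints > 0), all(cutpoints < 100),
            !is.unsorted(cutpoints, strictly = TRUE))
  if (max(values) == min(values)) {
    stop("cannot discretize: all values are identical (degenerate binning)", call. = FALSE)
  }
  q <- stats::quantile(values, cutpoints / 100, names = FALSE, type = 7)
  lev <- rep(1L, length(values))
  for (ct in q) lev <- lev + (values > ct)
  lev
}

# Shared ANOVA machinery: given level assignments, return the signature
# vector. For one factor this is the classical one-way table (grand mean,
# per-level effects as group mean minus grand mean, treatment mean square,
# error mean square). For two factors an additive sum-to-zero-coded model
# is fitted by least squares; treatment mean squares are sequential
# (type I) in the order the factors are given.
anova_core <- function(y, levels_list, factor_names, include_interaction = FALSE) {
  n <- length(y)
  k <- vapply(levels_list, max, integer(1))
  for (f in seq_along(levels_list)) {
    if (length(unique(levels_list[[f]])) < k[f]) {
      return(replicator_result(converged = FALSE,
                               notes = sprintf("empty cell in factor %s", factor_names[f])))
    }
  }
  if (length(levels_list) == 1) {
    g <- levels_list[[1]]
    gm <- mean(y)
    m <- tapply(y, factor(g, levels = seq_len(k[1])), mean)
    nj <- tabulate(g, k[1])
    eff <- m - gm
    sst <- sum(nj * eff^2)
    sse <- sum((y - m[g])^2)
    sig <- c(gm, eff, sst / (k[1] - 1), sse / (n - k[1]))
    names(sig) <- c("grand_mean",
                    paste0("eff:", factor_names[1], ":", seq_len(k[1])),
                    paste0("mst:", factor_names[1]), "mse")
    return(replicator_result(sig))
  }
  # additive (or interacted) two-factor design, sum-to-zero contrasts
  f1 <- factor(levels_list[[1]], levels = seq_len(k[1]))
  f2 <- factor(levels_list[[2]], levels = seq_len(k[2]))
  C1 <- stats::contr.sum(k[1]); C2 <- stats::contr.sum(k[2])
  Z1 <- C1[as.integer(f1), , drop = FALSE]
  Z2 <- C2[as.integer(f2), , drop = FALSE]
  Zd <- cbind(1, Z1, Z2)
  df_int <- 0L
  if (include_interaction) {
    ZI <- matrix(0, n, (k[1] - 1) * (k[2] - 1))
    col <- 0
    for (j in seq_len(k[2] - 1)) for (i in seq_len(k[1] - 1)) {
      col <- col + 1
      ZI[, col] <- Z1[, i] * Z2[, j]
    }
    Zd <- cbind(Zd, ZI)
    df_int <- ncol(ZI)
  }
  qr_d <- qr(Zd)
  if (qr_d$rank < ncol(Zd)) {
    return(replicator_result(converged = FALSE, notes = "aliased factor design"))
  }
  coefs <- qr.coef(qr_d, y)
  # sequential sums of squares via the ordered QR projection
  Q <- qr.Q(qr_d)
  proj2 <- drop(crossprod(Q, y))^2
  i1 <- 1 + seq_len(k[1] - 1)
  i2 <- 1 + (k[1] - 1) + seq_len(k[2] - 1)
  ss1 <- sum(proj2[i1]); ss2 <- sum(proj2[i2])
  sse <- sum(y^2) - sum(proj2)
  dfe <- n - ncol(Zd)
  eff1 <- drop(C1 %*% coefs[i1])
  eff2 <- drop(C2 %*% coefs[i2])
  sig <- c(coefs[1], eff1, eff2, ss1 / (k[1] - 1), ss2 / (k[2] - 1), sse / dfe)
  names(sig) <- c("grand_mean",
                  paste0("eff:", factor_names[1], ":", seq_len(k[1])),
                  paste0("eff:", factor_names[2], ":", seq_len(k[2])),
                  paste0("mst:", factor_names[1]),
                  paste0("mst:", factor_names[2]), "mse")
  if (include_interaction) {
    iI <- 1 + (k[1] - 1) + (k[2] - 1) + seq_len(df_int)
    sig <- c(sig, `mst:interaction` = sum(proj2[iI]) / df_int)
  }
  replicator_result(sig)
}

#' ANOVA replicator on discretized factors
#'
#' Re-runs a prior analysis-of-variance study: each named continuous column
#' is categorized at within-sample percentiles ([discretize()]) and the
#' study's reported statistics are recomputed — the grand mean, sum-to-zero
#' level effects for every factor, one treatment mean square (MST) per
#' factor, and the error mean square (MSE). This inventory yields 6
#' signatures for a 3-level one-way design, 7 for a 4-level one-way design,
#' and 11 for the additive two-factor 3 x 4 design. With two factors the
#' mean squares are sequential (type I) in the order given.
#'
#' @param X covariate table.
#' @param y numeric response vector.
#' @param factors list of `list(column =, cutpoints =)` specifications.
#' @param include_interaction add the interaction treatment mean square
#'   (two-factor designs only; the classic additive replication leaves this
#'   `FALSE`).
#' @return a [replicator_result()]; designs with empty cells do not
#'   converge.
#' @export
anova_signatures <- function(X, y, factors, include_interaction = FALSE) {
  X <- as.matrix(X)
  stopifnot(length(factors) %in% 1:2)
  levels_list <- lapply(factors, function(f) discretize(X[, f$column], f$cutpoints))
  anova_core(y, levels_list,
             vapply(factors, function(f) f$column, character(1)),
             include_interaction)
}

#' Package reported effect sizes as signatures
#'
#' Passthrough packaging for classical meta-analysis inputs: each study's
#' reported effect size and within-study variance become a labeled pair of
#' signatures (`effect`, `within_var`), so `L` studies yield `2L`
#' signatures.
#'
#' @param effects numeric vector of reported effect sizes.
#' @param within_vars positive numeric vector of reported within-study
#'   variances, same length.
#' @return list of named signature vectors, one per study.
#' @export
effect_size_signatures <- function(effects, within_vars) {
  if (length(effects) == 0) stop("no effect sizes supplied", call. = FALSE)
  stopifnot(length(effects) == length(within_vars))
  if (any(within_vars <= 0)) {
    stop("within-study variances must be strictly positive", call. = FALSE)
  }
  lapply(seq_along(effects), function(i) {
    c(effect = effects[i], within_var = within_vars[i])
  })
}

#' Declare between-study signatures
#'
#' Between-study signatures are statistics computed across the studies'
#' (simulated or published) per-study signatures — e.g. the sample variance
#' of a named effect across studies, the classical between-study
#' heterogeneity target.
#'
#' @param ... named definitions `name = list(stat =, label =)` where `stat`
#'   is one of `"var"`, `"sd"`, `"mean"` and `label` the per-study signature
#'   it aggregates.
#' @param empirical named numeric vector of the published values of these
#'   statistics.
#' @return an object of class `between_study_spec`.
#' @export
between_study_spec <- function(..., empirical = NULL) {
  defs <- list(...)
  stopifnot(length(defs) >= 1, !is.null(names(defs)), all(nzchar(names(defs))))
  for (d in defs) {
    stopifnot(d$stat %in% c("var", "sd", "mean"), is.character(d$label))
  }
  if (!is.null(empirical)) {
    stopifnot(is_named_numeric(empirical), setequal(names(empirical), names(defs)))
    empirical <- empirical[names(defs)]
  }
  structure(list(definitions = defs, empirical = empirical),
            class = "between_study_spec")
}

#' Compute between-study statistics from per-study signatures
#'
#' @param per_study list of named per-study signature vectors (one per
#'   study, all containing the referenced labels).
#' @param spec a [between_study_spec()].
#' @return named numeric vector, one value per definition.
#' @export
between_study_statistics <- function(per_study, spec) {
  stopifnot(inherits(spec, "between_study_spec"))
  out <- numeric(length(spec$definitions))
  names(out) <- names(spec$definitions)
  for (nm in names(spec$definitions)) {
    d <- spec$definitions[[nm]]
    vals <- vapply(per_study, function(s) {
      if (!d$label %in% names(s)) {
        stop(sprintf("between-study statistic '%s' references label '%s' absent from a study",
                     nm, d$label), call. = FALSE)
      }
      s[[d$label]]
    }, numeric(1))
    if (d$stat %in% c("var", "sd") && length(vals) < 2) {
      stop(sprintf("between-study %s of '%s' is undefined with a single study",
                   d$stat, d$label), call. = FALSE)
    }
    out[nm] <- switch(d$stat,
                      var = stats::var(vals),
                      sd = stats::sd(vals),
                      mean = mean(vals))
  }
  out
}
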