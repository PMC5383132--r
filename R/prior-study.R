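# The prior-study type: one published study, carrying everything needed to
# re-run its procedure on simulated data and the signature values it
# actually reported.

#' Declare a prior study
#'
#' A prior study bundles a published study's sample size, the subset of
#' explanatory variables it used, the statistical procedure it ran (its
#' replicator), its published signature vector, and — optionally — its
#' reported covariate moments and the measurement-noise channels linking
#' covariate columns to noise parameters of the meta-model.
#'
#' @param study_id unique study label.
#' @param n_obs the study's sample size `n_l` (for effect-size studies, the
#'   within-study number of observations behind the reported effect).
#' @param replicator one of `"ols"`, `"logistic"`, `"anova"`,
#'   `"effect_size"`.
#' @param covariate_subset ordered predictor subset the study used (empty
#'   for effect-size studies).
#' @param empirical_signatures named numeric vector of the published
#'   signature values; labels must match exactly what the replicator
#'   produces for this design (checked).
#' @param covariate_moments optional list with `mean` (named vector) and
#'   `cov` (matrix) — or `var` vector — of explanatory variables as reported
#'   by the study.
#' @param options replicator options: for `"ols"`, `include` (any of
#'   `"coefs"`, `"mse"`, `"r2"`) and `mse_df`; for `"anova"`, `factors`
#'   (list of `list(column =, cutpoints =)`) and `include_interaction`.
#' @param noise_channels named character vector mapping covariate columns to
#'   meta-model parameter names holding their measurement-noise fractions.
#' @return an object of class `prior_study`.
#' @export
prior_study <- function(study_id, n_obs,
                        replicator = c("ols", "logistic", "anova", "effect_size"),
                        covariate_subset = character(),
                        empirical_signatures = NULL,
                        covariate_moments = NULL,
                        options = list(),
                        noise_channels = NULL) {
  replicator <- match.arg(replicator)
  stopifnot(is.character(study_id), length(study_id) == 1,
            is.numeric(n_obs), n_obs >= 1)
  if (replicator == "ols") {
    options$include <- options$include %||% c("coefs", "mse")
    options$mse_df <- options$mse_df %||% "n-p"
  }
  if (replicator == "anova") {
    if (is.null(options$factors)) {
      stop("anova studies need options$factors (list of column/cutpoints specs)", call. = FALSE)
    }
    options$include_interaction <- options$include_interaction %||% FALSE
  }
  st <- structure(list(
    study_id = study_id, n_obs = as.integer(n_obs), replicator = replicator,
    covariate_subset = covariate_subset,
    empirical_signatures = empirical_signatures,
    covariate_moments = covariate_moments,
    options = options, noise_channels = noise_channels
  ), class = "prior_study")
  dim_rep <- replicated_model_dim(st)
  if (st$n_obs < dim_rep) {
    stop(sprintf("study '%s': n_obs (%d) is below the dimension of the replicated model (%d)",
                 study_id, st$n_obs, dim_rep), call. = FALSE)
  }
  if (!is.null(empirical_signatures)) {
    if (!is_named_numeric(empirical_signatures)) {
      stop("empirical_signatures must be a named numeric vector", call. = FALSE)
    }
    expected <- study_signature_labels(st)
    if (!identical(names(empirical_signatures), expected)) {
      stop(sprintf("study '%s': empirical signature labels (%s) do not match the replicator's output (%s)",
                   study_id, paste(names(empirical_signatures), collapse = ", "),
                   paste(expected, collapse = ", ")), call. = FALSE)
    }
  }
  st
}

replicated_model_dim <- function(study) {
  switch(study$replicator,
    ols = ,
    logistic = length(study$covariate_subset) + 1L,
    anova = sum(vapply(study$options$factors,
                       function(f) length(f$cutpoints), integer(1))) + 1L,
    effect_size = 2L)
}

#' Signature labels a study's replicator produces
#'
#' The label inventory is fully determined by the study declaration, so the
#' stacking order of signatures (study order, then label order) is known
#' before any simulation.
#'
#' @param study a [prior_study()].
#' @return character vector of labels.
#' @export
study_signature_labels <- function(study) {
  switch(study$replicator,
    ols = {
      lab <- character(0)
      if ("coefs" %in% study$options$include) {
        lab <- c(lab, coef_labels(study$covariate_subset))
      }
      if ("mse" %in% study$options$include) lab <- c(lab, "mse")
      if ("r2" %in% study$options$include) lab <- c(lab, "r2")
      lab
    },
    logistic = coef_labels(study$covariate_subset),
    anova = {
      facs <- study$options$factors
      lab <- "grand_mean"
      for (f in facs) {
        k <- length(f$cutpoints) + 1L
        lab <- c(lab, paste0("eff:", f$column, ":", seq_len(k)))
      }
      lab <- c(lab, paste0("mst:", vapply(facs, function(f) f$column, character(1))), "mse")
      if (isTRUE(study$options$include_interaction)) lab <- c(lab, "mst:interaction")
      lab
    },
    effect_size = c("effect", "within_var"))
}

#' @export
print.prior_study <- function(x, ...) {
  cat(sprintf("Prior study '%s': %s replicator, n = %d\n",
              x$study_id, x$replicator, x$n_obs))
  if (length(x$covariate_subset)) {
    cat("  covariates:", paste(x$covariate_subset, collapse = ", "), "\n")
  }
  if (!is.null(x$empirical_signatures)) {
    cat(sprintf("  %d published signatures\n", length(x$empirical_signatures)))
  }
  invisible(x)
}

# Run a study's replicator on (possibly noisy) data. The generic slow path;
# the estimator uses precomputed fast paths that must agree with this.
replicate_study <- function(study, X, y) {
  switch(study$replicator,
    ols = ols_signatures(X, y, study$covariate_subset,
                         include = study$options$include,
                         mse_df = study$options$mse_df),
    logistic = logistic_signatures(X, y, study$covariate_subset),
    anova = anova_signatures(X, y, study$options$factors,
                             study$options$include_interaction),
    effect_size = replicator_result(c(effect = mean(y),
                                      within_var = stats::var(y) / length(y))))
}
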