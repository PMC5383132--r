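# Covariate samplers: produce simulated explanatory-variable tables X^s
# consistent with what prior studies report (an empirical table, reported
# means/covariances, or a base table affinely calibrated to reported
# moments), plus optional measurement noise.

#' Sample covariates from reported moments
#'
#' Draws `n` rows from a multivariate normal with the given mean vector and
#' covariance matrix. Covariances that are symmetric but numerically
#' indefinite (smallest eigenvalue above `-1e-8` relative) are projected to
#' the nearest positive semi-definite matrix; clearly indefinite input is an
#' error reporting the most negative eigenvalue.
#'
#' @param mean named numeric mean vector; names become column names.
#' @param cov covariance matrix conformable with `mean`.
#' @param n number of rows.
#' @param seed optional integer seed (set for reproducible tables).
#' @return an `n` x `length(mean)` numeric matrix.
#' @export
sample_from_moments <- function(mean, cov, n, seed = NULL) {
  stopifnot(n >= 1, length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  cov <- project_psd(as.matrix(cov), what = "covariate covariance matrix")
  if (!is.null(seed)) set.seed(seed)
  X <- MASS::mvrnorm(n, mu = as.numeric(mean), Sigma = cov)
  if (n == 1) X <- matrix(X, nrow = 1)
  colnames(X) <- names(mean) %||% colnames(cov)
  X
}

#' Calibrate an affine sampler to reported moments
#'
#' Computes the per-column affine transform (shift, scale) that maps a base
#' covariate table onto given target means and variances exactly:
#' `scale = sqrt(target_var / base_var)`, `shift = target_mean -
#' scale * base_mean`. Being monotone per column, the transform preserves
#' the base table's rank correlations.
#'
#' @param base_table base covariate table (matrix or data frame) with
#'   strictly positive column variances wherever `target_var > 0`.
#' @param target_mean,target_var named numeric vectors of reported moments;
#'   names select the columns to calibrate.
#' @return an object of class `gma_calibration` with `shift` and `scale`
#'   vectors; apply it with [apply_calibration()].
#' @export
calibrate_sampler <- function(base_table, target_mean, target_var) {
  X <- as.matrix(base_table)
  cols <- names(target_mean)
  stopifnot(!is.null(cols), identical(cols, names(target_var)))
  missing <- setdiff(cols, colnames(X))
  if (length(missing)) {
    stop(sprintf("base table lacks column(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  bm <- colMeans(X[, cols, drop = FALSE])
  bv <- apply(X[, cols, drop = FALSE], 2, stats::var)
  if (any(bv <= 0 & target_var > 0)) {
    bad <- cols[which(bv <= 0 & target_var > 0)[1]]
    stop(sprintf("base column '%s' has zero variance; cannot scale to a positive target variance", bad),
         call. = FALSE)
  }
  scale <- ifelse(bv > 0, sqrt(target_var / bv), 0)
  shift <- target_mean - scale * bm
  structure(list(columns = cols, shift = shift, scale = scale),
            class = "gma_calibration")
}

#' Apply a calibration transform to a covariate table
#'
#' @param table covariate table.
#' @param calibration result of [calibrate_sampler()].
#' @return the table with calibrated columns transformed; other columns
#'   untouched.
#' @export
apply_calibration <- function(table, calibration) {
  stopifnot(inherits(calibration, "gma_calibration"))
  X <- as.matrix(table)
  for (nm in calibration$columns) {
    X[, nm] <- calibration$shift[[nm]] + calibration$scale[[nm]] * X[, nm]
  }
  X
}

#' Add simulated measurement noise to covariate columns
#'
#' Adds independent normal noise with standard deviation `delta * sd(column)`
#' to each named column — `delta` is the noise level expressed as a fraction
#' of the column's actual (sample) standard deviation. Unnamed columns are
#' returned bit-identical.
#'
#' @param X covariate table.
#' @param delta named non-negative numeric vector of noise fractions, one
#'   entry per noisy column.
#' @param seed optional integer seed.
#' @return the table with noisy columns perturbed.
#' @export
add_measurement_noise <- function(X, delta, seed = NULL) {
  X <- as.matrix(X)
  if (length(delta) == 0) return(X)
  stopifnot(is_named_numeric(delta))
  if (any(delta < 0)) stop("measurement-noise fractions must be non-negative", call. = FALSE)
  unknown <- setdiff(names(delta), colnames(X))
  if (length(unknown)) {
    stop(sprintf("noise requested for unknown column(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  for (nm in names(delta)) {
    if (delta[[nm]] > 0) {
      X[, nm] <- X[, nm] + stats::rnorm(n, sd = delta[[nm]] * stats::sd(X[, nm]))
    }
  }
  X
}

#' Declare a covariate source
#'
#' A covariate source tells the estimator how to produce each study's
#' simulated explanatory-variable table:
#' \describe{
#'   \item{`"moments"`}{multivariate-normal draws from moments pooled across
#'     the studies' reported mean vectors and covariance matrices (the
#'     default when studies carry `covariate_moments`);}
#'   \item{`"table"`}{rows resampled with replacement from a user-supplied
#'     empirical table (e.g. a public database of the explanatory
#'     variables);}
#'   \item{`"calibrated"`}{rows resampled from the base table, then affinely
#'     transformed per study so each study's reported covariate means and
#'     variances are reproduced exactly.}
#' }
#'
#' @param kind one of `"moments"`, `"table"`, `"calibrated"`.
#' @param table base covariate table for the `"table"` and `"calibrated"`
#'   kinds.
#' @param mean,cov optional explicit pooled moments for the `"moments"` kind
#'   (otherwise pooled from the studies).
#' @return an object of class `covariate_source`.
#' @export
covariate_source <- function(kind = c("moments", "table", "calibrated"),
                             table = NULL, mean = NULL, cov = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("table", "calibrated") && is.null(table)) {
    stop(sprintf("covariate source '%s' requires a base table", kind), call. = FALSE)
  }
  if (!is.null(table)) table <- as.matrix(table)
  structure(list(kind = kind, table = table, mean = mean, cov = cov),
            class = "covariate_source")
}

#' Pool covariate moments reported by several studies
#'
#' Averages the studies' reported mean vectors and covariance matrices,
#' weighting by study sample size, entry by entry over the predictors each
#' study reports. Entries reported by no study are filled with zero
#' covariance; the pooled covariance is projected to the nearest positive
#' semi-definite matrix.
#'
#' @param studies list of [prior_study()] objects with `covariate_moments`.
#' @param predictors character vector of all predictor names.
#' @return list with pooled `mean` and `cov`.
#' @export
pool_study_moments <- function(studies, predictors) {
  p <- length(predictors)
  msum <- stats::setNames(numeric(p), predictors); mw <- msum
  csum <- matrix(0, p, p, dimnames = list(predictors, predictors)); cw <- csum
  any_found <- FALSE
  for (st in studies) {
    mo <- st$covariate_moments
    if (is.null(mo)) next
    any_found <- TRUE
    nm <- intersect(names(mo$mean), predictors)
    if (length(nm) == 0) next
    w <- st$n_obs %||% 1
    msum[nm] <- msum[nm] + w * mo$mean[nm]
    mw[nm] <- mw[nm] + w
    cm <- as.matrix(mo$cov)
    if (is.null(dimnames(cm))) dimnames(cm) <- list(names(mo$mean), names(mo$mean))
    csum[nm, nm] <- csum[nm, nm] + w * cm[nm, nm]
    cw[nm, nm] <- cw[nm, nm] + w
  }
  if (!any_found) {
    stop("no study reports covariate moments; supply a covariate table instead", call. = FALSE)
  }
  if (any(mw == 0)) {
    stop(sprintf("no study reports moments for predictor(s): %s",
                 paste(predictors[mw == 0], collapse = ", ")), call. = FALSE)
  }
  mean <- msum / mw
  cov <- csum
  nz <- cw > 0
  cov[nz] <- csum[nz] / cw[nz]
  list(mean = mean, cov = project_psd(cov, what = "pooled covariate covariance"))
}

# Resolve a covariate source into a per-study sampling closure
# function(study, n) -> matrix. Seeding is handled by the caller (draws are
# taken from the ambient RNG stream so that simulation contexts control
# reproducibility).
resolve_covariate_source <- function(source, studies, predictors) {
  if (length(predictors) == 0) {
    # covariate-free meta-models (e.g. random-effects): empty design
    return(function(study, n) matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.null(source)) source <- covariate_source("moments")
  stopifnot(inherits(source, "covariate_source"))
  switch(source$kind,
    moments = {
      pooled <- if (!is.null(source$mean)) {
        list(mean = source$mean, cov = project_psd(as.matrix(source$cov),
                                                   what = "covariate covariance"))
      } else {
        pool_study_moments(studies, predictors)
      }
      R <- chol(pooled$cov + diag(1e-12, length(pooled$mean)))
      mu <- pooled$mean
      function(study, n) {
        Z <- matrix(stats::rnorm(n * length(mu)), n)
        X <- Z %*% R
        X <- sweep(X, 2, mu, "+")
        colnames(X) <- predictors
        X
      }
    },
    table = {
      tab <- source$table[, predictors, drop = FALSE]
      function(study, n) {
        tab[sample.int(nrow(tab), n, replace = TRUE), , drop = FALSE]
      }
    },
    calibrated = {
      tab <- source$table[, predictors, drop = FALSE]
      cals <- lapply(studies, function(st) {
        mo <- st$covariate_moments
        if (is.null(mo)) return(NULL)
        tv <- mo$var %||% diag(as.matrix(mo$cov))
        names(tv) <- names(mo$mean)
        calibrate_sampler(tab, mo$mean, tv)
      })
      names(cals) <- vapply(studies, function(s) s$study_id, character(1))
      function(study, n) {
        X <- tab[sample.int(nrow(tab), n, replace = TRUE), , drop = FALSE]
        cal <- cals[[study$study_id]]
        if (!is.null(cal)) X <- apply_calibration(X, cal)
        X
      }
    })
}
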