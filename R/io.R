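# Configuration, file formats and report rendering: YAML/JSON run configs,
# CSV signature and moment tables, JSON + text fit reports, and the
# multi-candidate MSC comparison that backs the command-line interface
# (inst/cli/gma).

plan_defaults <- list(S = 50, S_final = 500, n_weight_reps = 1000,
                      ridge = 1e-6, seed = 1, rounds = 3, n_starts = 2,
                      jitter = 0.5, nm_maxit = 400, lm_maxit = 50,
                      retry_limit = 5, penalty = 1000)
inference_defaults <- list(bootstrap = 0, loo = FALSE, level = 0.95)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)",
                 where, paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, rejects unknown keys, fills in
#' every default (simulation effort `S = 50`, `rounds = 3`, bootstrap
#' `B = 500` when enabled, ...), resolves referenced CSV files relative to
#' the config's directory, and returns a fully materialized configuration —
#' nothing is left to be decided at computation time.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration.
#' @return a validated named list of class `run_config` with blocks
#'   `model`, `studies`, `between` (optional), `sampler`, `plan`,
#'   `inference`, `output`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  base_dir <- dirname(normalizePath(path))
  check_keys(cfg, c("model", "models", "studies", "signatures_csv", "between",
                    "sampler", "plan", "inference", "output"), "config")
  if (is.null(cfg$model) && is.null(cfg$models)) {
    stop("config must declare a 'model' (or 'models') block", call. = FALSE)
  }
  if (is.null(cfg$studies) || length(cfg$studies) == 0) {
    stop("config must declare at least one study", call. = FALSE)
  }
  model_allowed <- c("kind", "name", "predictors", "terms", "coef_names",
                     "error_sd_param", "extra_params", "bounds", "init")
  for (m in c(list(cfg$model), cfg$models)) {
    if (!is.null(m)) check_keys(m, model_allowed, "model block")
  }
  shared_sigs <- NULL
  if (!is.null(cfg$signatures_csv)) {
    shared_sigs <- read_signature_table(resolve_path(cfg$signatures_csv, base_dir))
  }
  for (i in seq_along(cfg$studies)) {
    st <- cfg$studies[[i]]
    check_keys(st, c("study_id", "n_obs", "replicator", "covariate_subset",
                     "options", "signatures", "moments", "moments_csv",
                     "noise_channels"), sprintf("study %d", i))
    for (k in c("study_id", "n_obs", "replicator")) {
      if (is.null(st[[k]])) {
        stop(sprintf("study %d is missing required key '%s'", i, k), call. = FALSE)
      }
    }
    if (is.null(st$signatures)) {
      if (is.null(shared_sigs) || is.null(shared_sigs[[st$study_id]])) {
        stop(sprintf("study '%s' has no signatures (inline or via signatures_csv)",
                     st$study_id), call. = FALSE)
      }
      cfg$studies[[i]]$signatures <- as.list(shared_sigs[[st$study_id]])
    }
    if (!is.null(st$moments_csv)) {
      cfg$studies[[i]]$moments <- read_moments_csv(resolve_path(st$moments_csv, base_dir))
      cfg$studies[[i]]$moments_csv <- NULL
    }
  }
  check_keys(cfg$plan %||% list(), c(names(plan_defaults), "weight_floor"), "plan block")
  cfg$plan <- utils::modifyList(plan_defaults, cfg$plan %||% list())
  check_keys(cfg$inference %||% list(), names(inference_defaults), "inference block")
  cfg$inference <- utils::modifyList(inference_defaults, cfg$inference %||% list())
  if (!is.null(cfg$sampler)) {
    check_keys(cfg$sampler, c("kind", "table_csv"), "sampler block")
    if (!is.null(cfg$sampler$table_csv)) {
      cfg$sampler$table_csv <- resolve_path(cfg$sampler$table_csv, base_dir)
    }
  }
  if (!is.null(cfg$between)) {
    for (nm in names(cfg$between)) {
      check_keys(cfg$between[[nm]], c("stat", "label", "empirical"),
                 sprintf("between-study statistic '%s'", nm))
    }
  }
  cfg$output <- cfg$output %||% list()
  check_keys(cfg$output, c("fit_json", "fit_txt"), "output block")
  structure(cfg, class = "run_config", base_dir = base_dir)
}

resolve_path <- function(p, base_dir) {
  if (file.exists(p)) return(p)
  p2 <- file.path(base_dir, p)
  if (!file.exists(p2)) stop(sprintf("referenced file not found: %s", p), call. = FALSE)
  p2
}

#' Read a published-signature CSV
#'
#' Expects columns `study_id,label,value` with a header row; labels are
#' whitespace-trimmed; duplicate `(study, label)` pairs and non-numeric
#' values are errors naming the offending row.
#'
#' @param path CSV path.
#' @return named list of named numeric signature vectors, one per study,
#'   in file order.
#' @export
read_signature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(tab) == 0) stop(sprintf("signature file '%s' is empty", path), call. = FALSE)
  need <- c("study_id", "label", "value")
  if (!all(need %in% names(tab))) {
    stop(sprintf("signature file must have columns %s", paste(need, collapse = ",")),
         call. = FALSE)
  }
  tab$label <- trimws(tab$label)
  tab$study_id <- trimws(tab$study_id)
  vals <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric signature value at row %d of '%s'",
                 which(is.na(vals))[1], path), call. = FALSE)
  }
  key <- paste(tab$study_id, tab$label, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate (study, label) pair: %s", gsub("\r", " / ", d)), call. = FALSE)
  }
  out <- list()
  for (id in unique(tab$study_id)) {
    sel <- tab$study_id == id
    out[[id]] <- stats::setNames(vals[sel], tab$label[sel])
  }
  out
}

#' Read a covariate-moments CSV
#'
#' A moments file has a header row of predictor names, a first data row
#' holding the mean vector, and the following `p` rows holding the
#' covariance block.
#'
#' @param path CSV path.
#' @return list with named `mean` and `cov`.
#' @export
read_moments_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- ncol(tab)
  if (nrow(tab) != p + 1) {
    stop(sprintf("moments file '%s' must have 1 mean row + %d covariance rows", path, p),
         call. = FALSE)
  }
  m <- as.numeric(tab[1, ])
  names(m) <- names(tab)
  cv <- as.matrix(tab[-1, , drop = FALSE])
  dimnames(cv) <- list(names(tab), names(tab))
  list(mean = m, cov = cv)
}

# Turn the validated config blocks into package objects.
build_model_from_config <- function(m) {
  kind <- m$kind %||% "polynomial"
  terms <- lapply(m$terms, function(t) if (length(t) == 0) character(0) else as.character(unlist(t)))
  bounds <- lapply(m$bounds, as.numeric)
  switch(kind,
    polynomial = polynomial_meta_model(
      terms, predictors = as.character(m$predictors),
      coef_names = m$coef_names,
      error_sd_param = if (is.null(m$error_sd_param)) "sigma" else
        if (identical(m$error_sd_param, "none")) NULL else m$error_sd_param,
      extra_params = as.character(m$extra_params %||% character()),
      bounds = bounds, name = m$name %||% "polynomial"),
    logistic = logistic_meta_model(
      terms, predictors = as.character(m$predictors),
      coef_names = m$coef_names,
      extra_params = as.character(m$extra_params %||% character()),
      bounds = bounds, name = m$name %||% "logistic"),
    random_effects = random_effects_meta_model(name = m$name %||% "random-effects"),
    stop(sprintf("unknown model kind '%s'", kind), call. = FALSE))
}

build_study_from_config <- function(st) {
  opts <- st$options %||% list()
  if (!is.null(opts$factors)) {
    opts$factors <- lapply(opts$factors, function(f) {
      list(column = f$column, cutpoints = as.numeric(unlist(f$cutpoints)))
    })
  }
  if (!is.null(opts$include)) opts$include <- as.character(unlist(opts$include))
  mo <- st$moments
  if (!is.null(mo)) {
    mean <- unlist(mo$mean)
    cv <- mo$cov
    if (!is.null(cv) && !is.matrix(cv)) {
      cv <- do.call(rbind, lapply(cv, as.numeric))
      dimnames(cv) <- list(names(mean), names(mean))
    }
    mo <- list(mean = mean, cov = cv, var = if (!is.null(mo$var)) unlist(mo$var))
  }
  prior_study(
    study_id = st$study_id, n_obs = st$n_obs, replicator = st$replicator,
    covariate_subset = as.character(st$covariate_subset %||% character()),
    empirical_signatures = unlist(st$signatures),
    covariate_moments = mo, options = opts,
    noise_channels = if (!is.null(st$noise_channels)) unlist(st$noise_channels))
}

build_between_from_config <- function(b) {
  if (is.null(b)) return(NULL)
  defs <- lapply(b, function(d) list(stat = d$stat, label = d$label))
  emp <- vapply(b, function(d) as.numeric(d$empirical), numeric(1))
  do.call(between_study_spec, c(defs, list(empirical = emp)))
}

#' Execute a run configuration
#'
#' Builds the meta-model, studies, sampler and plan declared in a
#' [load_run_config()] result, fits the model, optionally runs the
#' bootstrap and leave-one-study-out diagnostics, and writes the requested
#' reports.
#'
#' @param config a `run_config` (or a path, which is loaded first).
#' @param seed optional master-seed override.
#' @return the [gma_fit()], invisibly, with any `bootstrap`/`loo` results
#'   attached.
#' @export
run_gma_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  model <- build_model_from_config(config$model %||% config$models[[1]])
  studies <- lapply(config$studies, build_study_from_config)
  between <- build_between_from_config(config$between)
  pl <- config$plan
  if (!is.null(seed)) pl$seed <- seed
  plan <- do.call(simulation_plan, pl)
  source <- NULL
  if (!is.null(config$sampler)) {
    tab <- if (!is.null(config$sampler$table_csv)) {
      utils::read.csv(config$sampler$table_csv)
    }
    source <- covariate_source(config$sampler$kind %||% "moments", table = tab)
  }
  beta0 <- if (!is.null(config$model$init)) unlist(config$model$init)
  fit <- gma_fit(model, studies, between = between, plan = plan,
                 beta0 = beta0, source = source)
  if (config$inference$bootstrap > 0) {
    fit$bootstrap <- bootstrap_ci(fit, B = config$inference$bootstrap,
                                  level = config$inference$level)
  }
  if (isTRUE(config$inference$loo)) {
    fit$loo <- loo_influence(model, studies, plan = plan, between = between,
                             source = source, fit = fit)
  }
  if (!is.null(config$output$fit_json)) {
    write_fit_report(fit, config$output$fit_json, config$output$fit_txt)
  }
  invisible(fit)
}

#' Write machine- and human-readable fit reports
#'
#' The JSON report carries the estimates at full precision (re-reading it
#' reproduces them bit-exactly), the parameter covariance, goodness of fit,
#' model-selection criterion, per-study error contributions, the seeds and
#' the resolved plan — everything needed to reproduce the run. The optional
#' text report renders the estimate +/- confidence-interval table.
#'
#' @param fit a [gma_fit()].
#' @param json_path output path for the JSON report.
#' @param txt_path optional output path for the text report.
#' @return `json_path`, invisibly.
#' @export
write_fit_report <- function(fit, json_path, txt_path = NULL) {
  stopifnot(inherits(fit, "gma_fit"))
  ci <- if (!is.null(fit$covariance)) stats::confint(fit)
  report <- list(
    model = fit$model$name,
    parameters = names(fit$beta_hat),
    estimates = as.list(fit$beta_hat),
    se = if (!is.null(fit$se)) as.list(stats::setNames(fit$se, names(fit$beta_hat))),
    ci_lower = if (!is.null(ci)) as.list(stats::setNames(ci[, 1], names(fit$beta_hat))),
    ci_upper = if (!is.null(ci)) as.list(stats::setNames(ci[, 2], names(fit$beta_hat))),
    covariance = fit$covariance,
    chi0 = fit$chi0, dof = fit$dof, p_value = fit$p_value, msc = fit$msc,
    objective = fit$objective,
    per_study_errors = lapply(fit$per_study_errors, as.list),
    converged = fit$converged,
    failures = fit$failures,
    plan = unclass(fit$plan),
    studies = lapply(fit$studies, function(s) {
      list(study_id = s$study_id, n_obs = s$n_obs, replicator = s$replicator,
           covariate_subset = s$covariate_subset,
           signatures = as.list(s$empirical_signatures))
    })
  )
  dir.create(dirname(json_path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, matrix = "rowmajor")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write report to '%s': %s", json_path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(fit)), con)
  }
  invisible(json_path)
}

#' Read back a fit report
#'
#' @param json_path path written by [write_fit_report()].
#' @return the report as a list, with `estimates` as a named numeric
#'   vector.
#' @export
read_fit_report <- function(json_path) {
  rep <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  rep$estimates <- unlist(rep$estimates)
  rep
}

#' Rank candidate meta-models by the model-selection criterion
#'
#' Fits every candidate meta-model to the same studies and ranks them by
#' MSC (smaller preferred) — the workflow for comparing alternative
#' meta-model specifications against one body of published signatures.
#'
#' @param models list of [meta_model()] candidates.
#' @param studies list of [prior_study()] objects.
#' @param between optional [between_study_spec()].
#' @param plan a [simulation_plan()].
#' @param source optional [covariate_source()].
#' @return list with `table` (data frame: model, n_params, chi0, dof, msc,
#'   rank) and `fits`.
#' @export
compare_meta_models <- function(models, studies, between = NULL,
                                plan = simulation_plan(), source = NULL) {
  stopifnot(length(models) >= 1)
  fits <- lapply(models, function(m) {
    gma_fit(m, studies, between = between, plan = plan, source = source)
  })
  tab <- data.frame(
    model = vapply(models, function(m) m$name, character(1)),
    n_params = vapply(models, function(m) length(m$param_names), integer(1)),
    chi0 = vapply(fits, function(f) f$chi0, numeric(1)),
    dof = vapply(fits, function(f) f$dof, integer(1)),
    msc = vapply(fits, function(f) f$msc, numeric(1))
  )
  tab$rank <- rank(tab$msc, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
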