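# Configuration-driven pipeline: simulate -> filter -> fit -> standardize ->
# variance -> (optional) evaluate -> funnel, with all outputs as CSV under
# one directory plus a JSON manifest of md5 hashes for reproducibility
# checks. One global seed is split deterministically into per-stage seeds,
# so e.g. changing the bootstrap B never perturbs data generation.

pipeline_defaults <- function() {
  list(
    input = NULL,                 # path to a patient CSV; NULL = simulate
    simulate = list(),            # sim_config() overrides
    filters = list(
      period = TRUE,              # uses the sim config's period_range
      min_group = list(enabled = TRUE, group_var = "indigenous",
                       group_level = "indigenous", min_count = 20),
      drop_missing = list(enabled = TRUE, fields = "late"),
      censored = list(enabled = TRUE, code = 2),
      drop_missing2 = list(enabled = TRUE,
                           fields = c("lung", "diabetes", "cvd"))
    ),
    model = list(fixed_effects = NULL,  # NULL = names of sim beta
                 outcome = "status", grouping = "centre_id", nAGQ = 1),
    standardize = list(expected = "null", zero_obs = "correct",
                       min_center_size = 1),
    variance = list(methods = "delta", B = 200, chains = 3,
                    total_iter = 4500, warmup = 500, delta_mode = "binomial",
                    level = 0.95),
    evaluate = list(enabled = FALSE, R = 10, flag_rule = "interval"),
    funnel = list(levels = c(0.95, 0.998)),
    out_dir = "sirvar-output",
    seed = 1
  )
}

merge_config <- function(defaults, overrides) {
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]])
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration (or takes a list), fills every unset
#' field with its documented default, and validates all stages up front
#' (fail-fast): every violation found is reported, not just the first.
#'
#' @param config Path to a YAML file, or a (possibly empty) named list.
#' @return A complete, validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  config$sim <- NULL   # derived field; recomputed below on re-validation
  known <- names(pipeline_defaults())
  bad <- setdiff(names(config), known)
  errors <- character()
  if (length(bad)) {
    errors <- c(errors, paste0("unknown config field(s): ",
                               paste(bad, collapse = ", ")))
  }
  cfg <- merge_config(pipeline_defaults(), config[setdiff(names(config), bad)])

  sim_cfg <- tryCatch(do.call(sim_config, c(cfg$simulate,
                                            list(seed = cfg$seed))),
                      error = function(e) conditionMessage(e))
  if (is.character(sim_cfg)) errors <- c(errors, sim_cfg)

  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    errors <- c(errors, paste0("`input` file not found: ", cfg$input))
  }
  if (cfg$variance$B < 2) errors <- c(errors, "`B` must be >= 2")
  if (cfg$variance$chains < 2) errors <- c(errors, "`chains` must be >= 2")
  if (cfg$variance$total_iter < cfg$variance$chains *
        (cfg$variance$warmup + 2)) {
    errors <- c(errors, "`total_iter` too small for `warmup` and `chains`")
  }
  bad_m <- setdiff(cfg$variance$methods, c("delta", "bootstrap", "bayes"))
  if (length(bad_m)) {
    errors <- c(errors, paste0("unknown variance method(s): ",
                               paste(bad_m, collapse = ", ")))
  }
  if (cfg$evaluate$enabled && cfg$evaluate$R < 2) {
    errors <- c(errors, "`evaluate$R` must be >= 2")
  }
  if (!cfg$standardize$expected %in% c("null", "center", "marginal")) {
    errors <- c(errors, "`standardize$expected` must be null/center/marginal")
  }
  if (length(errors)) {
    stop(errorCondition(
      paste0("invalid pipeline configuration:\n  - ",
             paste(errors, collapse = "\n  - ")),
      errors = errors, class = c("sirvar_config_error", "error")))
  }
  if (!length(errors) && !is.character(sim_cfg)) cfg$sim <- sim_cfg
  cfg
}

#' Run the full profiling pipeline
#'
#' Executes the configured stages in order and writes every artifact under
#' the output directory: `patients.csv`, `truth.csv`, `filtered.csv`,
#' `attrition.csv`, `coefficients.csv` + `fit.yaml`,
#' `center_summaries.csv`, `variance_<method>.csv`, `flags.csv`,
#' `funnel.csv` + `funnel.svg`, optionally `evaluation.csv`, and
#' `manifest.json` with the seed, package version and an md5 hash of every
#' CSV output. The same configuration and seed reproduce byte-identical CSV
#' outputs and hence an identical hash manifest.
#'
#' @param config Path to a YAML configuration, or a named list (see
#'   [validate_config()]).
#' @param seed Optional override of the configured global seed.
#' @param out_dir Optional override of the configured output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$sim <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- derive_seeds(cfg$seed, 4)  # sim, bootstrap, bayes, evaluate
  outputs <- character()
  emit <- function(obj, name, writer = utils::write.csv) {
    path <- file.path(cfg$out_dir, name)
    if (identical(writer, utils::write.csv)) {
      utils::write.csv(obj, path, row.names = FALSE, na = "")
    } else writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    message("[sirvar] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
        class = c("sirvar_stage_error", "error")))
    })
  }

  # -- simulate or load ------------------------------------------------
  truth <- NULL
  patients <- stage("simulate", {
    if (is.null(cfg$input)) {
      sim <- cfg$sim
      sim$seed <- stage_seeds[1]
      pop <- generate_population(sim)
      tab <- inject_missingness(pop$patients, sim)
      truth <- pop$truth
      emit(tab, "patients.csv")
      emit(truth, "truth.csv")
      tab
    } else {
      read_patient_table(cfg$input)
    }
  })

  # -- filter cascade --------------------------------------------------
  filtered <- stage("filter", {
    chain <- list()
    f <- cfg$filters
    res <- patients
    if (isTRUE(f$period)) {
      pr <- if (!is.null(cfg$sim)) cfg$sim$period_range else
        range(patients$year, na.rm = TRUE)
      res <- filter_period(res, pr[1], pr[2]); chain <- c(chain, list(res))
    }
    if (isTRUE(f$min_group$enabled)) {
      res <- filter_min_group_per_center(res, f$min_group$group_var,
                                         f$min_group$group_level,
                                         f$min_group$min_count)
      chain <- c(chain, list(res))
    }
    if (isTRUE(f$drop_missing$enabled)) {
      res <- filter_drop_missing(res, f$drop_missing$fields)
      chain <- c(chain, list(res))
    }
    if (isTRUE(f$censored$enabled)) {
      res <- filter_status_censored(res, as.integer(f$censored$code))
      chain <- c(chain, list(res))
    }
    if (isTRUE(f$drop_missing2$enabled)) {
      res <- filter_drop_missing(res, f$drop_missing2$fields)
      chain <- c(chain, list(res))
    }
    emit(attrition_report(chain), "attrition.csv")
    tab <- as_patient_table(res)
    emit(tab, "filtered.csv")
    tab
  })

  # -- fit -------------------------------------------------------------
  fixed <- cfg$model$fixed_effects %||%
    (if (!is.null(cfg$sim)) names(cfg$sim$beta) else
       setdiff(names(registry_dictionary()), character(0)))
  spec <- model_spec(outcome = cfg$model$outcome, fixed_effects = fixed,
                     grouping = cfg$model$grouping)
  fit <- stage("fit", fit_risk_model(filtered, spec,
                                     nAGQ = cfg$model$nAGQ))
  emit(data.frame(term = c("(Intercept)", names(fit$beta_hat)),
                  estimate = c(fit$intercept_hat, unname(fit$beta_hat)),
                  se = unname(fit$se_beta),
                  stringsAsFactors = FALSE), "coefficients.csv")
  yaml::write_yaml(list(sigma_u_hat = fit$sigma_u_hat,
                        converged = fit$converged, loglik = fit$loglik,
                        n = fit$n, n_centers = fit$n_centers),
                   file.path(cfg$out_dir, "fit.yaml"))
  outputs <- c(outputs, file.path(cfg$out_dir, "fit.yaml"))

  # -- standardize -----------------------------------------------------
  summaries <- stage("standardize", {
    mode <- switch(cfg$standardize$expected, null = "conditional_null",
                   center = "conditional_center", marginal = "marginal")
    probs <- predict_probability(fit, filtered, mode)
    s <- center_summaries(filtered, probs, outcome = spec$outcome,
                          centre = spec$grouping,
                          min_center_size = cfg$standardize$min_center_size,
                          zero_obs = cfg$standardize$zero_obs)
    attr(s, "probs") <- probs
    emit(as.data.frame(s), "center_summaries.csv")
    s
  })
  probs <- attr(summaries, "probs")

  # -- variance --------------------------------------------------------
  estimates <- list()
  for (m in cfg$variance$methods) {
    estimates[[m]] <- stage(paste0("variance:", m), switch(m,
      delta = delta_variance(summaries, probs, filtered[[spec$grouping]],
                             mode = cfg$variance$delta_mode,
                             level = cfg$variance$level),
      bootstrap = bootstrap_variance(filtered, spec, B = cfg$variance$B,
                                     seed = stage_seeds[2],
                                     level = cfg$variance$level),
      bayes = suppressWarnings(bayesian_variance(
        filtered, spec, chains = cfg$variance$chains,
        total_iter = cfg$variance$total_iter,
        warmup = cfg$variance$warmup, seed = stage_seeds[3],
        level = cfg$variance$level))))
    emit(as.data.frame(estimates[[m]]), paste0("variance_", m, ".csv"))
  }

  # -- evaluate (optional) ---------------------------------------------
  if (isTRUE(cfg$evaluate$enabled)) {
    ev <- stage("evaluate", run_method_comparison(
      cfg$sim, R = cfg$evaluate$R, methods = cfg$variance$methods,
      seed = stage_seeds[4], B = cfg$variance$B,
      chains = cfg$variance$chains, total_iter = cfg$variance$total_iter,
      warmup = cfg$variance$warmup, flag_rule = cfg$evaluate$flag_rule,
      level = cfg$variance$level))
    emit(as.data.frame(ev), "evaluation.csv")
  }

  # -- funnel ----------------------------------------------------------
  stage("funnel", {
    flags <- flag_outliers(summaries, level = cfg$variance$level)
    emit(data.frame(centre_id = summaries$centre_id, flag = flags),
         "flags.csv")
    grid <- funnel_limits(
      exp(seq(log(max(min(summaries$E) * 0.8, 0.5)),
              log(max(summaries$E) * 1.2), length.out = 200)),
      levels = cfg$funnel$levels)
    export_funnel(summaries, grid, file.path(cfg$out_dir, "funnel.csv"),
                  file.path(cfg$out_dir, "funnel.svg"),
                  levels = cfg$funnel$levels)
    outputs <<- c(outputs, file.path(cfg$out_dir, "funnel.csv"))
  })

  # -- manifest --------------------------------------------------------
  csvs <- sort(unique(outputs[grepl("\\.(csv|yaml)$", outputs)]))
  manifest <- list(
    seed = cfg$seed,
    package = "sirvar",
    version = as.character(utils::packageVersion("sirvar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    hashes = as.list(stats::setNames(unname(tools::md5sum(csvs)),
                                     basename(csvs)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
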