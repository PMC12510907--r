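# Simulation-based comparison of the variance estimators: bias, variance,
# MSE of the log SIR point estimates against known synthetic truth, plus
# interval coverage and false-positive rate, over seeded replicates.

#' Bias, variance and MSE of a set of estimates against a known truth
#'
#' `bias = mean(estimates) - truth`; `variance` is the population variance
#' (denominator R) of the estimates; `mse = mean((estimates - truth)^2)`.
#' With the population-variance convention the decomposition
#' `mse = bias^2 + variance` is exact.
#'
#' @param estimates Numeric vector of estimates (one per replicate).
#' @param truth The reference value.
#' @return Named list `bias`, `variance`, `mse`.
#' @export
bias_variance_mse <- function(estimates, truth) {
  if (!length(estimates)) stop_data("`estimates` must be non-empty")
  e <- estimates - truth
  bias <- mean(e)
  list(bias = bias,
       variance = mean((e - bias)^2),
       mse = mean(e^2))
}

#' Fraction of intervals covering their true values
#'
#' Closed endpoints: `low <= truth <= high` counts as covered.
#'
#' @param intervals Two-column matrix/data frame of `(low, high)`.
#' @param truths Numeric vector aligned with the rows of `intervals`.
#' @return Coverage fraction in `[0, 1]`.
#' @export
interval_coverage <- function(intervals, truths) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) != length(truths)) {
    stop_data("`intervals` and `truths` must be aligned")
  }
  mean(intervals[, 1] <= truths & truths <= intervals[, 2])
}

#' False-positive rate among in-control centers
#'
#' Among centers that are truly in control, the fraction flagged as
#' outlying.
#'
#' @param flags Logical vector: center flagged.
#' @param in_control Logical vector: center truly in control.
#' @return Fraction in `[0, 1]`.
#' @export
false_positive_rate <- function(flags, in_control) {
  if (length(flags) != length(in_control)) {
    stop_data("`flags` and `in_control` must be aligned")
  }
  if (!any(in_control)) stop_data("no in-control centers")
  mean(flags[in_control])
}

#' Compare the three variance estimators on synthetic registries
#'
#' For each replicate: generate a registry from `config` (with a
#' replicate-specific seed derived from `seed`), fit the risk model,
#' standardize, estimate each center's log SIR variance by every requested
#' method, flag outlying centers, and score against the known true log SIR.
#' Point estimates are the plug-in log SIR for the delta and bootstrap
#' methods and the posterior mean for the Bayesian method. Errors are pooled
#' over replicate-centers, so `bias`, `variance` (population convention) and
#' `mse` obey `mse = bias^2 + variance` exactly. Failed replicates are
#' dropped and counted.
#'
#' @param config A [sim_config()]; its `seed` is overridden per replicate.
#' @param R Number of replicates (>= 2).
#' @param methods Subset of `c("delta", "bootstrap", "bayes")`.
#' @param seed Master seed for the replicate stream.
#' @param B Bootstrap resamples per replicate.
#' @param chains,total_iter,warmup MCMC settings per replicate.
#' @param delta_mode Delta-method variance mode.
#' @param flag_rule `"interval"` flags a center when its 95% interval for
#'   log SIR excludes 0; `"funnel"` flags when its SIR falls outside the
#'   funnel control limit at its expected count.
#' @param bayes_sir_draw Per-draw log SIR construction for the Bayesian
#'   method (default `"posterior"`, whose credible interval is the one that
#'   can cover the simulated truth; see [bayesian_variance()]).
#' @param level Interval level.
#' @return An `evaluation_table` data frame: one row per method with `bias`,
#'   `variance`, `mse`, `coverage`, `fpr`, `R` (successful replicates) and
#'   `n_estimates` (pooled replicate-centers). `fpr` is `NA` when no
#'   generated center is in control (i.e. `sigma_u > 0`).
#' @export
run_method_comparison <- function(config, R, methods = c("delta", "bootstrap",
                                                         "bayes"),
                                  seed = 1L, B = 200L, chains = 3L,
                                  total_iter = 4500L, warmup = 500L,
                                  delta_mode = "binomial",
                                  flag_rule = c("interval", "funnel"),
                                  bayes_sir_draw = "posterior",
                                  level = 0.95) {
  flag_rule <- match.arg(flag_rule)
  methods <- match.arg(methods, several.ok = TRUE)
  if (R < 2) stop_config("`R` must be >= 2")
  rep_seeds <- derive_seeds(seed, 3L * R)
  spec <- model_spec(outcome = "status", fixed_effects = names(config$beta),
                     grouping = "centre_id")

  acc <- stats::setNames(lapply(methods, function(m)
    list(err = numeric(), cover = logical(), flag = logical(),
         in_control = logical())), methods)
  n_failed <- 0L

  for (r in seq_len(R)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- rep_seeds[r]
      pop <- generate_population(cfg)
      fit <- suppressWarnings(fit_risk_model(pop$patients, spec))
      probs <- predict_probability(fit, pop$patients, "conditional_null")
      sm <- suppressWarnings(center_summaries(pop$patients, probs))
      truth <- pop$truth[match(sm$centre_id, pop$truth$centre_id), ]
      lt <- log(truth$true_sir)

      ests <- list()
      if ("delta" %in% methods) {
        ests$delta <- delta_variance(sm, probs, pop$patients$centre_id,
                                     mode = delta_mode, level = level)
      }
      if ("bootstrap" %in% methods) {
        ests$bootstrap <- bootstrap_variance(pop$patients, spec, B = B,
                                             seed = rep_seeds[R + r],
                                             level = level)
      }
      if ("bayes" %in% methods) {
        ests$bayes <- suppressWarnings(bayesian_variance(
          pop$patients, spec, chains = chains, total_iter = total_iter,
          warmup = warmup, seed = rep_seeds[2L * R + r], level = level,
          sir_draw = bayes_sir_draw))
      }
      list(sm = sm, truth = truth, lt = lt, ests = ests)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }

    for (m in names(res$ests)) {
      est <- res$ests[[m]]
      i <- match(res$sm$centre_id, est$centre_id)
      est <- est[i, ]
      flags <- if (flag_rule == "interval") {
        est$ci_low > 0 | est$ci_high < 0
      } else {
        lim <- funnel_limits(res$sm$E, levels = level)
        res$sm$sir > lim[[paste0("limit_high_", fmt_level(level))]] |
          res$sm$sir < lim[[paste0("limit_low_", fmt_level(level))]]
      }
      acc[[m]]$err <- c(acc[[m]]$err, est$estimate - res$lt)
      acc[[m]]$cover <- c(acc[[m]]$cover,
                          est$ci_low <= res$lt & res$lt <= est$ci_high)
      acc[[m]]$flag <- c(acc[[m]]$flag, flags)
      acc[[m]]$in_control <- c(acc[[m]]$in_control, res$truth$in_control)
    }
  }
  if (n_failed == R) stop_data("every replicate failed")

  rows <- lapply(methods, function(m) {
    a <- acc[[m]]
    bvm <- bias_variance_mse(a$err, 0)
    data.frame(
      method = m, bias = bvm$bias, variance = bvm$variance, mse = bvm$mse,
      coverage = mean(a$cover),
      fpr = if (any(a$in_control)) false_positive_rate(a$flag, a$in_control)
            else NA_real_,
      R = as.integer(R - n_failed), n_estimates = length(a$err),
      n_failed = n_failed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_table", "data.frame")
  out
}
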