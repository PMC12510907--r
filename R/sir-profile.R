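#' Profile providers by indirectly standardized incidence ratios
#'
#' The package's central fitting function. Fits the random-intercept
#' logistic risk-adjustment model given as a formula (lme4 syntax,
#' e.g. `status ~ gender + agegp + diabetes + (1 | centre_id)`), computes
#' per-patient event probabilities with the random intercept set to zero
#' ("as expected at an average center"), sums them within centers into
#' expected counts, and returns per-center observed/expected counts, SIR
#' and log SIR ready for variance estimation, flagging and funnel plotting.
#'
#' Methods: [print()], [summary()], [coef()] (fixed effects), [fitted()]
#' (per-patient probabilities), [predict()] (new data, any prediction
#' mode), [residuals()] (per-center Pearson residuals
#' `(O - E) / sqrt(sum p(1-p))`), [confint()] (per-center intervals for
#' log SIR by the delta, bootstrap or Bayesian method), [plot()] (funnel
#' plot) and [simulate()] (outcome vectors redrawn from the fitted model).
#'
#' @param formula Model formula with one `(1 | centre)` term.
#' @param data Complete-case patient table.
#' @param expected Prediction mode for expected counts:
#'   `"null"` (u = 0, the conventional indirect-standardization choice),
#'   `"center"` (each center's predicted intercept) or `"marginal"`
#'   (integrated over the random-intercept distribution).
#' @param zero_obs Passed to [center_summaries()].
#' @param min_center_size Passed to [center_summaries()].
#' @param nAGQ Quadrature points for [fit_risk_model()] (1 = Laplace).
#' @param reference_levels Passed to [model_spec()].
#' @return An object of class `sir_profile`: list with `fit` (the
#'   `risk_fit`), `summaries` (the [center_summaries()] table), `probs`,
#'   `spec`, `data` and `call`.
#' @examples
#' cfg <- sim_config(n_centers = 8, center_size_range = c(80, 120),
#'                   beta = default_beta()[c("gender", "diabetes")],
#'                   sigma_u = 0.4, seed = 42)
#' pop <- generate_population(cfg)
#' pr <- sir_profile(status ~ gender + diabetes + (1 | centre_id),
#'                   data = pop$patients)
#' pr
#' confint(pr, method = "delta")
#' @export
sir_profile <- function(formula, data,
                        expected = c("null", "center", "marginal"),
                        zero_obs = c("correct", "exclude"),
                        min_center_size = 1L, nAGQ = 1L,
                        reference_levels = NULL) {
  expected <- match.arg(expected)
  bars <- lme4::findbars(formula)
  if (length(bars) != 1L) {
    stop_config("`formula` must contain exactly one (1 | centre) term")
  }
  grouping <- deparse(bars[[1]][[3]])
  fixed <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  outcome <- deparse(formula[[2]])
  spec <- model_spec(outcome = outcome, fixed_effects = fixed,
                     grouping = grouping,
                     reference_levels = reference_levels)
  fit <- fit_risk_model(data, spec, nAGQ = nAGQ)
  mode <- switch(expected, null = "conditional_null",
                 center = "conditional_center", marginal = "marginal")
  probs <- predict_probability(fit, data, mode)
  summaries <- center_summaries(data, probs, outcome = outcome,
                                centre = grouping,
                                min_center_size = min_center_size,
                                zero_obs = match.arg(zero_obs))
  out <- list(fit = fit, summaries = summaries, probs = probs, spec = spec,
              expected = expected, data = data, call = match.call())
  class(out) <- "sir_profile"
  out
}

#' @export
print.sir_profile <- function(x, ...) {
  s <- x$summaries
  cat(sprintf(
    "SIR profile of %d centers (%d patients, %d events)\n",
    nrow(s), x$fit$n, sum(x$data[[x$spec$outcome]] == 1)))
  cat(sprintf("  risk model: %s ~ %s + (1 | %s), sigma_u_hat = %.3f\n",
              x$spec$outcome, paste(x$spec$fixed_effects, collapse = " + "),
              x$spec$grouping, x$fit$sigma_u_hat))
  cat(sprintf("  SIR range %.3f - %.3f (expected counts at u = %s)\n",
              min(s$sir), max(s$sir), x$expected))
  invisible(x)
}

#' @export
summary.sir_profile <- function(object, level = 0.95, ...) {
  est <- delta_variance(object$summaries, object$probs,
                        object$data[[object$spec$grouping]], level = level)
  out <- list(profile = object,
              table = cbind(object$summaries,
                            se = est$se, ci_low = est$ci_low,
                            ci_high = est$ci_high),
              flags = flag_outliers(object$summaries, level = level),
              level = level)
  class(out) <- "summary.sir_profile"
  out
}

#' @export
print.summary.sir_profile <- function(x, ...) {
  print(x$profile)
  cat(sprintf("\nPer-center log SIR with delta-method %g%% intervals:\n",
              100 * x$level))
  tab <- x$table
  tab$flag <- as.character(x$flags)
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.sir_profile <- function(object, ...) {
  c("(Intercept)" = object$fit$intercept_hat, object$fit$beta_hat)
}

#' @export
fitted.sir_profile <- function(object, ...) object$probs

#' @export
predict.sir_profile <- function(object, newdata = NULL,
                                mode = c("conditional_null",
                                         "conditional_center",
                                         "marginal"), ...) {
  predict_probability(object$fit, newdata %||% object$data,
                      match.arg(mode))
}

#' @export
residuals.sir_profile <- function(object, ...) {
  s <- object$summaries
  vO <- rowsum(object$probs * (1 - object$probs),
               factor(as.character(object$data[[object$spec$grouping]])))
  stats::setNames((s$O - s$E) / sqrt(vO[match(s$centre_id, rownames(vO)), 1]),
                  s$centre_id)
}

#' @export
confint.sir_profile <- function(object, parm, level = 0.95,
                                method = c("delta", "bootstrap", "bayes"),
                                ...) {
  method <- match.arg(method)
  est <- switch(method,
    delta = delta_variance(object$summaries, object$probs,
                           object$data[[object$spec$grouping]],
                           level = level, ...),
    bootstrap = bootstrap_variance(object$data, object$spec, level = level,
                                   ...),
    bayes = bayesian_variance(object$data, object$spec, level = level, ...))
  if (!missing(parm)) est <- est[est$centre_id %in% parm, , drop = FALSE]
  est
}

#' @export
plot.sir_profile <- function(x, levels = c(0.95, 0.998), ...) {
  plot_funnel(x$summaries, levels = levels, ...)
}

#' @export
simulate.sir_profile <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict_probability(object$fit, object$data, "conditional_center")
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
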