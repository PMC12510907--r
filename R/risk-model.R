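#' Specification of the risk-adjustment model
#'
#' Names the binary outcome, the ordered fixed-effect covariates, and the
#' grouping column that receives the Gaussian random intercept. Reference
#' levels default to the first level observed in the data (or the registry
#' dictionary order for dictionary covariates).
#'
#' @param outcome Outcome column name (strictly 0/1 at fit time).
#' @param fixed_effects Character vector of covariate columns.
#' @param grouping Column for the center random intercept, or `NULL` for a
#'   plain logistic model without a random effect.
#' @param reference_levels Optional named list/character vector mapping a
#'   covariate to its reference level.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = "status",
                       fixed_effects = names(registry_dictionary()),
                       grouping = "centre_id",
                       reference_levels = NULL) {
  if (outcome %in% fixed_effects) {
    stop_config("`outcome` must not appear in `fixed_effects`")
  }
  if (!is.null(grouping) && grouping %in% fixed_effects) {
    stop_config("`grouping` must not appear in `fixed_effects`")
  }
  out <- list(outcome = outcome, fixed_effects = as.character(fixed_effects),
              grouping = grouping,
              reference_levels = as.list(reference_levels))
  class(out) <- "model_spec"
  out
}

# Coerce model columns to factors with the configured reference level first.
prepare_model_frame <- function(table, spec) {
  dict <- registry_dictionary()
  for (v in spec$fixed_effects) {
    if (!v %in% names(table)) stop_data("missing model column `", v, "`")
    if (is.character(table[[v]]) || is.factor(table[[v]])) {
      levs <- if (v %in% names(dict)) {
        intersect(dict[[v]], unique(as.character(table[[v]])))
      } else sort(unique(as.character(table[[v]])))
      ref <- spec$reference_levels[[v]]
      if (!is.null(ref)) {
        if (!ref %in% levs) {
          stop_config("reference level '", ref, "' not present in `", v, "`")
        }
        levs <- c(ref, setdiff(levs, ref))
      }
      table[[v]] <- factor(as.character(table[[v]]), levels = levs)
    }
  }
  if (!is.null(spec$grouping)) {
    table[[spec$grouping]] <- factor(as.character(table[[spec$grouping]]))
  }
  table
}

fixed_formula <- function(spec) {
  rhs <- if (length(spec$fixed_effects)) {
    paste(spec$fixed_effects, collapse = " + ")
  } else "1"
  stats::as.formula(paste("~", rhs))
}

# lme4/glm coefficient labels ("agegp26-35") -> stable "agegp[26-35]" names.
pretty_coef_names <- function(labels, table, spec) {
  out <- labels
  for (v in spec$fixed_effects) {
    if (is.factor(table[[v]])) {
      for (l in levels(table[[v]])[-1]) {
        out[out == paste0(v, l)] <- paste0(v, "[", l, "]")
      }
    }
  }
  out
}

#' Fit the random-intercept logistic risk-adjustment model
#'
#' Maximum-likelihood fit (Laplace approximation by default; set `nAGQ > 1`
#' for adaptive Gauss-Hermite quadrature) of
#' `logit P(y = 1) = intercept + x' beta + u_c`, `u_c ~ N(0, sigma_u^2)`,
#' via [lme4::glmer()]. With `grouping = NULL` in the spec the model reduces
#' to plain logistic regression via [stats::glm()] (used for degenerate
#' designs such as a single center).
#'
#' @param table Complete-case patient table.
#' @param spec A [model_spec()].
#' @param nAGQ Number of quadrature points (1 = Laplace).
#' @param maxit Maximum optimizer iterations.
#' @return An object of class `risk_fit`: fixed-effect estimates
#'   (`intercept_hat`, `beta_hat`, `se_beta`), `sigma_u_hat`, predicted
#'   random intercepts `u_hat` (one per center), `converged`, `loglik`, and
#'   the fitted [lme4::glmer()] / [stats::glm()] object in `$model`.
#' @export
fit_risk_model <- function(table, spec, nAGQ = 1L, maxit = 200L) {
  cols <- c(spec$outcome, spec$fixed_effects, spec$grouping)
  miss <- vapply(cols, function(v) anyNA(table[[v]]), logical(1))
  if (any(miss)) {
    stop_data("model columns contain missing values: ",
              paste(cols[miss], collapse = ", "),
              " (apply filter_drop_missing() first)")
  }
  y <- table[[spec$outcome]]
  if (!all(y %in% c(0, 1))) {
    stop_data("outcome `", spec$outcome, "` must be strictly binary 0/1")
  }
  tab <- prepare_model_frame(table, spec)

  use_ranef <- !is.null(spec$grouping)
  if (use_ranef && nlevels(tab[[spec$grouping]]) < 2L) {
    warning("fewer than 2 centers; fitting without a random intercept")
    use_ranef <- FALSE
  }
  rhs <- if (length(spec$fixed_effects)) {
    paste(spec$fixed_effects, collapse = " + ")
  } else "1"

  if (use_ranef) {
    form <- stats::as.formula(
      paste(spec$outcome, "~", rhs, "+ (1 |", spec$grouping, ")"))
    model <- lme4::glmer(
      form, data = tab, family = stats::binomial(),
      nAGQ = nAGQ,
      control = lme4::glmerControl(
        optimizer = "bobyqa",
        optCtrl = list(maxfun = max(10000L, 100L * maxit)),
        calc.derivs = TRUE))
    fe <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    sigma_u_hat <- sqrt(unname(lme4::VarCorr(model)[[spec$grouping]][1, 1]))
    re <- lme4::ranef(model)[[spec$grouping]]
    u_hat <- stats::setNames(re[["(Intercept)"]], rownames(re))
    msgs <- unlist(model@optinfo$conv$lme4$messages)
    # a boundary (singular) fit converged -- to sigma_u = 0 -- and is not a
    # failure; anything else (gradient, Hessian) is
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    conv <- length(msgs) == 0L && model@optinfo$conv$opt == 0
    if (!conv) {
      warning("risk model did not converge cleanly: ",
              paste(msgs, collapse = "; "))
    }
    ll <- as.numeric(stats::logLik(model))
  } else {
    form <- stats::as.formula(paste(spec$outcome, "~", rhs))
    model <- stats::glm(form, data = tab, family = stats::binomial(),
                        control = stats::glm.control(maxit = maxit))
    fe <- stats::coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    sigma_u_hat <- 0
    u_hat <- if (!is.null(spec$grouping)) {
      stats::setNames(rep(0, nlevels(tab[[spec$grouping]])),
                      levels(tab[[spec$grouping]]))
    } else numeric()
    conv <- model$converged
    if (!conv) warning("glm did not converge")
    ll <- as.numeric(stats::logLik(model))
  }

  nice <- pretty_coef_names(names(fe), tab, spec)
  beta_hat <- stats::setNames(as.numeric(fe), nice)
  se_beta <- stats::setNames(as.numeric(se), nice)

  out <- list(
    model = model,
    spec = spec,
    coef_raw = fe,                     # model-matrix order, raw labels
    intercept_hat = unname(fe[["(Intercept)"]]),
    beta_hat = beta_hat[names(beta_hat) != "(Intercept)"],
    se_beta = se_beta,
    sigma_u_hat = sigma_u_hat,
    u_hat = u_hat,
    converged = conv,
    loglik = ll,
    xlevels = lapply(tab[spec$fixed_effects], function(col)
      if (is.factor(col)) levels(col) else NULL),
    n = nrow(tab),
    n_centers = if (use_ranef) nlevels(tab[[spec$grouping]]) else
      length(u_hat)
  )
  class(out) <- "risk_fit"
  out
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic risk model: n = %d, centers = %d\n",
    x$n, max(x$n_centers, 1L)))
  cat(sprintf("  sigma_u_hat = %.4f, logLik = %.2f, converged: %s\n",
              x$sigma_u_hat, x$loglik, x$converged))
  cat("  coefficients:\n")
  print(round(c("(Intercept)" = x$intercept_hat, x$beta_hat), 4))
  invisible(x)
}

# Model matrix for new data under the fit's factor levels; unseen levels are
# a schema error naming the offending level(s).
risk_model_matrix <- function(fit, table) {
  spec <- fit$spec
  for (v in spec$fixed_effects) {
    levs <- fit$xlevels[[v]]
    if (!is.null(levs)) {
      vals <- as.character(table[[v]])
      unseen <- setdiff(unique(vals[!is.na(vals)]), levs)
      if (length(unseen)) {
        stop_data("unseen level(s) in `", v, "`: ",
                  paste(unseen, collapse = ", "))
      }
      table[[v]] <- factor(vals, levels = levs)
    }
  }
  stats::model.matrix(fixed_formula(spec), data = table)
}

#' Per-patient event probabilities from the fitted risk model
#'
#' The probabilities whose within-center sums form the expected counts of
#' indirect standardization. `conditional_null` evaluates the fixed effects
#' at `u = 0` ("as if treated at an average center" -- the conventional
#' reading for expected counts); `conditional_center` adds the center's
#' predicted random intercept; `marginal` integrates the random intercept
#' out over `N(0, sigma_u_hat^2)` by quadrature.
#'
#' @param fit A [fit_risk_model()] result.
#' @param table Rows to predict for (must cover the model covariates).
#' @param mode One of `"conditional_null"`, `"conditional_center"`,
#'   `"marginal"`.
#' @return Numeric vector of probabilities in (0, 1), aligned with rows.
#' @export
predict_probability <- function(fit, table,
                                mode = c("conditional_null",
                                         "conditional_center",
                                         "marginal")) {
  mode <- match.arg(mode)
  X <- risk_model_matrix(fit, table)
  eta <- as.vector(X %*% fit$coef_raw[colnames(X)])
  if (mode == "conditional_null") {
    return(plogis(eta))
  }
  if (mode == "conditional_center") {
    grp <- as.character(table[[fit$spec$grouping]])
    unseen <- setdiff(unique(grp), names(fit$u_hat))
    if (length(unseen)) {
      stop_data("unseen center(s): ", paste(unseen, collapse = ", "))
    }
    return(plogis(eta + unname(fit$u_hat[grp])))
  }
  # marginal: fixed-grid Gaussian quadrature over u
  if (fit$sigma_u_hat == 0) return(plogis(eta))
  z <- seq(-6, 6, length.out = 121)
  w <- stats::dnorm(z); w <- w / sum(w)
  p <- numeric(length(eta))
  for (k in seq_along(z)) p <- p + w[k] * plogis(eta + fit$sigma_u_hat * z[k])
  p
}
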