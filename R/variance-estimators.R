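# The three estimators of Var(log SIR) under comparison. Each returns a
# `variance_estimate` data frame with one row per center:
#   centre_id, method, estimate (point estimate of log SIR), variance, se,
#   ci_low, ci_high (interval for log SIR at `level`), level, diagnostics
# (method-specific details serialized as a JSON string, so the table
# round-trips through CSV).

new_variance_estimate <- function(centre_id, method, estimate, variance,
                                  ci_low, ci_high, level, diagnostics) {
  stopifnot(all(variance >= 0), all(ci_low <= ci_high))
  out <- data.frame(
    centre_id = as.character(centre_id), method = method,
    estimate = estimate, variance = variance, se = sqrt(variance),
    ci_low = ci_low, ci_high = ci_high, level = level,
    diagnostics = vapply(diagnostics, function(d)
      as.character(jsonlite::toJSON(d, auto_unbox = TRUE)), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("variance_estimate", "data.frame")
  out
}

#' Delta-method variance of the log SIR
#'
#' First-order propagation treating the expected count E as fixed:
#' `Var(log SIR) = Var(O) / O^2`. In `binomial` mode (the default, matching
#' the Bernoulli likelihood of the risk model) `Var(O) = sum_i p_i (1-p_i)`
#' over the center's patients; in `poisson` mode `Var(O) = O`, reducing to
#' the classical `1/O`. The interval is Wald: `log SIR +/- z * se`.
#'
#' @param summaries A [center_summaries()] table (continuity-corrected where
#'   `O = 0`).
#' @param probs Per-row predicted probabilities aligned with `centre`
#'   (required in binomial mode).
#' @param centre Per-row center ids aligned with `probs`.
#' @param mode `"binomial"` or `"poisson"`.
#' @param level Interval level (default 0.95).
#' @return A `variance_estimate` data frame, one row per center.
#' @export
delta_variance <- function(summaries, probs = NULL, centre = NULL,
                           mode = c("binomial", "poisson"), level = 0.95) {
  mode <- match.arg(mode)
  if (any(summaries$O <= 0)) {
    stop_data("delta variance undefined for O <= 0; apply the continuity ",
              "correction in center_summaries() first")
  }
  if (mode == "binomial") {
    if (is.null(probs) || is.null(centre)) {
      stop_config("binomial mode needs per-row `probs` and `centre`")
    }
    vO <- rowsum(probs * (1 - probs), factor(as.character(centre)))
    var_O <- vO[match(summaries$centre_id, rownames(vO)), 1]
    if (anyNA(var_O)) stop_data("`centre` does not cover every summary center")
  } else {
    var_O <- summaries$O
  }
  v <- var_O / summaries$O^2
  z <- stats::qnorm(1 - (1 - level) / 2)
  new_variance_estimate(
    summaries$centre_id, "delta", summaries$log_sir, v,
    summaries$log_sir - z * sqrt(v), summaries$log_sir + z * sqrt(v),
    level,
    lapply(seq_len(nrow(summaries)), function(i)
      list(mode = mode, corrected = summaries$corrected[i]))
  )
}

#' Nonparametric bootstrap variance of the log SIR
#'
#' Resamples patients with replacement (by default within each center,
#' preserving every center's size so its SIR exists in every replicate),
#' refits the full risk-adjustment model on each resample, recomputes every
#' center's log SIR, and takes the sample variance over successful
#' replicates (denominator `B_ok - 1`) with a percentile interval. Failed
#' refits are dropped and counted; more than 10% failures is an error.
#'
#' @param table Fit-ready patient table.
#' @param spec A [model_spec()].
#' @param B Number of bootstrap resamples (default 5000).
#' @param scheme `"within_center"` (default) or `"centers"` (cluster
#'   bootstrap resampling whole centers; per-center results average over the
#'   copies of that center in each replicate).
#' @param seed Integer seed; the full set of resamples is deterministic
#'   given it.
#' @param level Interval level.
#' @param nAGQ Passed to [fit_risk_model()].
#' @return A `variance_estimate` data frame, one row per center; diagnostics
#'   carry `B`, `n_failed_refits` and the scheme.
#' @export
bootstrap_variance <- function(table, spec, B = 5000L,
                               scheme = c("within_center", "centers"),
                               seed = NULL, level = 0.95, nAGQ = 1L) {
  scheme <- match.arg(scheme)
  if (B < 2) stop_config("`B` must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  fit0 <- fit_risk_model(table, spec, nAGQ = nAGQ)
  p0 <- predict_probability(fit0, table, "conditional_null")
  sum0 <- suppressWarnings(center_summaries(table, p0,
                                            outcome = spec$outcome,
                                            centre = spec$grouping))
  centres <- sum0$centre_id
  grp <- as.character(table[[spec$grouping]])
  by_centre <- split(seq_len(nrow(table)), grp)

  one_rep <- function() {
    if (scheme == "within_center") {
      idx <- unlist(lapply(by_centre, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      tab_b <- table[idx, , drop = FALSE]
      orig <- tab_b[[spec$grouping]]
    } else {
      picks <- sample(names(by_centre), length(by_centre), replace = TRUE)
      idx <- unlist(lapply(seq_along(picks), function(k)
        by_centre[[picks[k]]]), use.names = FALSE)
      tab_b <- table[idx, , drop = FALSE]
      # distinct id per drawn copy so the model sees each copy as a center
      tab_b[[spec$grouping]] <- rep(paste0(picks, "#", seq_along(picks)),
                                    lengths(by_centre[picks]))
      orig <- rep(picks, lengths(by_centre[picks]))
    }
    # convergence *warnings* on a resample are tolerated (boundary fits are
    # legitimate draws); only hard errors or non-finite results count as
    # failed refits
    fit_b <- suppressWarnings(fit_risk_model(tab_b, spec, nAGQ = nAGQ))
    p_b <- predict_probability(fit_b, tab_b, "conditional_null")
    s_b <- suppressWarnings(center_summaries(
      tab_b, p_b, outcome = spec$outcome, centre = spec$grouping))
    if (scheme == "centers") {
      # average the log SIRs of the copies of each original center
      key <- sub("#.*$", "", s_b$centre_id)
      ls <- tapply(s_b$log_sir, key, mean)
      ls[match(centres, names(ls))]
    } else {
      s_b$log_sir[match(centres, s_b$centre_id)]
    }
  }
  check_finite <- function(x) {
    if (anyNA(x) || any(!is.finite(x))) stop("non-finite log SIR in refit")
    x
  }

  draws <- matrix(NA_real_, nrow = length(centres), ncol = B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch(check_finite(one_rep()), error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else draws[, b] <- res
  }
  if (n_failed > 0.10 * B) {
    stop_data("bootstrap failed in ", n_failed, "/", B, " refits (> 10%); ",
              "consider larger centers or fewer covariates")
  }
  ok <- !is.na(draws[1, ])
  v <- apply(draws[, ok, drop = FALSE], 1, stats::var)
  qs <- t(apply(draws[, ok, drop = FALSE], 1, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                na.rm = TRUE))
  new_variance_estimate(
    centres, "bootstrap", sum0$log_sir, v, qs[, 1], qs[, 2], level,
    lapply(seq_along(centres), function(i)
      list(B = B, n_failed_refits = n_failed, scheme = scheme))
  )
}

#' Prior specification for the Bayesian variance estimator
#'
#' Weakly informative defaults: Normal(0, 2.5) on covariate coefficients,
#' Normal(0, 10) on the intercept, Half-Normal(1) on the random-intercept
#' SD (all on the log-odds scale).
#'
#' @param beta_sd,intercept_sd,sigma_u_scale Positive prior scales.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 2.5, intercept_sd = 10, sigma_u_scale = 1) {
  if (beta_sd <= 0 || intercept_sd <= 0 || sigma_u_scale <= 0) {
    stop_config("prior scales must be positive (proper priors)")
  }
  structure(list(beta_sd = beta_sd, intercept_sd = intercept_sd,
                 sigma_u_scale = sigma_u_scale), class = "prior_spec")
}

jags_model_string <- function(use_ranef) {
  if (use_ranef) {
    "model {
      for (i in 1:N) {
        y[i] ~ dbern(ilogit(inprod(X[i, ], b) + u[centre[i]]))
      }
      for (j in 1:P) { b[j] ~ dnorm(0, prec_b[j]) }
      for (c in 1:C) { u[c] ~ dnorm(0, tau_u) }
      sigma_u ~ dnorm(0, prec_sigma) T(0, )
      tau_u <- 1 / (sigma_u * sigma_u + 1.0E-12)
    }"
  } else {
    "model {
      for (i in 1:N) {
        y[i] ~ dbern(ilogit(inprod(X[i, ], b)))
      }
      for (j in 1:P) { b[j] ~ dnorm(0, prec_b[j]) }
    }"
  }
}

#' Bayesian MCMC variance of the log SIR
#'
#' Samples the posterior of the hierarchical logistic model with JAGS
#' (defaults: 3 chains, 25,500 total iterations split equally across chains,
#' 1500 warmup draws per chain). Two constructions of the per-draw log SIR
#' are available. With `sir_draw = "expected"` (the default), each center's
#' expected count is recomputed from that draw's fixed effects at `u = 0`
#' and combined with the *observed* count, so the posterior spread
#' quantifies expected-count (risk-model) uncertainty around the plug-in
#' SIR. With `sir_draw = "posterior"`, each draw's SIR is the model's own
#' `sum(plogis(eta + u_c)) / sum(plogis(eta))` over the center's patients
#' -- the fully Bayesian posterior of the center-effect SIR, whose credible
#' interval is the one that can calibrate against simulation truth. In
#' either case the estimator is the posterior variance of log SIR with an
#' equal-tailed credible interval. Split-chain convergence is monitored per
#' center (Gelman-Rubin R-hat, effective sample size); any R-hat above 1.05
#' flags the result `unconverged` with a warning.
#'
#' @param table Fit-ready patient table.
#' @param spec A [model_spec()].
#' @param chains Number of chains (>= 2, needed for R-hat).
#' @param total_iter Total post-adaptation iterations summed over chains
#'   (warmup included).
#' @param warmup Burn-in iterations per chain.
#' @param adapt JAGS adaptation iterations.
#' @param priors A [prior_spec()].
#' @param seed Integer seed driving all chains' RNGs.
#' @param level Credible level.
#' @param sir_draw Per-draw log SIR construction: `"expected"` (observed O
#'   over the draw's expected count at u = 0) or `"posterior"` (the draw's
#'   own center-effect SIR); see Details.
#' @return A `variance_estimate` data frame, one row per center; diagnostics
#'   carry `n_chains`, `n_iter`, per-center `rhat` and `ess`, and the
#'   `unconverged` flag. The full per-center draws are attached as attribute
#'   `"draws"` (centers x kept draws matrix).
#' @export
bayesian_variance <- function(table, spec, chains = 3L, total_iter = 25500L,
                              warmup = 1500L, adapt = 500L,
                              priors = prior_spec(), seed = NULL,
                              level = 0.95,
                              sir_draw = c("expected", "posterior")) {
  sir_draw <- match.arg(sir_draw)
  if (chains < 2) stop_config("`chains` must be >= 2 (required for R-hat)")
  per_chain <- floor(total_iter / chains)
  kept <- per_chain - warmup
  if (kept < 2) {
    stop_config("`total_iter` too small: ", kept,
                " retained draws per chain after warmup")
  }
  y <- table[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop_data("outcome must be strictly binary 0/1")
  tab <- prepare_model_frame(table, spec)
  X <- stats::model.matrix(fixed_formula(spec), data = tab)

  use_ranef <- !is.null(spec$grouping) &&
    nlevels(tab[[spec$grouping]]) >= 2L
  g <- if (!is.null(spec$grouping)) factor(tab[[spec$grouping]]) else
    factor(rep("all", nrow(tab)))
  centres <- levels(g)

  prec_b <- rep(1 / priors$beta_sd^2, ncol(X))
  prec_b[colnames(X) == "(Intercept)"] <- 1 / priors$intercept_sd^2
  jd <- list(y = as.integer(y), X = X, N = nrow(X), P = ncol(X),
             prec_b = prec_b)
  monitor <- "b"
  if (use_ranef) {
    jd$centre <- as.integer(g)
    jd$C <- nlevels(g)
    jd$prec_sigma <- 1 / priors$sigma_u_scale^2
    monitor <- c("b", "sigma_u", "u")
  }
  if (sir_draw == "posterior" && !use_ranef) {
    warning("no random intercept in the model; falling back to ",
            "sir_draw = \"expected\"")
    sir_draw <- "expected"
  }
  inits <- NULL
  if (!is.null(seed)) {
    rngs <- derive_seeds(seed, chains)
    inits <- lapply(seq_len(chains), function(k)
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = rngs[k]))
  }
  jm <- rjags::jags.model(textConnection(jags_model_string(use_ranef)),
                          data = jd, inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor, n.iter = kept,
                              progress.bar = "none")

  # observed counts, continuity-corrected like center_summaries()
  O <- as.vector(rowsum(as.numeric(y), g))
  corrected <- O == 0
  O[corrected] <- 0.5

  bcols <- paste0("b[", seq_len(ncol(X)), "]")
  if (ncol(X) == 1L) bcols <- intersect(c("b", "b[1]"), colnames(samp[[1]]))
  ucols <- paste0("u[", seq_along(centres), "]")
  # per chain: centers x kept matrix of log SIR draws
  chain_draws <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    bmat <- m[, bcols, drop = FALSE]
    nd <- nrow(bmat)
    umat <- if (sir_draw == "posterior") m[, ucols, drop = FALSE] else NULL
    out <- matrix(NA_real_, nrow = length(centres), ncol = nd)
    chunk <- 500L
    for (s in seq(1L, nd, by = chunk)) {
      e <- min(s + chunk - 1L, nd)
      eta <- X %*% t(bmat[s:e, , drop = FALSE])        # n x chunk
      Ec <- rowsum(plogis(eta), g)                     # centers x chunk
      if (sir_draw == "expected") {
        out[, s:e] <- log(O / Ec)
      } else {
        ui <- t(umat[s:e, , drop = FALSE])[as.integer(g), , drop = FALSE]
        Oc <- rowsum(plogis(eta + ui), g)
        out[, s:e] <- log(Oc / Ec)
      }
    }
    out
  })
  draws <- do.call(cbind, chain_draws)

  rhat <- ess <- numeric(length(centres))
  for (i in seq_along(centres)) {
    ml <- coda::mcmc.list(lapply(chain_draws, function(m) coda::mcmc(m[i, ])))
    rhat[i] <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1],
                        error = function(e) NA_real_)
    ess[i] <- sum(coda::effectiveSize(ml))
  }
  unconverged <- any(rhat > 1.05, na.rm = TRUE)
  if (unconverged) {
    warning("R-hat > 1.05 for center(s): ",
            paste(centres[which(rhat > 1.05)], collapse = ", "),
            "; results flagged `unconverged`")
  }

  v <- apply(draws, 1, stats::var)
  qs <- t(apply(draws, 1, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
  out <- new_variance_estimate(
    centres, "bayes", rowMeans(draws), v, qs[, 1], qs[, 2], level,
    lapply(seq_along(centres), function(i)
      list(n_chains = chains, n_iter = chains * per_chain,
           warmup = warmup, rhat = rhat[i], ess = ess[i],
           unconverged = unconverged, sir_draw = sir_draw,
           corrected = corrected[i]))
  )
  attr(out, "draws") <- draws
  attr(out, "sigma_u_draws") <- if (use_ranef)
    unlist(lapply(samp, function(ch) as.matrix(ch)[, "sigma_u"])) else NULL
  out
}

#' Map a log-scale interval to the SIR scale
#'
#' Exponentiates the interval endpoints (order preserved).
#'
#' @param est A `variance_estimate` data frame.
#' @return Data frame `centre_id`, `sir_low`, `sir_high`.
#' @export
interval_on_sir_scale <- function(est) {
  data.frame(centre_id = est$centre_id,
             sir_low = exp(est$ci_low), sir_high = exp(est$ci_high),
             stringsAsFactors = FALSE)
}

#' @rdname delta_variance
#' @param est A `variance_estimate` data frame.
#' @param path CSV path.
#' @export
write_variance_estimates <- function(est, path) {
  utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  invisible(path)
}
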