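make_summary <- function(O, E, n = 100) {
  s <- data.frame(centre_id = "A", n = n, O = O, E = E, sir = O / E,
                  log_sir = log(O / E), corrected = FALSE,
                  stringsAsFactors = FALSE)
  class(s) <- c("center_summary", "data.frame")
  s
}

test_that("delta variance matches its closed forms", {
  # poisson mode: Var = 1/O
  s <- make_summary(O = 100, E = 90)
  est <- delta_variance(s, mode = "poisson")
  expect_equal(est$variance, 0.01, tolerance = 1e-12)
  expect_equal(est$se, 0.1, tolerance = 1e-12)

  # binomial mode: 100 patients at p = 0.5, O = 50: Var(O) = 25, v = 0.01
  s2 <- make_summary(O = 50, E = 50)
  est2 <- delta_variance(s2, probs = rep(0.5, 100), centre = rep("A", 100),
                         mode = "binomial")
  expect_equal(est2$variance, 25 / 2500, tolerance = 1e-12)
  # Wald interval at 95%
  expect_equal(est2$ci_high - est2$ci_low, 2 * qnorm(0.975) * 0.1,
               tolerance = 1e-9)

  expect_error(delta_variance(make_summary(O = 0, E = 3), mode = "poisson"),
               "O <= 0")
})

test_that("poisson-mode delta variance dominates binomial mode", {
  cfg <- quick_config(seed = 59, n_centers = 8, sizes = c(40, 120))
  tab <- generate_population(cfg)$patients
  fit <- fit_risk_model(tab, quick_spec())
  probs <- predict_probability(fit, tab, "conditional_null")
  s <- center_summaries(tab, probs)
  vb <- delta_variance(s, probs, tab$centre_id, mode = "binomial")$variance
  vp <- delta_variance(s, mode = "poisson")$variance
  expect_true(all(vp >= vb))  # p(1-p) < p whenever p < 1
})

test_that("se and interval invariants hold for every method row", {
  cfg <- quick_config(seed = 61, n_centers = 4, sizes = c(50, 80))
  tab <- generate_population(cfg)$patients
  fit <- fit_risk_model(tab, quick_spec())
  probs <- predict_probability(fit, tab, "conditional_null")
  s <- center_summaries(tab, probs)
  est <- delta_variance(s, probs, tab$centre_id)
  expect_true(all(abs(est$se - sqrt(est$variance)) < 1e-12))
  expect_true(all(est$ci_low < est$ci_high))
  expect_true(all(est$variance > 0))
})

test_that("log-scale intervals exponentiate onto the SIR scale", {
  s <- make_summary(O = 10, E = 10)
  est <- delta_variance(s, mode = "poisson")
  est$ci_low <- 0; est$ci_high <- 0
  expect_equal(unlist(interval_on_sir_scale(est)[, 2:3]), c(sir_low = 1,
                                                            sir_high = 1))
  est$ci_low <- -0.1; est$ci_high <- 0.2
  si <- interval_on_sir_scale(est)
  expect_equal(si$sir_low, exp(-0.1), tolerance = 1e-12)
  expect_equal(si$sir_high, exp(0.2), tolerance = 1e-12)
  expect_equal(log(unlist(si[, 2:3])), c(sir_low = -0.1, sir_high = 0.2),
               tolerance = 1e-12)
})

test_that("bootstrap is deterministic given a seed and records diagnostics", {
  cfg <- quick_config(seed = 67, n_centers = 4, sizes = c(40, 60))
  tab <- generate_population(cfg)$patients
  spec <- quick_spec()
  b1 <- bootstrap_variance(tab, spec, B = 25, seed = 5)
  b2 <- bootstrap_variance(tab, spec, B = 25, seed = 5)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  d <- jsonlite::fromJSON(b1$diagnostics[1])
  expect_identical(d$B, 25L)
  expect_identical(d$scheme, "within_center")
  expect_error(bootstrap_variance(tab, spec, B = 1), "B")
})

test_that("a degenerate table with constant centers has zero bootstrap variance", {
  # every row within a center identical (covariates and outcome): each
  # resample reproduces the data exactly, so the replicate log SIRs are
  # constant
  tab <- data.frame(
    centre_id = rep(c("A", "B", "C", "D"), each = 20),
    status = rep(c(1L, 0L, 1L, 0L), each = 20),
    stringsAsFactors = FALSE)
  spec <- model_spec(fixed_effects = character(), grouping = "centre_id")
  est <- suppressWarnings(bootstrap_variance(tab, spec, B = 10, seed = 1))
  expect_equal(est$variance, rep(0, 4), tolerance = 1e-20)
  expect_equal(est$ci_low, est$ci_high, tolerance = 1e-12)
})

test_that("bootstrap variance is stable in B", {
  cfg <- quick_config(seed = 71, n_centers = 5, sizes = c(40, 60),
                      covs = "diabetes")
  tab <- generate_population(cfg)$patients
  spec <- model_spec(fixed_effects = "diabetes")
  b1 <- bootstrap_variance(tab, spec, B = 80, seed = 11, nAGQ = 0L)
  b2 <- bootstrap_variance(tab, spec, B = 160, seed = 12, nAGQ = 0L)
  # Monte-Carlo error of a variance over B replicates ~ v * sqrt(2/B);
  # allow 4 such SDs on the difference
  tol <- 4 * b1$variance * sqrt(2 / 80 + 2 / 160)
  expect_true(all(abs(b1$variance - b2$variance) < tol))
})

test_that("MCMC runs are seed-reproducible with per-center diagnostics", {
  cfg <- quick_config(seed = 73, n_centers = 4, sizes = c(30, 50))
  tab <- generate_population(cfg)$patients
  spec <- quick_spec()
  a1 <- suppressWarnings(bayesian_variance(tab, spec, chains = 2,
                                           total_iter = 800, warmup = 100,
                                           adapt = 150, seed = 9))
  a2 <- suppressWarnings(bayesian_variance(tab, spec, chains = 2,
                                           total_iter = 800, warmup = 100,
                                           adapt = 150, seed = 9))
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_true(all(a1$variance > 0))  # posterior variance strictly positive
  d <- jsonlite::fromJSON(a1$diagnostics[1])
  expect_identical(d$n_chains, 2L)
  expect_true(is.finite(d$rhat))
  expect_gt(d$ess, 0)
  expect_error(bayesian_variance(tab, spec, chains = 1), "chains")
})

test_that("all three methods rank center uncertainty consistently", {
  # large centers with strongly graded sizes: the SE ordering is driven by
  # center precision and should agree across methods
  cfg <- quick_config(seed = 79, n_centers = 8, sizes = c(1400, 1400))
  tab <- generate_population(cfg)$patients
  sizes <- round(100 * 1.45^(0:7))   # well-separated precision ladder
  tab <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    rows <- tab[tab$centre_id == sprintf("C%03d", k), ]
    rows[seq_len(sizes[k]), ]
  }))
  spec <- quick_spec()
  fit <- fit_risk_model(tab, spec)
  probs <- predict_probability(fit, tab, "conditional_null")
  s <- center_summaries(tab, probs)
  se_d <- delta_variance(s, probs, tab$centre_id)$se
  se_b <- bootstrap_variance(tab, spec, B = 60, seed = 3, nAGQ = 0L)$se
  se_m <- suppressWarnings(
    bayesian_variance(tab, spec, chains = 3, total_iter = 5400,
                      warmup = 300, seed = 4, sir_draw = "posterior"))$se
  expect_gte(cor(se_d, se_b, method = "spearman"), 0.9)
  expect_gte(cor(se_d, se_m, method = "spearman"), 0.9)
})
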