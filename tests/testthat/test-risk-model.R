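test_that("intercept-only fit recovers the closed-form Bernoulli MLE", {
  cfg <- quick_config(seed = 17, n_centers = 4, sizes = c(50, 80))
  tab <- generate_population(cfg)$patients
  spec0 <- model_spec(fixed_effects = character(), grouping = NULL)
  fit <- fit_risk_model(tab, spec0)
  expect_equal(fit$intercept_hat, qlogis(mean(tab$status)),
               tolerance = 1e-6)
  expect_identical(fit$sigma_u_hat, 0)
  expect_true(fit$converged)
})

test_that("fit rejects incomplete or non-binary data", {
  cfg <- quick_config(seed = 18)
  tab <- generate_population(cfg)$patients
  spec <- quick_spec()
  tab_na <- tab; tab_na$gender[3] <- NA
  expect_error(fit_risk_model(tab_na, spec), "missing values")
  tab_bad <- tab; tab_bad$status[1] <- 2L
  expect_error(fit_risk_model(tab_bad, spec), "binary")
})

test_that("coefficient names are stable covariate[level] labels", {
  cfg <- quick_config(seed = 19)
  fit <- fit_risk_model(generate_population(cfg)$patients, quick_spec())
  expect_setequal(names(fit$beta_hat), c("gender[female]", "diabetes[yes]"))
  expect_identical(length(fit$u_hat), 6L)
  expect_gte(fit$sigma_u_hat, 0)
})

test_that("predictions match hand-computed logistic probabilities", {
  spec <- quick_spec()
  fit <- fake_fit(
    coef_raw = c("(Intercept)" = -1, "genderfemale" = 0.5,
                 "diabetesyes" = -0.25),
    spec = spec,
    xlevels = list(gender = c("male", "female"), diabetes = c("no", "yes")))
  tab <- data.frame(gender = c("male", "female", "female"),
                    diabetes = c("no", "no", "yes"),
                    stringsAsFactors = FALSE)
  expect_equal(predict_probability(fit, tab, "conditional_null"),
               plogis(c(-1, -0.5, -0.75)), tolerance = 1e-12)

  # all coefficients zero: every probability exactly 1/2
  fit0 <- fake_fit(c("(Intercept)" = 0, "genderfemale" = 0,
                     "diabetesyes" = 0), spec, fit$xlevels)
  expect_identical(unique(predict_probability(fit0, tab)), 0.5)

  # unseen category level is a schema error naming the level
  tab_bad <- data.frame(gender = "other", diabetes = "no",
                        stringsAsFactors = FALSE)
  expect_error(predict_probability(fit, tab_bad), "other")
})

test_that("center-conditional prediction reduces to the null at u = 0", {
  cfg <- quick_config(seed = 23)
  tab <- generate_population(cfg)$patients
  fit <- fit_risk_model(tab, quick_spec())
  fit$u_hat[] <- 0
  expect_equal(predict_probability(fit, tab, "conditional_center"),
               predict_probability(fit, tab, "conditional_null"),
               tolerance = 1e-12)
  fit$sigma_u_hat <- 0
  expect_equal(predict_probability(fit, tab, "marginal"),
               predict_probability(fit, tab, "conditional_null"),
               tolerance = 1e-12)
})

test_that("raising an active coefficient raises the predicted probability", {
  spec <- quick_spec()
  xlev <- list(gender = c("male", "female"), diabetes = c("no", "yes"))
  tab <- data.frame(gender = "female", diabetes = "yes",
                    stringsAsFactors = FALSE)
  p <- vapply(seq(-1, 1, by = 0.25), function(b) {
    f <- fake_fit(c("(Intercept)" = -0.5, "genderfemale" = b,
                    "diabetesyes" = 0.2), spec, xlev)
    predict_probability(f, tab)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("fits are invariant to row order", {
  cfg <- quick_config(seed = 29, n_centers = 8, sizes = c(100, 150))
  tab <- generate_population(cfg)$patients
  fit1 <- fit_risk_model(tab, quick_spec())
  set.seed(1)
  fit2 <- fit_risk_model(tab[sample.int(nrow(tab)), ], quick_spec())
  # summation order in the Laplace deviance moves the optimum at ~1e-7
  expect_equal(fit1$beta_hat, fit2$beta_hat, tolerance = 1e-6)
  expect_equal(fit1$sigma_u_hat, fit2$sigma_u_hat, tolerance = 1e-6)
})

test_that("maximized likelihood dominates the generating parameters", {
  # on the no-random-effect path the exact Bernoulli log-likelihood at the
  # MLE must beat the truth on every replicate
  for (s in 1:8) {
    cfg <- quick_config(seed = 100 + s, n_centers = 4, sizes = c(80, 120),
                        sigma_u = 0)
    tab <- generate_population(cfg)$patients
    fit <- fit_risk_model(tab, model_spec(fixed_effects = c("gender",
                                                            "diabetes"),
                                          grouping = NULL))
    eta_true <- sirvar:::fixed_linear_predictor(cfg, tab)
    ll_true <- sum(dbinom(tab$status, 1, plogis(eta_true), log = TRUE))
    expect_gte(fit$loglik, ll_true - 1e-8)
  }
})

test_that("a single-center table falls back to plain logistic regression", {
  cfg <- quick_config(seed = 37, n_centers = 1, sizes = c(200, 200))
  tab <- generate_population(cfg)$patients
  expect_warning(fit <- fit_risk_model(tab, quick_spec()), "fewer than 2")
  expect_identical(fit$sigma_u_hat, 0)
  expect_true(fit$converged)
})
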