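# Shared fixtures: all synthetic, built in code.

# Small registry configuration with a reduced covariate set, for fast fits.
quick_config <- function(n_centers = 6, sizes = c(60, 100), sigma_u = 0.3,
                         seed = 7, covs = c("gender", "diabetes"),
                         intercept = -1.2, ...) {
  sim_config(n_centers = n_centers, center_size_range = sizes,
             beta = default_beta()[covs], sigma_u = sigma_u,
             intercept = intercept, seed = seed, ...)
}

quick_spec <- function(covs = c("gender", "diabetes")) {
  model_spec(outcome = "status", fixed_effects = covs,
             grouping = "centre_id")
}

# Hand-buildable risk_fit with known coefficients, for prediction oracles.
fake_fit <- function(coef_raw, spec, xlevels, u_hat = numeric(),
                     sigma_u_hat = 0) {
  structure(list(coef_raw = coef_raw, spec = spec, xlevels = xlevels,
                 u_hat = u_hat, sigma_u_hat = sigma_u_hat),
            class = "risk_fit")
}

# Tiny hand-written patient table for the filter fixtures.
toy_table <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:10),
    centre_id = c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C"),
    status = c(1L, 0L, 1L, 0L, 0L, 1L, 2L, 0L, 1L, 0L),
    indigenous = c("indigenous", "indigenous", "non-indigenous",
                   "indigenous", "non-indigenous", "non-indigenous",
                   "indigenous", "non-indigenous", "non-indigenous",
                   "non-indigenous"),
    late = c("no", "yes", NA, "no", "yes", NA, "no", "yes", "no", NA),
    year = c(2004L, 2004L, 2004L, 2012L, 2015L, 2019L, 2020L, 2021L,
             2022L, 2023L),
    stringsAsFactors = FALSE
  )
}
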