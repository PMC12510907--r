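test_that("logistic(0) generator yields prevalence 1/2 and degenerate nulls", {
  cfg <- sim_config(n_centers = 10, center_size_range = c(500, 500),
                    intercept = 0, beta = list(), sigma_u = 0, seed = 3)
  pop <- generate_population(cfg)
  n <- nrow(pop$patients)
  expect_identical(n, 5000L)
  # symmetry: mean(status) ~ 0.5 within 3 Monte-Carlo SEs
  expect_lt(abs(mean(pop$patients$status) - 0.5), 3 * sqrt(0.25 / n))
  # degenerate random effect
  expect_true(all(pop$truth$u_c == 0))
  expect_true(all(pop$truth$in_control))
  expect_true(all(pop$truth$true_sir == 1))
})

test_that("center random intercepts have the configured spread", {
  cfg <- sim_config(n_centers = 200, center_size_range = c(5, 10),
                    sigma_u = 0.4, seed = 11)
  pop <- generate_population(cfg)
  u <- pop$truth$u_c
  se_sd <- 0.4 / sqrt(2 * (length(u) - 1))  # asymptotic SE of the sample SD
  expect_lt(abs(sd(u) - 0.4), 3 * se_sd)
})

test_that("generation is byte-identical under the same configuration", {
  cfg <- quick_config(seed = 21)
  expect_identical(generate_population(cfg), generate_population(cfg))
  # missingness uses its own sub-stream: outcomes unchanged by it
  cfg2 <- quick_config(seed = 21)
  cfg2$missing_rates <- list(late = 0.2)
  pop2 <- generate_population(cfg2)
  expect_identical(pop2$patients$status,
                   generate_population(cfg)$patients$status)
})

test_that("empirical prevalence converges to the model average at large n", {
  cfg <- sim_config(n_centers = 10, center_size_range = c(10000, 10000),
                    sigma_u = 0.25, seed = 5)
  pop <- generate_population(cfg)
  eta <- sirvar:::fixed_linear_predictor(cfg, pop$patients)
  u <- pop$truth$u_c[match(pop$patients$centre_id, pop$truth$centre_id)]
  target <- mean(plogis(eta + u))
  n <- nrow(pop$patients)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(pop$patients$status) - target),
            3 * sqrt(target * (1 - target) / n))
})

test_that("true SIR matches closed forms and a brute-force oracle", {
  cfg <- sim_config(n_centers = 2, center_size_range = c(1, 1),
                    intercept = 0, beta = list(), sigma_u = 0, seed = 1)
  tab <- data.frame(centre_id = c("X", "Y"), gender = "male",
                    stringsAsFactors = FALSE)
  truth <- data.frame(centre_id = c("X", "Y"), u_c = c(0, log(3)),
                      true_sir = NA_real_, in_control = c(TRUE, FALSE))
  out <- compute_true_sir(cfg, truth, tab)
  expect_identical(out$true_sir[out$centre_id == "X"], 1)  # exact, not approx
  # single patient, eta = 0, u = ln 3: logistic(ln 3)/logistic(0) = 1.5
  expect_equal(out$true_sir[out$centre_id == "Y"], 0.75 / 0.5,
               tolerance = 1e-12)

  # multi-patient center with mixed eta vs an independent per-patient loop
  cfg2 <- quick_config(n_centers = 4, sizes = c(10, 30), seed = 9)
  pop <- generate_population(cfg2)
  eta <- sirvar:::fixed_linear_predictor(cfg2, pop$patients)
  for (k in seq_len(nrow(pop$truth))) {
    rows <- which(pop$patients$centre_id == pop$truth$centre_id[k])
    num <- den <- 0
    for (i in rows) {  # brute-force loop oracle
      num <- num + plogis(eta[i] + pop$truth$u_c[k])
      den <- den + plogis(eta[i])
    }
    expect_equal(pop$truth$true_sir[k], num / den, tolerance = 1e-12)
  }
})

test_that("compute_true_sir drops centers without patients, with a warning", {
  cfg <- quick_config(n_centers = 3, sizes = c(5, 5), seed = 2)
  pop <- generate_population(cfg)
  truth <- rbind(pop$truth,
                 data.frame(centre_id = "GHOST", u_c = 0.5,
                            true_sir = NA_real_, in_control = FALSE))
  expect_warning(out <- compute_true_sir(cfg, truth, pop$patients), "GHOST")
  expect_setequal(out$centre_id, pop$truth$centre_id)
})

test_that("missingness injection follows its per-field rates", {
  cfg <- quick_config(seed = 4)
  pop <- generate_population(cfg)

  expect_identical(inject_missingness(pop$patients, cfg), pop$patients)

  cfg$missing_rates <- list(late = 1)
  expect_true(all(is.na(inject_missingness(pop$patients, cfg)$late)))

  big <- sim_config(n_centers = 10, center_size_range = c(1000, 1000),
                    missing_rates = list(late = 0.1), seed = 8)
  tab <- inject_missingness(generate_population(big)$patients, big)
  n <- nrow(tab)
  expect_identical(n, 10000L)
  expect_lt(abs(sum(is.na(tab$late)) - 0.1 * n),
            3 * sqrt(n * 0.1 * 0.9))
  # original untouched fields
  expect_false(anyNA(tab$status))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(sigma_u = -0.1), "sigma_u")
  expect_error(sim_config(center_size_range = c(0, 5)), "center_size_range")
  expect_error(sim_config(covariate_freqs = list(gender = c(0.5, 0.6))),
               "gender")
  expect_error(sim_config(missing_rates = list(late = 1.5)), "late")
  expect_error(sim_config(beta = list(gender = c(male = 1))), "gender")
})

test_that("patient table round-trips through CSV with empty-string NAs", {
  cfg <- quick_config(seed = 13, n_centers = 3, sizes = c(10, 20))
  cfg$missing_rates <- list(late = 0.3)
  pop <- generate_population(cfg)
  tab <- inject_missingness(pop$patients, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_table(tab, path)
  expect_false(grepl("NA", paste(readLines(path), collapse = "")))
  back <- read_patient_table(path)
  expect_identical(back$late, tab$late)
  expect_identical(back$status, tab$status)
})

test_that("YAML simulation configs merge over documented defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_centers: 4", "sigma_u: 0.5",
               "beta:", "  diabetes:", "    \"yes\": 0.4"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$n_centers, 4L)
  expect_identical(cfg$sigma_u, 0.5)
  expect_identical(names(cfg$beta), "diabetes")
  expect_identical(cfg$center_size_range, c(100L, 600L))  # default kept
  writeLines("not_a_field: 1", path)
  expect_error(read_sim_config(path), "not_a_field")
})
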