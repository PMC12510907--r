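#' Covariate dictionary of the synthetic dialysis registry
#'
#' Category levels for every risk-adjustment covariate in the synthetic
#' registry: patient demographics (gender, 7 age bands, Indigenous status),
#' comorbidities (lung disease, diabetes, cardiovascular disease), late
#' referral, obesity (BMI >= 30), a 7-level remoteness scale (MM1
#' metropolitan to MM7 very remote) and a 3-level treatment-era period.
#' The first level of each covariate is its reference level: coefficient
#' maps omit it.
#'
#' @return Named list of character vectors, one per covariate.
#' @export
registry_dictionary <- function() {
  list(
    gender     = c("male", "female"),
    agegp      = c("16-25", "26-35", "36-45", "46-55", "56-65", "66-75", "76+"),
    indigenous = c("non-indigenous", "indigenous"),
    lung       = c("no", "yes"),
    diabetes   = c("no", "yes"),
    cvd        = c("no", "yes"),
    late       = c("no", "yes"),
    bmi30      = c("no", "yes"),
    mmm        = paste0("MM", 1:7),
    timegp     = c("2012-2015", "2016-2019", "2020-2023")
  )
}

#' Default generator settings
#'
#' `default_covariate_freqs()` gives the category frequencies and
#' `default_beta()` the log-odds coefficients (non-reference levels only)
#' used by [sim_config()] unless overridden: modest positive effects for
#' age, comorbidities, late referral and remoteness, chosen to mimic a
#' realistic case-mix gradient in a dialysis registry.
#'
#' @return Named list keyed by covariate.
#' @export
default_covariate_freqs <- function() {
  list(
    gender     = c(0.55, 0.45),
    agegp      = c(0.08, 0.10, 0.14, 0.18, 0.20, 0.18, 0.12),
    indigenous = c(0.80, 0.20),
    lung       = c(0.85, 0.15),
    diabetes   = c(0.60, 0.40),
    cvd        = c(0.70, 0.30),
    late       = c(0.72, 0.28),
    bmi30      = c(0.65, 0.35),
    mmm        = c(0.42, 0.14, 0.10, 0.09, 0.09, 0.09, 0.07),
    timegp     = c(0.32, 0.34, 0.34)
  )
}

#' @rdname default_covariate_freqs
#' @export
default_beta <- function() {
  list(
    gender     = c("female" = -0.10),
    agegp      = c("26-35" = 0.10, "36-45" = 0.20, "46-55" = 0.30,
                   "56-65" = 0.45, "66-75" = 0.60, "76+" = 0.80),
    indigenous = c("indigenous" = 0.30),
    lung       = c("yes" = 0.30),
    diabetes   = c("yes" = 0.40),
    cvd        = c("yes" = 0.35),
    late       = c("yes" = 0.50),
    bmi30      = c("yes" = 0.15),
    mmm        = c("MM2" = 0.05, "MM3" = 0.10, "MM4" = 0.15,
                   "MM5" = 0.20, "MM6" = 0.30, "MM7" = 0.40),
    timegp     = c("2016-2019" = -0.10, "2020-2023" = -0.20)
  )
}

#' Configuration of the synthetic registry generator
#'
#' Defines the data-generating process: a random-intercept logistic model
#' `logit P(status = 1) = intercept + x' beta + u_c`, with center effects
#' `u_c ~ N(0, sigma_u^2)`, covariates sampled independently from
#' `covariate_freqs`, center sizes uniform on `center_size_range`, and
#' optional missingness and censoring for the cohort-filter stage.
#'
#' @param n_centers Number of treatment centers.
#' @param center_size_range Integer `c(min, max)`; per-center patient counts
#'   are drawn uniformly on this range.
#' @param intercept Log-odds intercept of the outcome model.
#' @param beta Named list, one entry per covariate, each a named numeric
#'   vector of log-odds coefficients for the non-reference levels (the first
#'   dictionary level is the reference and is omitted).
#' @param sigma_u Standard deviation (log-odds scale) of the center random
#'   intercepts; `0` gives the global null in which every center is in
#'   control.
#' @param covariate_freqs Named list of category probability vectors, one per
#'   covariate, aligned with [registry_dictionary()] levels.
#' @param missing_rates Named list of per-field missingness probabilities in
#'   `[0, 1]`, applied by [inject_missingness()].
#' @param censored_rate Probability that a patient's outcome is recorded as
#'   censored (`censored_code`) rather than 0/1; exercises the status filter.
#' @param censored_code Integer code used for censored outcomes.
#' @param period_range Integer `c(first, last)` calendar year; `year` is
#'   uniform on this range.
#' @param seed Integer seed; the full generated registry is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_centers = 20,
                       center_size_range = c(100, 600),
                       intercept = -1.6,
                       beta = default_beta(),
                       sigma_u = 0.3,
                       covariate_freqs = default_covariate_freqs(),
                       missing_rates = list(),
                       censored_rate = 0,
                       censored_code = 2L,
                       period_range = c(2012, 2023),
                       seed = 1L) {
  cfg <- list(
    n_centers = as.integer(n_centers),
    center_size_range = as.integer(center_size_range),
    intercept = intercept,
    beta = beta,
    sigma_u = sigma_u,
    covariate_freqs = covariate_freqs,
    missing_rates = missing_rates,
    censored_rate = censored_rate,
    censored_code = as.integer(censored_code),
    period_range = as.integer(period_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  dict <- registry_dictionary()
  if (!is.numeric(cfg$n_centers) || cfg$n_centers < 1) {
    stop_config("invalid `n_centers`: must be a positive integer")
  }
  if (length(cfg$center_size_range) != 2L || cfg$center_size_range[1] < 1 ||
      cfg$center_size_range[1] > cfg$center_size_range[2]) {
    stop_config("invalid `center_size_range`: need c(min, max) with min >= 1")
  }
  if (!is.numeric(cfg$sigma_u) || cfg$sigma_u < 0) {
    stop_config("invalid `sigma_u`: must be >= 0")
  }
  for (v in names(cfg$covariate_freqs)) {
    if (!v %in% names(dict)) {
      stop_config("invalid `covariate_freqs`: unknown covariate '", v, "'")
    }
    p <- cfg$covariate_freqs[[v]]
    if (length(p) != length(dict[[v]])) {
      stop_config("invalid `covariate_freqs$", v, "`: need ",
                  length(dict[[v]]), " probabilities")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop_config("invalid `covariate_freqs$", v,
                  "`: probabilities must be >= 0 and sum to 1 (within 1e-12)")
    }
  }
  for (v in names(cfg$beta)) {
    if (!v %in% names(dict)) {
      stop_config("invalid `beta`: unknown covariate '", v, "'")
    }
    bad <- setdiff(names(cfg$beta[[v]]), dict[[v]][-1])
    if (length(bad)) {
      stop_config("invalid `beta$", v, "`: unknown level(s) ",
                  paste(bad, collapse = ", "),
                  " (reference level '", dict[[v]][1], "' must be omitted)")
    }
  }
  for (v in names(cfg$missing_rates)) {
    r <- cfg$missing_rates[[v]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop_config("invalid `missing_rates$", v, "`: must lie in [0, 1]")
    }
  }
  if (cfg$censored_rate < 0 || cfg$censored_rate > 1) {
    stop_config("invalid `censored_rate`: must lie in [0, 1]")
  }
  if (length(cfg$period_range) != 2L ||
      cfg$period_range[1] > cfg$period_range[2]) {
    stop_config("invalid `period_range`: need c(first, last) with first <= last")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic registry configuration\n")
  cat(sprintf("  centers: %d, sizes %d-%d, sigma_u = %.3g, intercept = %.3g\n",
              x$n_centers, x$center_size_range[1], x$center_size_range[2],
              x$sigma_u, x$intercept))
  cat(sprintf("  covariates: %s\n", paste(names(x$beta), collapse = ", ")))
  cat(sprintf("  period %d-%d, seed %d\n",
              x$period_range[1], x$period_range[2], x$seed))
  invisible(x)
}

# True fixed-effect linear predictor (intercept + x'beta) for every row,
# from the generating coefficients -- not a fitted model.
fixed_linear_predictor <- function(config, table) {
  eta <- rep(config$intercept, nrow(table))
  for (v in names(config$beta)) {
    b <- config$beta[[v]]
    val <- unname(b[match(as.character(table[[v]]), names(b))])
    val[is.na(val)] <- 0  # reference level (or missing cell) contributes 0
    eta <- eta + val
  }
  eta
}

#' Generate a synthetic patient registry with known center effects
#'
#' Draws center sizes and random intercepts, samples covariates
#' independently from the configured frequencies, and generates binary
#' outcomes from the random-intercept logistic model. The result is a
#' deterministic function of the configuration (including its seed):
#' the seed is split into separate sub-streams for center structure,
#' covariates, outcomes and missingness, so turning missingness on or off
#' leaves the outcomes untouched.
#'
#' @param config A [sim_config()].
#' @return List with `patients` (the patient table: `patient_id`,
#'   `centre_id`, `status`, the ten covariates, `year`) and `truth` (one row
#'   per center: `centre_id`, `u_c`, `true_sir`, `in_control`).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  dict <- registry_dictionary()
  seeds <- derive_seeds(config$seed, 4)

  # stream 1: center structure
  set.seed(seeds[1])
  rng <- config$center_size_range
  sizes <- rng[1] + sample.int(rng[2] - rng[1] + 1L, config$n_centers,
                               replace = TRUE) - 1L
  u <- if (config$sigma_u > 0) rnorm(config$n_centers, 0, config$sigma_u) else
    rep(0, config$n_centers)
  centre_ids <- sprintf("C%03d", seq_len(config$n_centers))

  n <- sum(sizes)
  tab <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    centre_id = rep(centre_ids, sizes),
    stringsAsFactors = FALSE
  )

  # stream 2: covariates and calendar year
  set.seed(seeds[2])
  for (v in names(dict)) {
    p <- config$covariate_freqs[[v]] %||%
      rep(1 / length(dict[[v]]), length(dict[[v]]))
    tab[[v]] <- sample(dict[[v]], n, replace = TRUE, prob = p)
  }
  tab$year <- sample(seq(config$period_range[1], config$period_range[2]),
                     n, replace = TRUE)

  # stream 3: outcomes (and censoring marks, drawn after the outcomes)
  set.seed(seeds[3])
  eta <- fixed_linear_predictor(config, tab) + rep(u, sizes)
  tab$status <- rbinom(n, 1L, plogis(eta))
  if (config$censored_rate > 0) {
    cens <- runif(n) < config$censored_rate
    tab$status[cens] <- config$censored_code
  }
  tab <- tab[, c("patient_id", "centre_id", "status", names(dict), "year")]

  truth <- data.frame(centre_id = centre_ids, u_c = u,
                      true_sir = NA_real_, in_control = u == 0,
                      stringsAsFactors = FALSE)
  truth <- compute_true_sir(config, truth, tab)
  list(patients = tab, truth = truth)
}

#' True standardized incidence ratio of each center
#'
#' The reference value that bias/MSE evaluation measures against: for
#' center c, `true_sir_c = sum_i plogis(eta_i + u_c) / sum_i plogis(eta_i)`
#' over the center's patients, where `eta_i` is the true fixed-effect linear
#' predictor. A center with `u_c = 0` has `true_sir = 1` exactly.
#'
#' @param config The generating [sim_config()].
#' @param truth Truth table with `centre_id` and `u_c`.
#' @param table Patient table generated from `config`.
#' @return `truth` with its `true_sir` column filled in; centers with no
#'   patients are dropped with a warning.
#' @export
compute_true_sir <- function(config, truth, table) {
  eta <- fixed_linear_predictor(config, table)
  idx <- match(table$centre_id, truth$centre_id)
  num <- rowsum(plogis(eta + truth$u_c[idx]), table$centre_id)
  den <- rowsum(plogis(eta), table$centre_id)
  present <- truth$centre_id %in% rownames(num)
  if (any(!present)) {
    warning("excluding center(s) with zero patients: ",
            paste(truth$centre_id[!present], collapse = ", "))
    truth <- truth[present, , drop = FALSE]
  }
  truth$true_sir <- ifelse(truth$u_c == 0, 1,
                           num[truth$centre_id, 1] / den[truth$centre_id, 1])
  truth
}

#' Inject missingness into registry fields
#'
#' Independently sets each targeted cell to `NA` with its configured rate,
#' using the missingness sub-stream of the configuration seed. The input
#' table is not modified.
#'
#' @param table Patient table.
#' @param config A [sim_config()] whose `missing_rates` name the fields.
#' @return A copy of `table` with missing cells.
#' @export
inject_missingness <- function(table, config) {
  validate_sim_config(config)
  bad <- setdiff(names(config$missing_rates), names(table))
  if (length(bad)) {
    stop_config("`missing_rates` names field(s) not in the table: ",
                paste(bad, collapse = ", "))
  }
  if (!length(config$missing_rates)) return(table)
  set.seed(derive_seeds(config$seed, 4)[4])
  for (v in names(config$missing_rates)) {
    hit <- runif(nrow(table)) < config$missing_rates[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Read / write the patient table and truth table as CSV
#'
#' Missing cells are written as empty strings, the fixed header is
#' `patient_id, centre_id, status, gender, agegp, indigenous, lung,
#' diabetes, cvd, late, bmi30, mmm, timegp, year`.
#'
#' @param table Patient table (or truth table for the `truth` variants).
#' @param path File path.
#' @return `read_patient_table()` returns the table; writers return the
#'   path invisibly.
#' @export
write_patient_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  for (v in intersect(c("status", "year"), names(tab))) {
    tab[[v]] <- as.integer(tab[[v]])
  }
  tab
}

#' @rdname write_patient_table
#' @export
write_truth_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Every field of [sim_config()] may be set; unset fields keep their
#' documented defaults, unknown fields are an error.
#'
#' @param path YAML file path.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_config("unknown simulation config field(s): ",
                paste(bad, collapse = ", "))
  }
  for (v in c("beta", "covariate_freqs")) {
    if (!is.null(raw[[v]])) raw[[v]] <- lapply(raw[[v]], unlist)
  }
  do.call(sim_config, raw)
}
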