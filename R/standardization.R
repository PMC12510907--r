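#' Per-center observed and expected counts, SIR and log SIR
#'
#' Indirect standardization: for each center c, the observed event count
#' `O_c = sum(status)` is compared with the model-based expected count
#' `E_c = sum(p_hat)` over the center's own patients, giving
#' `SIR_c = O_c / E_c` and its natural log. Expected counts conserve the
#' predictions exactly: `sum_c E_c = sum_i p_hat_i`.
#'
#' Centers with `O_c = 0` get a continuity correction `O* = 0.5` (flagged in
#' the `corrected` column) so that log SIR and its variance stay finite; set
#' `zero_obs = "exclude"` to drop them instead.
#'
#' @param table Patient table with the outcome and center columns.
#' @param probs Per-row predicted probabilities aligned with `table`,
#'   typically [predict_probability()] in `conditional_null` mode.
#' @param outcome,centre Column names (defaults `status`, `centre_id`).
#' @param min_center_size Centers with fewer patients are excluded with a
#'   warning (default 1 keeps everything non-empty).
#' @param zero_obs How to treat `O_c = 0`: `"correct"` (O* = 0.5) or
#'   `"exclude"`.
#' @return A `center_summary` data frame: `centre_id`, `n`, `O`, `E`, `sir`,
#'   `log_sir`, `corrected`.
#' @export
center_summaries <- function(table, probs, outcome = "status",
                             centre = "centre_id", min_center_size = 1L,
                             zero_obs = c("correct", "exclude")) {
  zero_obs <- match.arg(zero_obs)
  if (length(probs) != nrow(table)) {
    stop_data("`probs` must align with the rows of `table`")
  }
  if (any(probs <= 0 | probs >= 1)) {
    stop_data("all probabilities must lie strictly in (0, 1)")
  }
  y <- table[[outcome]]
  if (!all(y %in% c(0, 1))) stop_data("outcome must be strictly binary 0/1")

  g <- factor(as.character(table[[centre]]))
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty)) {
    warning("excluding empty center(s): ", paste(empty, collapse = ", "))
  }
  n <- as.vector(table(g))
  O <- as.vector(rowsum(as.numeric(y), g))
  E <- as.vector(rowsum(probs, g))
  out <- data.frame(centre_id = levels(g), n = n, O = O, E = E,
                    corrected = FALSE, stringsAsFactors = FALSE)

  small <- out$n < min_center_size
  if (any(small)) {
    warning("excluding ", sum(small), " center(s) below minimum size ",
            min_center_size)
    out <- out[!small, , drop = FALSE]
  }
  zero <- out$O == 0
  if (any(zero)) {
    if (zero_obs == "exclude") {
      warning("excluding ", sum(zero), " center(s) with zero observed events")
      out <- out[!zero, , drop = FALSE]
    } else {
      warning(sum(zero), " center(s) with zero observed events: applying ",
              "continuity correction O* = 0.5")
      out$O[zero] <- 0.5
      out$corrected[zero] <- TRUE
    }
  }
  out$sir <- out$O / out$E
  out$log_sir <- log(out$sir)
  out <- out[, c("centre_id", "n", "O", "E", "sir", "log_sir", "corrected")]
  rownames(out) <- NULL
  class(out) <- c("center_summary", "data.frame")
  out
}

#' @rdname center_summaries
#' @param path CSV path.
#' @export
write_center_summaries <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname center_summaries
#' @export
read_center_summaries <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(centre_id = "character"))
  class(out) <- c("center_summary", "data.frame")
  out
}
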