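# Funnel plots for provider profiling: SIR against expected count E, with
# control limits around the null SIR = 1 that tighten as precision grows.

#' Funnel-plot control limits
#'
#' Under the null SIR = 1, the log-scale standard error at precision E is
#' `sqrt(1/E)` (Poisson delta form), so the SIR-scale limits at level
#' `1 - alpha` are `exp(+/- z_{alpha/2} / sqrt(E))`. Conventional levels are
#' 95% and 99.8% (roughly 2 and 3 SDs).
#'
#' @param E_grid Positive expected counts (the precision axis).
#' @param levels Control-limit levels (default `c(0.95, 0.998)`).
#' @return Data frame with `E` and, per level L, `limit_low_<L>` /
#'   `limit_high_<L>` columns (e.g. `limit_low_95`, `limit_high_998`).
#' @export
funnel_limits <- function(E_grid, levels = c(0.95, 0.998)) {
  if (any(E_grid <= 0)) stop_data("`E_grid` must be positive")
  out <- data.frame(E = E_grid)
  se <- sqrt(1 / E_grid)
  for (l in sort(levels)) {
    z <- stats::qnorm(1 - (1 - l) / 2)
    out[[paste0("limit_low_", fmt_level(l))]] <- exp(-z * se)
    out[[paste0("limit_high_", fmt_level(l))]] <- exp(z * se)
  }
  out
}

#' Flag centers outside funnel or interval limits
#'
#' A center is `above`/`below` when its SIR lies strictly outside the
#' control limit at its own expected count (a point exactly on the limit is
#' `inside`). Alternatively, pass per-center `estimates` (a
#' `variance_estimate` table) to flag by the method's own interval for
#' log SIR excluding 0.
#'
#' @param summaries A [center_summaries()] table.
#' @param level Control-limit level (used for funnel flagging).
#' @param estimates Optional `variance_estimate` table; when given, interval
#'   flagging is used instead of funnel limits.
#' @return Factor (`inside`, `above`, `below`), one per center.
#' @export
flag_outliers <- function(summaries, level = 0.95, estimates = NULL) {
  if (!is.null(estimates)) {
    i <- match(summaries$centre_id, estimates$centre_id)
    if (anyNA(i)) stop_data("`estimates` does not cover every center")
    est <- estimates[i, ]
    out <- ifelse(est$ci_low > 0, "above",
                  ifelse(est$ci_high < 0, "below", "inside"))
  } else {
    lim <- funnel_limits(summaries$E, levels = level)
    lo <- lim[[paste0("limit_low_", fmt_level(level))]]
    hi <- lim[[paste0("limit_high_", fmt_level(level))]]
    out <- ifelse(summaries$sir > hi, "above",
                  ifelse(summaries$sir < lo, "below", "inside"))
  }
  factor(out, levels = c("inside", "above", "below"))
}

#' Draw a funnel plot
#'
#' Centers as points (SIR vs expected count), solid null line at SIR = 1,
#' dashed/dotted control-limit curves at the requested levels; flagged
#' centers are highlighted.
#'
#' @param summaries A [center_summaries()] table.
#' @param levels Control-limit levels.
#' @param flag_level Level used to highlight outlying centers.
#' @param main Plot title.
#' @return The funnel-limit grid, invisibly.
#' @export
plot_funnel <- function(summaries, levels = c(0.95, 0.998),
                        flag_level = 0.95,
                        main = "Funnel plot of standardized incidence ratios") {
  E_grid <- exp(seq(log(max(min(summaries$E) * 0.8, 0.5)),
                    log(max(summaries$E) * 1.2), length.out = 200))
  lim <- funnel_limits(E_grid, levels = levels)
  flags <- flag_outliers(summaries, level = flag_level)
  ymax <- max(summaries$sir, unlist(lim[, -1]), 1.1)
  plot(summaries$E, summaries$sir, xlab = "Expected count E",
       ylab = "SIR (O / E)", main = main, pch = 19,
       col = ifelse(flags == "inside", "grey30", "firebrick"),
       ylim = c(0, ymax))
  abline(h = 1, col = "grey50")
  ltys <- c(2, 3)
  for (k in seq_along(sort(levels))) {
    l <- sort(levels)[k]
    lines(E_grid, lim[[paste0("limit_low_", fmt_level(l))]], lty = ltys[k])
    lines(E_grid, lim[[paste0("limit_high_", fmt_level(l))]], lty = ltys[k])
  }
  legend("topright", bty = "n", lty = ltys,
         legend = sprintf("%s%% limits", format(100 * sort(levels))))
  invisible(lim)
}

#' Export funnel-plot data and figure
#'
#' Writes the per-center plot data and limit curves as CSV and renders the
#' funnel as a vector graphic (SVG when cairo is available, otherwise PDF).
#'
#' @param summaries A [center_summaries()] table (may be empty: the figure
#'   then shows only the limit curves).
#' @param points Funnel-limit grid from [funnel_limits()].
#' @param csv_path,fig_path Output paths; `fig_path`'s extension selects the
#'   device.
#' @param levels Control-limit levels for the figure.
#' @return Invisibly, the two paths.
#' @export
export_funnel <- function(summaries, points, csv_path, fig_path,
                          levels = c(0.95, 0.998)) {
  utils::write.csv(points, csv_path, row.names = FALSE)
  dev <- if (grepl("\\.pdf$", fig_path)) {
    function(f) grDevices::pdf(f, width = 7, height = 5)
  } else {
    function(f) grDevices::svg(f, width = 7, height = 5)
  }
  dev(fig_path)
  on.exit(grDevices::dev.off())
  if (nrow(summaries)) {
    plot_funnel(summaries, levels = levels)
  } else {
    lim <- funnel_limits(points$E, levels = levels)
    plot(NA, xlim = range(points$E), ylim = c(0, 2.5),
         xlab = "Expected count E", ylab = "SIR (O / E)",
         main = "Funnel control limits")
    abline(h = 1, col = "grey50")
    for (k in seq_along(sort(levels))) {
      l <- sort(levels)[k]
      lines(points$E, lim[[paste0("limit_low_", fmt_level(l))]], lty = k + 1)
      lines(points$E, lim[[paste0("limit_high_", fmt_level(l))]], lty = k + 1)
    }
  }
  invisible(c(csv_path, fig_path))
}
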