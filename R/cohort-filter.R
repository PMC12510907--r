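# Exclusion cascade: each filter consumes a patient table (or the result of
# the previous filter) and returns an auditable filter_result, so the whole
# cascade can be reported as an attrition table.

filter_result <- function(name, table_in, table_out) {
  out <- list(name = name,
              n_in = nrow(table_in),
              n_out = nrow(table_out),
              n_dropped = nrow(table_in) - nrow(table_out),
              table = table_out)
  class(out) <- "filter_result"
  out
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter %s> in %d -> out %d (dropped %d)\n",
              x$name, x$n_in, x$n_out, x$n_dropped))
  invisible(x)
}

# Accept either a raw table or the previous filter's result, so filters chain.
as_patient_table <- function(x) {
  if (inherits(x, "filter_result")) x$table else x
}

#' Cohort exclusion filters
#'
#' Composable filters reproducing a registry study's exclusion cascade:
#' restriction to a study period, exclusion of centers with too few patients
#' in a subgroup of interest, complete-case exclusion of rows with missing
#' fields, and removal of censored outcomes. Each returns a `filter_result`
#' carrying the filtered table together with in/out/dropped row counts;
#' results chain (any filter accepts the previous one's output) and the
#' chain is summarized by [attrition_report()].
#'
#' `filter_min_group_per_center()` drops *all* rows of a center whose count
#' of `group_var == group_level` rows is below `min_count` (the whole center
#' is removed, not just the small subgroup, because per-center subgroup
#' comparisons need adequate counts on both sides).
#'
#' @param table Patient table or a previous `filter_result`.
#' @param start_year,end_year Inclusive calendar-year bounds.
#' @param group_var,group_level Column and level whose per-center count is
#'   thresholded; defaults `"indigenous"` / `"indigenous"`.
#' @param min_count Minimum per-center count of the subgroup (default 20).
#' @param fields Character vector of columns; rows missing *any* of them are
#'   dropped (complete-case).
#' @param censored_code Outcome code marking censored rows (default 2).
#' @return A `filter_result`: list with `name`, `n_in`, `n_out`, `n_dropped`
#'   and the filtered `table`.
#' @export
filter_period <- function(table, start_year, end_year) {
  tab <- as_patient_table(table)
  if (start_year > end_year) stop_config("`start_year` must be <= `end_year`")
  keep <- !is.na(tab$year) & tab$year >= start_year & tab$year <= end_year
  filter_result(sprintf("period %d-%d", start_year, end_year),
                tab, tab[keep, , drop = FALSE])
}

#' @rdname filter_period
#' @export
filter_min_group_per_center <- function(table, group_var = "indigenous",
                                        group_level = "indigenous",
                                        min_count = 20) {
  tab <- as_patient_table(table)
  if (!group_var %in% names(tab)) {
    stop_data("unknown column `", group_var, "`")
  }
  if (min_count < 0) stop_config("`min_count` must be >= 0")
  counts <- table(factor(tab$centre_id)[!is.na(tab[[group_var]]) &
                                          tab[[group_var]] == group_level])
  n_grp <- as.vector(counts)[match(tab$centre_id, names(counts))]
  n_grp[is.na(n_grp)] <- 0L
  filter_result(sprintf("min %d '%s' %s per center", min_count, group_level,
                        group_var),
                tab, tab[n_grp >= min_count, , drop = FALSE])
}

#' @rdname filter_period
#' @export
filter_drop_missing <- function(table, fields) {
  tab <- as_patient_table(table)
  if (!length(fields)) stop_config("`fields` must be non-empty")
  bad <- setdiff(fields, names(tab))
  if (length(bad)) stop_data("unknown column(s): ", paste(bad, collapse = ", "))
  any_missing <- Reduce(`|`, lapply(fields, function(f) is.na(tab[[f]])))
  filter_result(sprintf("complete cases on %s", paste(fields, collapse = "+")),
                tab, tab[!any_missing, , drop = FALSE])
}

#' @rdname filter_period
#' @export
filter_status_censored <- function(table, censored_code = 2L) {
  tab <- as_patient_table(table)
  keep <- is.na(tab$status) | tab$status != censored_code
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(tab) > 0L) {
    warning("all rows had censored status; the filtered table is empty")
  }
  filter_result(sprintf("drop censored status (code %d)", censored_code),
                tab, out)
}

#' Attrition report for a chain of cohort filters
#'
#' One row per filter with its in/out/dropped counts. The filters must have
#' been applied in sequence: each `n_in` must equal the previous `n_out`.
#'
#' @param results List of `filter_result`s in application order.
#' @return Data frame with columns `step`, `filter`, `n_in`, `n_out`,
#'   `n_dropped`.
#' @export
attrition_report <- function(results) {
  if (!length(results)) {
    return(data.frame(step = integer(), filter = character(),
                      n_in = integer(), n_out = integer(),
                      n_dropped = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(vapply(results, inherits, logical(1), "filter_result")))
  n_in <- vapply(results, `[[`, numeric(1), "n_in")
  n_out <- vapply(results, `[[`, numeric(1), "n_out")
  if (length(results) > 1L && any(n_in[-1] != n_out[-length(n_out)])) {
    stop_data("inconsistent filter chain: a filter's n_in does not match ",
              "the previous filter's n_out")
  }
  data.frame(step = seq_along(results),
             filter = vapply(results, `[[`, character(1), "name"),
             n_in = as.integer(n_in), n_out = as.integer(n_out),
             n_dropped = as.integer(n_in - n_out),
             stringsAsFactors = FALSE)
}
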