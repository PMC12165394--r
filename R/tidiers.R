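#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TUG event set
#'
#' @param x A `tug_events` object.
#' @param ... Unused.
#' @return Tibble of events and times.
#' @export
tidy.tug_events <- function(x, ...) x$times

#' Tidy an OLS fit: one row per model term
#'
#' @param x An `ols_result`.
#' @param ... Unused.
#' @return Tibble with `term`, `B`, `SE`, `t`, `p` and CI bounds.
#' @export
tidy.ols_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ols_result")
  out
}

#' One-row model summary of an OLS fit
#'
#' @param x An `ols_result`.
#' @param ... Unused.
#' @return Tibble with `dependent`, `r_squared`, `adj_r_squared`, `n`.
#' @export
glance.ols_result <- function(x, ...) {
  tibble::tibble(
    dependent = attr(x, "dependent"),
    r_squared = attr(x, "r_squared"),
    adj_r_squared = attr(x, "adj_r_squared"),
    n = attr(x, "n")
  )
}

#' Tidy a statistical report into one long table
#'
#' @param x A `stat_report`.
#' @param table Which component to return.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.stat_report <- function(x, table = c("correlations", "normality", "ols",
                                          "manova", "vif"), ...) {
  table <- match.arg(table)
  x[[table]]
}

#' One-row summary of a statistical report
#'
#' @param x A `stat_report`.
#' @param ... Unused.
#' @return Tibble with cohort size and battery counts.
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_variables = nrow(x$normality),
    n_non_normal = sum(!x$normality$normal, na.rm = TRUE),
    n_correlations = nrow(x$correlations),
    n_significant = sum(x$correlations$significant, na.rm = TRUE),
    max_vif = max(x$vif$vif),
    alpha = x$config$alpha
  )
}
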