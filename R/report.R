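# Machine-readable JSON reports for analysis results.

#' Convert an analysis result to a plain report list
#'
#' Methods exist for `fit_result`, `unwrap_scan`, `phase_assignment`,
#' `titration_result`, `guinier_result` and `pair_distance_distribution`.
#' All real-space spacings use the `d = 2*pi/q` convention.
#'
#' @param x Result object.
#' @param ... Unused.
#' @return A named list suitable for [write_report_json()].
#' @export
report <- function(x, ...) UseMethod("report")

#' @export
report.fit_result <- function(x, ...) {
  list(model_id = x$model_id %||% NA, c = x$scale, b = x$background,
       chi2_reduced = x$chi2_reduced, window = x$q_window)
}

#' @export
report.unwrap_scan <- function(x, ...) {
  list(convention = "d = 2*pi/q",
       ranking = lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])))
}

#' @export
report.phase_assignment <- function(x, ...) {
  list(convention = "d = 2*pi/q",
       phase = x$phase, h = x$h, a_H = x$a_H, d_L = x$d_L,
       assignments = x$assignments,
       peaks = as.list(as.data.frame(x$peaks)))
}

#' @export
report.titration_result <- function(x, ...) {
  list(ec50_precipitation_mM = x$ec50_precipitation,
       ec50_resolubilisation_mM = x$ec50_resolubilisation,
       full_aggregation_window_mM = x$full_aggregation_window,
       split_at_mM = x$split_at)
}

#' @export
report.guinier_result <- function(x, ...) {
  list(rg = x$rg, i0 = x$i0, q_window = x$q_window,
       r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
report.pair_distance_distribution <- function(x, ...) {
  list(rg = x$rg, dmax = x$dmax,
       chi2_reduced = x$chi2_reduced %||% NA,
       alpha = x$alpha %||% NA)
}

#' Write a report list as JSON
#'
#' @param x A result object (passed through [report()]) or a plain list.
#' @param path Output path.
#' @param seed Optional seed recorded in the report.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, seed = NULL) {
  if (!is.list(x) || !is.null(attr(x, "class"))) x <- report(x)
  if (!is.null(seed)) x$seed <- seed
  x$generator <- paste0("chromosaxs ",
                        as.character(utils::packageVersion("chromosaxs")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
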