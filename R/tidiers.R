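#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted arrival model
#'
#' @param x a [fit_par()] object.
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.par_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = sqrt(pmax(diag(x$vcov), 0)))
}

#' @rdname tidy.par_fit
#' @export
glance.par_fit <- function(x, ...) {
  tibble::tibble(order = x$order, n_harmonics = x$harmonic$n_harmonics,
                 logLik = x$loglik, BIC = x$bic, nobs = x$n_eff)
}

#' Tidy fitted departure models
#'
#' @param x a [fit_departures()] object.
#' @param ... unused.
#' @return one row per (horizon, stratum, term) with estimates and standard
#'   errors; `glance()` gives one row per (horizon, stratum) block with sample
#'   size, event count and the fallback flag.
#' @export
tidy.departure_models <- function(x, ...) {
  purrr::map_dfr(x$blocks, function(b) {
    tibble::tibble(horizon = b$k, stratum = b$stratum, term = names(b$coef),
                   estimate = unname(b$coef),
                   std.error = sqrt(pmax(diag(b$vcov), 0)))
  })
}

#' @rdname tidy.departure_models
#' @export
glance.departure_models <- function(x, ...) {
  purrr::map_dfr(x$blocks, function(b) {
    tibble::tibble(horizon = b$k, stratum = b$stratum, n = b$n,
                   events = b$events, fallback = b$fallback)
  })
}

#' Tidy a census forecast
#'
#' @param x a [forecast_census()] result.
#' @param ... unused.
#' @return the per-horizon summary table (`origin`, `horizon`, `point`, `lo`,
#'   `hi`).
#' @export
tidy.census_forecast <- function(x, ...) x$summary

#' @rdname tidy.census_forecast
#' @export
glance.census_forecast <- function(x, ...) {
  tibble::tibble(origin = x$origin, census = x$census,
                 m = nrow(x$realizations), seed = x$seed)
}

#' Tidy a backtest report
#'
#' @param x a [run_backtest()] report.
#' @param ... unused.
#' @return `tidy()`: the per-day forecast table (with the comparator's rows
#'   bound on, distinguished by a `model` column, when present); `glance()`:
#'   the per-horizon metric summary.
#' @export
tidy.backtest_report <- function(x, ...) {
  out <- dplyr::mutate(x$daily, model = "ensemble")
  if (!is.null(x$comparator_daily)) {
    out <- dplyr::bind_rows(
      out, dplyr::mutate(x$comparator_daily, model = "census_only"))
  }
  out
}

#' @rdname tidy.backtest_report
#' @export
glance.backtest_report <- function(x, ...) {
  out <- dplyr::mutate(x$metrics, model = "ensemble")
  if (!is.null(x$comparator_metrics)) {
    out <- dplyr::bind_rows(
      out, dplyr::mutate(x$comparator_metrics, model = "census_only"))
  }
  out
}
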