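#' Backtest configuration
#'
#' @param split_day first forecast origin: training data are the days up to
#'   and including each origin, so the initial training window is
#'   `1 ... split_day`.
#' @param n_test number of consecutive forecast origins (test days).
#' @param horizons forecast horizons in days.
#' @param cadence days between model refits (1 = refit at every origin; larger
#'   cadences reuse the last fit but always update the census state, the
#'   arrival history, and the pseudo-subject pool).
#' @param ensemble an [ensemble_config()] (its `horizons` are overridden by
#'   `horizons`).
#' @param order autoregressive order for the arrival model, or `NULL` to
#'   select it by BIC (up to `p_max`) at the first refit.
#' @param p_max largest candidate order when `order` is `NULL`.
#' @param n_harmonics number of seasonal harmonics (0 disables seasonality).
#' @param freq_candidates candidate frequencies (cycles per training series)
#'   scanned at the first refit; the implied period is then frozen across
#'   refits.
#' @param spec a [stratum_spec()].
#' @param comparator also run the census-only benchmark: a seasonality
#'   adjusted Poisson autoregression fitted directly to the census-count
#'   series, ignoring patient-level information.
#' @param penalty ridge penalty for the departure models.
#' @return an object of class `backtest_config`.
#' @export
backtest_config <- function(split_day, n_test, horizons = c(1, 3, 5, 7),
                            cadence = 1, ensemble = ensemble_config(),
                            order = NULL, p_max = 7, n_harmonics = 1,
                            freq_candidates = 1:6, spec = stratum_spec(),
                            comparator = FALSE, penalty = 1e-4) {
  stopifnot(cadence >= 1, n_test >= 1, split_day >= 2)
  structure(
    list(split_day = as.integer(split_day), n_test = as.integer(n_test),
         horizons = sort(unique(as.integer(horizons))),
         cadence = as.integer(cadence), ensemble = ensemble, order = order,
         p_max = p_max, n_harmonics = n_harmonics,
         freq_candidates = freq_candidates, spec = spec,
         comparator = comparator, penalty = penalty),
    class = "backtest_config"
  )
}

#' Mean absolute prediction error
#'
#' Mean absolute difference between observed and forecast census counts (in
#' patients), with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 SE of the absolute errors).
#'
#' @param observed,forecast equal-length numeric vectors.
#' @return tibble with `mape`, `lo`, `hi`, `n`.
#' @export
mape <- function(observed, forecast) {
  if (length(observed) != length(forecast) || length(observed) == 0) {
    stop("observed and forecast must be non-empty and of equal length",
         call. = FALSE)
  }
  ae <- abs(observed - forecast)
  se <- if (length(ae) > 1) stats::sd(ae) / sqrt(length(ae)) else 0
  tibble::tibble(mape = mean(ae), lo = mean(ae) - 1.96 * se,
                 hi = mean(ae) + 1.96 * se, n = length(ae))
}

#' Prediction-interval coverage and widths
#'
#' @param daily a per-day forecast table with columns `observed`, `lo`, `hi`.
#' @return list with `coverage` (fraction of days with `lo <= observed <= hi`)
#'   and `widths` (vector of `hi - lo`).
#' @export
interval_metrics <- function(daily) {
  if (nrow(daily) == 0) stop("empty forecast table", call. = FALSE)
  stopifnot(all(daily$lo <= daily$hi))
  list(coverage = mean(daily$lo <= daily$observed & daily$observed <= daily$hi),
       widths = daily$hi - daily$lo)
}

summarize_daily <- function(daily) {
  daily |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(
      mape = mean(abs(.data$observed - .data$point)),
      mape_lo = mape - 1.96 * stats::sd(abs(.data$observed - .data$point)) /
        sqrt(dplyr::n()),
      mape_hi = mape + 1.96 * stats::sd(abs(.data$observed - .data$point)) /
        sqrt(dplyr::n()),
      coverage = mean(.data$lo <= .data$observed & .data$observed <= .data$hi),
      mean_width = mean(.data$hi - .data$lo),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Continuously-updating census backtest
#'
#' Expanding-window prospective evaluation: for each test day `t`, every model
#' is (re)fitted on the information determinable by `t` (arrival counts for
#' days `<= t`; patient records censored at `t`, so the training window
#' absorbs each elapsed test day), the ensemble forecast is issued from origin
#' `t` for every horizon, and scored against the observed census at `t + k`.
#' Origins whose target day falls beyond the data range are skipped for that
#' horizon.
#'
#' @inheritParams patient-records
#' @param arrivals daily arrival series (tibble `day`, `arrivals` or numeric
#'   vector), gap-free from day 1 and covering `split_day + n_test - 1`.
#' @param config a [backtest_config()].
#' @return an object of class `backtest_report`: `daily` per-day table
#'   (`origin`, `horizon`, `day`, `observed`, `point`, `lo`, `hi`), `metrics`
#'   per-horizon summary (MAPE with CI, coverage, mean interval width),
#'   `comparator_daily`/`comparator_metrics` when the benchmark is enabled,
#'   and the fitted specification frozen at the first refit.
#' @export
run_backtest <- function(patients, arrivals, config) {
  a <- as_count_vector(arrivals)
  patients <- validate_patients(patients)
  origins <- config$split_day + seq_len(config$n_test) - 1L
  if (config$split_day > length(a)) {
    stop("split_day beyond the arrival series", call. = FALSE)
  }
  obs_census <- census_series(patients,
                              seq_len(max(length(a),
                                          max(last_present_day(patients)))))
  last_obs_day <- length(a)  # score only within the observed calendar
  kmax <- max(config$horizons)
  seed <- master_seed(config$ensemble$seed)

  par_fit <- NULL; dep_models <- NULL; hspec <- NULL; p_order <- config$order
  cmp_fit <- NULL; cmp_hspec <- NULL; cmp_order <- NULL
  rows <- list(); cmp_rows <- list()

  for (i in seq_along(origins)) {
    t0 <- origins[i]
    train_a <- a[seq_len(t0)]
    refit <- is.null(par_fit) || ((i - 1L) %% config$cadence == 0L)
    if (refit) {
      if (is.null(hspec)) {
        hspec <- if (config$n_harmonics > 0) {
          om <- estimate_frequency(train_a, config$freq_candidates)$omega_hat
          harmonic_spec(rep(om, config$n_harmonics) *
                          seq_len(config$n_harmonics), length(train_a))
        } else harmonic_spec(numeric(), length(train_a))
      }
      if (is.null(p_order)) {
        p_order <- select_par_order(train_a, p_max = config$p_max,
                                    harmonic = hspec)$order
      }
      par_fit <- fit_par(train_a, order = p_order, harmonic = hspec)
      dep_models <- fit_departures(patients, horizons = seq_len(kmax),
                                   spec = config$spec, cutoff_day = t0,
                                   penalty = config$penalty)
      if (config$comparator) {
        cens_train <- obs_census$census[seq_len(t0)]
        if (is.null(cmp_hspec)) {
          cmp_hspec <- if (config$n_harmonics > 0) {
            om <- estimate_frequency(cens_train, config$freq_candidates)$omega_hat
            harmonic_spec(rep(om, config$n_harmonics) *
                            seq_len(config$n_harmonics), length(cens_train))
          } else harmonic_spec(numeric(), length(cens_train))
          cmp_order <- if (is.null(config$order)) {
            select_par_order(cens_train, p_max = config$p_max,
                             harmonic = cmp_hspec)$order
          } else config$order
        }
        cmp_fit <- fit_par(cens_train, order = cmp_order, harmonic = cmp_hspec)
      }
    }
    train_pat <- censor_at(patients, t0)
    state <- census_state(train_pat, t0)
    ecfg <- config$ensemble
    ecfg$horizons <- config$horizons
    ecfg$seed <- substream_seed(seed, i)
    fc <- forecast_census(state, par_fit, dep_models, train_pat, ecfg,
                          arrival_history = train_a)
    keep <- t0 + config$horizons <= last_obs_day
    if (any(keep)) {
      sm <- fc$summary[keep, , drop = FALSE]
      sm$day <- sm$origin + sm$horizon
      sm$observed <- obs_census$census[sm$day]
      rows[[length(rows) + 1]] <- sm
    }
    if (config$comparator) {
      cmp <- census_only_forecast(
        cmp_fit, obs_census$census[seq_len(t0)], config$horizons,
        n_realizations = config$ensemble$n_realizations,
        quantiles = config$ensemble$quantiles, point = config$ensemble$point,
        seed = substream_seed(seed + 7L, i))
      cmp$origin <- t0
      cmp$day <- t0 + cmp$horizon
      cmp <- cmp[cmp$day <= last_obs_day, , drop = FALSE]
      if (nrow(cmp) > 0) {
        cmp$observed <- obs_census$census[cmp$day]
        cmp_rows[[length(cmp_rows) + 1]] <- cmp
      }
    }
  }
  if (length(rows) == 0) stop("no scorable forecasts in the test window",
                              call. = FALSE)
  daily <- dplyr::bind_rows(rows) |>
    dplyr::select("origin", "horizon", "day", "observed", "point", "lo", "hi")
  out <- list(daily = daily, metrics = summarize_daily(daily),
              config = config, seed = seed,
              harmonic = hspec, order = p_order)
  if (config$comparator) {
    cdaily <- dplyr::bind_rows(cmp_rows) |>
      dplyr::select("origin", "horizon", "day", "observed", "point", "lo", "hi")
    out$comparator_daily <- cdaily
    out$comparator_metrics <- summarize_daily(cdaily)
    out$comparator_order <- cmp_order
    out$comparator_harmonic <- cmp_hspec
  }
  structure(out, class = "backtest_report")
}

#' @export
print.backtest_report <- function(x, ...) {
  cat("<backtest_report>", nrow(x$daily), "scored forecasts, PAR order",
      x$order, "\n")
  print(x$metrics)
  if (!is.null(x$comparator_metrics)) {
    cat("census-only comparator:\n")
    print(x$comparator_metrics)
  }
  invisible(x)
}

#' Census-only benchmark forecast
#'
#' The benchmark that ignores patient-level information: a seasonality
#' adjusted Poisson autoregression fitted directly to the daily census-count
#' series. Forecasts are an ensemble over parameter draws
#' \eqn{\lambda^{(r)} \sim MVN(\hat\lambda, V_\lambda)}, each simulating the
#' census path sequentially `k` days ahead; point and interval are the same
#' summaries as the primary model's.
#'
#' @param fit a [fit_par()] object fitted to the census series.
#' @param census_history census counts through the forecast origin.
#' @param horizons horizons to forecast.
#' @param n_realizations ensemble size.
#' @param quantiles,point interval percentiles and point summary.
#' @param seed master seed (substreams per realization).
#' @return tibble with `horizon`, `point`, `lo`, `hi`.
#' @export
census_only_forecast <- function(fit, census_history, horizons,
                                 n_realizations = 1000,
                                 quantiles = c(0.025, 0.975),
                                 point = "median", seed = NULL) {
  seed <- master_seed(seed)
  kmax <- max(horizons)
  real <- matrix(NA_real_, n_realizations, length(horizons))
  for (r in seq_len(n_realizations)) {
    set.seed(substream_seed(seed, r))
    lambda_r <- mvn_draw(fit$coef, fit$factor)
    path <- simulate_arrivals(fit, census_history, kmax, coef = lambda_r)
    real[r, ] <- path[horizons]
  }
  purrr::map_dfr(seq_along(horizons), function(h) {
    sm <- summarize_ensemble(real[, h], point, quantiles)
    tibble::tibble(horizon = horizons[h], point = sm[["point"]],
                   lo = sm[["lo"]], hi = sm[["hi"]])
  })
}
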