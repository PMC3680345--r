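test_that("ensemble summaries match an independent order-statistics oracle", {
  expect_equal(summarize_ensemble(rep(7, 50)), c(point = 7, lo = 7, hi = 7))
  expect_equal(summarize_ensemble(c(1, 2, 3, 4))[["point"]], 2.5)
  x <- 1:100
  sm <- summarize_ensemble(x, quantiles = c(0.025, 0.975))
  # independent sort-based evaluation of the type-7 convention:
  # q(p) = x_(1 + p (n - 1)) with linear interpolation
  oracle <- function(p) {
    h <- 1 + p * (length(x) - 1)
    xs <- sort(x)
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(sm[["lo"]], oracle(0.025))
  expect_equal(sm[["hi"]], oracle(0.975))
  expect_error(summarize_ensemble(numeric()), "empty")
})

test_that("forecasts are bit-identical under a fixed seed and extend stably in M", {
  fits <- shared_fits()
  cfg <- ensemble_config(n_realizations = 40, horizons = c(1, 3), seed = 17)
  f1 <- forecast_census(fits$state, fits$par_fit, fits$dep, fits$train_pat, cfg)
  f2 <- forecast_census(fits$state, fits$par_fit, fits$dep, fits$train_pat, cfg)
  expect_identical(f1$realizations, f2$realizations)
  # growing M preserves the first 40 realizations (per-realization substreams)
  cfg80 <- ensemble_config(n_realizations = 80, horizons = c(1, 3), seed = 17)
  f3 <- forecast_census(fits$state, fits$par_fit, fits$dep, fits$train_pat, cfg80)
  expect_identical(f3$realizations[1:40, ], f1$realizations)
})

test_that("degenerate inputs give a zero-width forecast at the current census", {
  # empty census, arrival model frozen at mu ~ 0, no parameter uncertainty
  gap <- make_patients(admit_days = c(1, 10), los = c(1, 2))
  st0 <- census_state(gap, 5)
  expect_equal(st0$census_count, 0)
  pf <- fit_par(rpois(60, 2), order = 0)
  pf$coef[1] <- -100
  pf$vcov <- matrix(0, 1, 1); pf$factor <- matrix(0, 1, 1)
  dep <- fit_departures(shared_history()$patients, horizons = 1:3,
                        cutoff_day = 300)
  fc <- forecast_census(st0, pf, dep, censor_at(shared_history()$patients, 300),
                        ensemble_config(50, horizons = c(1, 3), seed = 2))
  expect_true(all(fc$realizations == 0))
  expect_true(all(fc$summary$hi - fc$summary$lo == 0))
})

test_that("with all uncertainty frozen the k=1 ensemble mean matches the closed form", {
  fits <- shared_fits()
  st <- fits$state
  # arrival model: fixed mu, no parameter uncertainty
  pf <- fits$par_fit
  pf$order <- 0L
  pf$harmonic <- harmonic_spec(numeric(), 320)
  pf$coef <- c(intercept = log(2.5))
  pf$vcov <- matrix(0, 1, 1); pf$factor <- matrix(0, 1, 1)
  # departure models: deterministic 0/1 probabilities, no uncertainty
  dep <- fits$dep
  set.seed(123)
  sure <- rbinom(length(stratum_levels(dep$spec)), 1, 0.4)
  names(sure) <- stratum_levels(dep$spec)
  for (key in names(dep$blocks)) {
    b <- dep$blocks[[key]]
    dep$blocks[[key]]$coef <- c(if (sure[as.character(b$stratum)] == 1) 60 else -60,
                                rep(0, length(b$coef) - 1))
    z <- matrix(0, length(b$coef), length(b$coef))
    dep$blocks[[key]]$vcov <- z
    dep$blocks[[key]]$factor <- z
  }
  n_sure <- sum(vapply(split(st$present, stratum_of(st$present$s, dep$spec)),
                       nrow, integer(1)) *
                  sure[as.character(sort(unique(stratum_of(st$present$s, dep$spec))))])
  cfg <- ensemble_config(4000, horizons = 1, seed = 31)
  fc <- forecast_census(st, pf, dep, fits$train_pat, cfg)
  expected <- st$census_count + 2.5 - n_sure
  mc_se <- sqrt(2.5 / 4000)  # only Poisson arrival noise remains
  expect_lt(abs(mean(fc$realizations[, 1]) - expected), 4 * mc_se)
})

test_that("realizations obey the hard census bounds", {
  fits <- shared_fits()
  cfg <- ensemble_config(150, horizons = c(1, 3, 5, 7), seed = 11)
  fc <- forecast_census(fits$state, fits$par_fit, fits$dep, fits$train_pat, cfg)
  expect_true(all(fc$realizations >= 0))
  # cannot lose more than everyone present
  expect_true(all(fc$realizations >= fits$state$census_count -
                    nrow(fits$state$present)))
  expect_true(all(fc$realizations == round(fc$realizations)))
  # departures never exceed those ever present: C(t) + arrivals is a ceiling,
  # and pseudo departures <= interim pseudo arrivals keeps the floor at the
  # day-k arrivals
  for (h in seq_along(cfg$horizons)) {
    k <- cfg$horizons[h]
    arr_sum <- rowSums(fc$arrivals[, seq_len(k), drop = FALSE])
    expect_true(all(fc$realizations[, h] <= fits$state$census_count + arr_sum))
    expect_true(all(fc$realizations[, h] >=
                      fc$arrivals[, k] - 0 + (fits$state$census_count -
                                                nrow(fits$state$present))))
  }
})

test_that("interval width grows with horizon on average across origins", {
  h <- shared_history()
  widths <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    t0 <- 280 + 10 * i
    train <- censor_at(h$patients, t0)
    pf <- fit_par(h$arrivals$arrivals[1:t0], order = 1)
    dep <- fit_departures(h$patients, horizons = 1:7, cutoff_day = t0)
    fc <- forecast_census(census_state(train, t0), pf, dep, train,
                          ensemble_config(120, horizons = c(1, 7), seed = i))
    widths[i, ] <- fc$summary$hi - fc$summary$lo
  }
  expect_gt(mean(widths[, 2]), mean(widths[, 1]))
})
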