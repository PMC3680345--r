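#' Harmonic seasonality specification
#'
#' Specifies `K` harmonic (cosine/sine pair) seasonality terms for the
#' log-linear arrival mean. Frequencies are indexed in cycles per
#' `series_length` days, so frequency `w` corresponds to a period of
#' `series_length / w` days; the spec is kept fixed when predicting beyond the
#' series, which preserves the period.
#'
#' @param frequencies positive frequencies (cycles per `series_length`); may be
#'   non-integer. Use `numeric(0)` for no seasonality.
#' @param series_length the series length `T` the frequencies are indexed
#'   against.
#' @return an object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(frequencies = numeric(), series_length = 1) {
  frequencies <- as.numeric(frequencies)
  stopifnot(all(frequencies > 0), series_length >= 1)
  structure(
    list(n_harmonics = length(frequencies),
         frequencies = frequencies,
         series_length = as.numeric(series_length)),
    class = "harmonic_spec"
  )
}

# Harmonic design columns cos(2*pi*t*w/T), sin(2*pi*t*w/T) for days t.
harmonic_design <- function(harmonic, t) {
  if (harmonic$n_harmonics == 0) {
    return(matrix(numeric(0), nrow = length(t), ncol = 0))
  }
  cols <- lapply(harmonic$frequencies, function(w) {
    ang <- 2 * pi * t * w / harmonic$series_length
    cbind(cos(ang), sin(ang))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- as.vector(vapply(seq_along(harmonic$frequencies), function(k) {
    c(paste0("cos", k), paste0("sin", k))
  }, character(2)))
  X
}

par_param_names <- function(p, K) {
  c("intercept",
    if (p > 0) paste0("ar", seq_len(p)),
    if (K > 0) as.vector(rbind(paste0("cos", seq_len(K)), paste0("sin", seq_len(K)))))
}

# Full conditional-mean design matrix for days t (lag columns taken from the
# count vector `a` indexed by calendar day).
par_design <- function(a, p, harmonic, t) {
  X <- cbind(intercept = rep(1, length(t)))
  if (p > 0) {
    lags <- vapply(seq_len(p), function(i) a[t - i], numeric(length(t)))
    lags <- matrix(lags, nrow = length(t))
    colnames(lags) <- paste0("ar", seq_len(p))
    X <- cbind(X, lags)
  }
  cbind(X, harmonic_design(harmonic, t))
}

#' Conditional mean of the seasonality-adjusted PAR model
#'
#' Evaluates
#' \deqn{\log \mu_t = \beta_0 + \sum_{k=1}^{K}[\phi_k \cos(2\pi t \omega_k/T)
#'  + \alpha_k \sin(2\pi t \omega_k/T)] + \sum_{i=1}^{p} \beta_i A(t-i).}
#' The linear predictor is clipped to `[-30, 30]` before exponentiation.
#'
#' @param params named list or `par_fit` with elements `coef` (stacked
#'   parameter vector: intercept, `p` AR coefficients, then cos/sin pairs) and
#'   `harmonic` (a [harmonic_spec()]), plus `order`.
#' @param lagged_counts the `p` most recent counts, most recent first
#'   (`A(t-1), ..., A(t-p)`).
#' @param t the day index at which to evaluate the mean.
#' @return the positive conditional mean \eqn{\mu_t}.
#' @export
par_mean <- function(params, lagged_counts = numeric(), t) {
  p <- params$order
  if (length(lagged_counts) != p) {
    stop("need exactly p = ", p, " lagged counts, got ", length(lagged_counts),
         call. = FALSE)
  }
  K <- params$harmonic$n_harmonics
  x <- c(1, lagged_counts,
         if (K > 0) as.vector(t(harmonic_design(params$harmonic, t))))
  eta <- clip_lp(sum(x * params$coef))
  exp(eta)
}

# Poisson log-linear fit by iteratively reweighted least squares (Newton on
# the conditional log-likelihood). Returns coef, vcov (inverse observed
# Fisher information), loglik, fitted mu.
poisson_irls <- function(X, y, max_iter = 60, tol = 1e-11) {
  beta <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1))
  loglik <- function(b) {
    mu <- exp(clip_lp(drop(X %*% b)))
    sum(stats::dpois(y, mu, log = TRUE))
  }
  ll <- loglik(beta)
  for (iter in seq_len(max_iter)) {
    eta <- clip_lp(drop(X %*% beta))
    mu <- exp(eta)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * mu, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("PAR fit failed: singular information matrix (iteration ", iter, ")",
           call. = FALSE)
    })
    # step-halving keeps the likelihood ascent monotone
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) {
        stop("PAR fit failed to converge: step-halving exhausted at iteration ",
             iter, call. = FALSE)
      }
    }
    beta <- cand
    converged <- max(abs(lambda * step)) < tol || abs(ll_new - ll) < 1e-12
    ll <- ll_new
    if (converged) {
      mu <- exp(clip_lp(drop(X %*% beta)))
      info <- crossprod(X * mu, X)
      return(list(coef = beta, vcov = ensure_psd(solve(info)),
                  loglik = ll, fitted = mu))
    }
  }
  stop("PAR fit did not converge in ", max_iter, " iterations", call. = FALSE)
}

#' Fit a seasonality-adjusted Poisson autoregressive model
#'
#' Conditional maximum likelihood: the first days of the series act as fixed
#' initial conditions and the Poisson log-likelihood of `A(t)` given its `p`
#' lags and the harmonic terms is maximized by Newton iteration. The parameter
#' covariance is the inverse observed Fisher information at the optimum.
#'
#' @param arrivals daily arrival counts: a numeric vector `A(1..T)` or a data
#'   frame with an `arrivals` (or `count`) column, gap-free and daily.
#' @param order autoregressive order `p >= 0`.
#' @param harmonic a [harmonic_spec()]; defaults to no seasonality. Pass
#'   `series_length = length(arrivals)` specs for cycles-per-series indexing.
#' @param cond_start first day entering the likelihood (default `p + 1`).
#'   [select_par_order()] uses a common `p_max + 1` so candidate likelihoods
#'   are comparable.
#' @return an object of class `par_fit`: stacked coefficient vector `coef`
#'   (named intercept, ar1..arp, cos/sin pairs), covariance `vcov`, `loglik`,
#'   `bic`, `order`, `harmonic`, `n_eff`, and the training series.
#' @export
fit_par <- function(arrivals, order = 0, harmonic = NULL, cond_start = NULL) {
  a <- as_count_vector(arrivals)
  T_len <- length(a)
  if (is.null(harmonic)) harmonic <- harmonic_spec(numeric(), T_len)
  p <- as.integer(order)
  K <- harmonic$n_harmonics
  npar <- 1 + p + 2 * K
  if (is.null(cond_start)) cond_start <- p + 1
  if (cond_start < p + 1) stop("cond_start must be > order", call. = FALSE)
  tt <- seq(cond_start, T_len)
  if (length(tt) <= npar) {
    stop("series too short (", T_len, ") for ", npar, " parameters", call. = FALSE)
  }
  X <- par_design(a, p, harmonic, tt)
  y <- a[tt]
  fit <- poisson_irls(X, y)
  names(fit$coef) <- par_param_names(p, K)
  dimnames(fit$vcov) <- list(names(fit$coef), names(fit$coef))
  n_eff <- length(tt)
  structure(
    list(coef = fit$coef, vcov = fit$vcov, factor = psd_factor(fit$vcov),
         loglik = fit$loglik, bic = -2 * fit$loglik + npar * log(n_eff),
         order = p, harmonic = harmonic, n_eff = n_eff,
         cond_start = cond_start, series = a),
    class = "par_fit"
  )
}

#' @export
print.par_fit <- function(x, ...) {
  cat("<par_fit> PAR(", x$order, ") with ", x$harmonic$n_harmonics,
      " harmonic(s); logLik ", round(x$loglik, 2), ", BIC ", round(x$bic, 2),
      "\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Select the autoregressive order by BIC
#'
#' Fits `PAR(p)` for `p = 0..p_max` on a common conditioning window (all
#' candidates condition on the first `p_max` days, so their likelihoods are
#' comparable) and returns the order minimizing BIC; ties break toward the
#' smaller order. Orders whose fit fails are skipped with a warning.
#'
#' @inheritParams fit_par
#' @param p_max largest candidate order.
#' @return list with `order` (the selected `p`), `table` (tibble of `p`,
#'   `loglik`, `bic`) and `fits` (the fitted candidates).
#' @export
select_par_order <- function(arrivals, p_max = 7, harmonic = NULL) {
  stopifnot(p_max >= 0)
  a <- as_count_vector(arrivals)
  fits <- vector("list", p_max + 1)
  for (p in 0:p_max) {
    fits[[p + 1]] <- tryCatch(
      fit_par(a, order = p, harmonic = harmonic, cond_start = p_max + 1),
      error = function(e) {
        warning("order ", p, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate order could be fitted", call. = FALSE)
  tab <- tibble::tibble(
    p = (0:p_max)[ok],
    loglik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    bic = vapply(fits[ok], function(f) f$bic, numeric(1))
  )
  best <- tab$p[which.min(tab$bic)]
  list(order = best, table = tab, fits = stats::setNames(fits[ok], tab$p))
}

#' Estimate the seasonal frequency from the periodogram
#'
#' Returns the candidate frequency (in cycles per series length) whose
#' periodogram ordinate of the mean-centered series is largest — an automated
#' proxy for visual inspection of the cyclical pattern in the sample
#' autocorrelation function, which is also returned for plotting.
#'
#' @inheritParams fit_par
#' @param candidates integer candidate frequencies (cycles per series), each
#'   `>= 1`.
#' @return an object of class `frequency_scan`: `omega_hat`, `periodogram`
#'   (tibble of `frequency`, `ordinate`), and `acf` (from [stats::acf()]).
#' @export
estimate_frequency <- function(arrivals, candidates = 1:8) {
  a <- as_count_vector(arrivals)
  stopifnot(length(candidates) >= 1, all(candidates >= 1))
  if (stats::var(a) == 0) {
    stop("constant series: frequency is unidentifiable", call. = FALSE)
  }
  T_len <- length(a)
  x <- a - mean(a)
  ords <- vapply(candidates, function(w) {
    Mod(sum(x * exp(-2i * pi * w * seq_len(T_len) / T_len)))^2 / T_len
  }, numeric(1))
  structure(
    list(omega_hat = candidates[which.max(ords)],
         periodogram = tibble::tibble(frequency = candidates, ordinate = ords),
         acf = stats::acf(a, lag.max = min(T_len - 1, 3 * T_len %/% 4),
                          plot = FALSE)),
    class = "frequency_scan"
  )
}

#' @export
print.frequency_scan <- function(x, ...) {
  cat("<frequency_scan> omega_hat =", x$omega_hat, "cycles per series\n")
  invisible(x)
}

#' Sample arrival-model parameters from their asymptotic distribution
#'
#' Draws from \eqn{MVN(\hat\lambda, V_\lambda)} where \eqn{V_\lambda} is the
#' inverse Fisher information of the fit; used by the forecasting ensemble to
#' propagate arrival-parameter uncertainty.
#'
#' @param fit a [fit_par()] object.
#' @param n number of draws.
#' @return an `n` x `npar` matrix of parameter draws (uses the current RNG).
#' @export
sample_par_params <- function(fit, n = 1) {
  d <- length(fit$coef)
  draws <- matrix(vapply(seq_len(n), function(i) mvn_draw(fit$coef, fit$factor),
                         numeric(d)),
                  nrow = n, ncol = d, byrow = TRUE,
                  dimnames = list(NULL, names(fit$coef)))
  draws
}

#' Simulate future arrivals from a (possibly perturbed) PAR model
#'
#' Sequential sampling: the conditional mean for day `t + j` uses observed
#' counts for days `<= t` and previously sampled counts for days in
#' `(t, t+j)`; each arrival count is a Poisson draw with that mean.
#'
#' @param fit a [fit_par()] object supplying the order and harmonic spec.
#' @param history observed counts through the forecast origin (day indices
#'   `1..t`); must have length `>= order`.
#' @param horizon number of days ahead to simulate.
#' @param coef optional parameter vector (e.g. a row of
#'   [sample_par_params()]); defaults to the fitted coefficients.
#' @return integer vector of simulated arrivals `A(t+1) ... A(t+horizon)`.
#' @export
simulate_arrivals <- function(fit, history, horizon, coef = NULL) {
  if (is.null(coef)) coef <- fit$coef
  p <- fit$order
  a <- if (length(history) > 0) as_count_vector(history) else numeric(0)
  if (length(a) < p) stop("history shorter than the model order", call. = FALSE)
  t0 <- length(a)
  out <- numeric(horizon)
  a <- c(a, numeric(horizon))
  for (j in seq_len(horizon)) {
    t <- t0 + j
    x <- c(1, if (p > 0) a[t - seq_len(p)],
           if (fit$harmonic$n_harmonics > 0)
             as.vector(t(harmonic_design(fit$harmonic, t))))
    # cap keeps explosive parameter draws (autoregression on large counts)
    # finite and representable as integer Poisson draws
    mu <- min(exp(clip_lp(sum(x * coef))), 1e7)
    out[j] <- stats::rpois(1, mu)
    a[t] <- out[j]
  }
  as.integer(out)
}
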