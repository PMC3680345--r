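#' Day-of-stay stratification and covariate availability
#'
#' Departure-probability models are stratified by the number of days `s` a
#' patient has already spent in the unit: `s = 0, 1, ..., max_stratum - 1` plus
#' a pooled stratum for `s >= max_stratum`. The covariate set grows with `s` as
#' severity scores become available: at admission (`s = 0`) only birth weight
#' and gestational age exist; day-1 scores (`snapdol1`, `main1`) join at
#' `s >= 1`, the day-3 score (`snapdol3`) at `s >= 3` and the day-7 score
#' (`main7`) at `s >= 7`.
#'
#' @param max_stratum `R`: days of stay `>= R` are pooled into one stratum.
#' @return an object of class `stratum_spec`.
#' @export
stratum_spec <- function(max_stratum = 10) {
  stopifnot(max_stratum >= 1)
  structure(list(max_stratum = as.integer(max_stratum)), class = "stratum_spec")
}

#' @rdname stratum_spec
#' @param spec a `stratum_spec`.
#' @param s day of stay (for `covariate_set`) or vector of days of stay (for
#'   `stratum_of`).
#' @return `covariate_set()`: character vector of covariate names available at
#'   day of stay `s` (intercept excluded); `stratum_of()`: integer stratum
#'   index with `max_stratum` standing for the pooled `>= R` stratum;
#'   `stratum_levels()`: all stratum indices.
#' @export
covariate_set <- function(s) {
  out <- c("bweight", "gestage")
  if (s >= 1) out <- c(out, "snapdol1", "main1")
  if (s >= 3) out <- c(out, "snapdol3")
  if (s >= 7) out <- c(out, "main7")
  out
}

#' @rdname stratum_spec
#' @export
stratum_of <- function(s, spec = stratum_spec()) {
  as.integer(pmin(s, spec$max_stratum))
}

#' @rdname stratum_spec
#' @export
stratum_levels <- function(spec = stratum_spec()) {
  0:spec$max_stratum
}

# Covariate set used by the model of a stratum: for the pooled stratum the set
# at s = R (available for every pooled row since sets are monotone in s).
stratum_covariates <- function(stratum, spec = stratum_spec()) {
  covariate_set(min(stratum, spec$max_stratum))
}

#' Departure labels
#'
#' `Y^(k,s)` indicates whether a patient who has already spent `s` days in the
#' unit departs within `k` further days: 1 if `LOS <= k + s`, 0 if
#' `LOS > k + s`, and undefined (`NA`) when `LOS <= s` (the patient was never
#' at risk at day of stay `s`). For a stay censored at `c` days (`LOS > c`) the
#' label is determinable only as 0, when `c >= k + s`.
#'
#' @param los length of stay (or censoring bound), vectorized.
#' @param censored logical, vectorized.
#' @param k horizon in days, `>= 1`.
#' @param s days already spent in the unit, `>= 0`.
#' @return integer vector of 1/0/`NA` labels.
#' @export
departure_label <- function(los, censored = FALSE, k, s) {
  stopifnot(k >= 1, s >= 0)
  n <- max(length(los), length(censored))
  los <- rep_len(los, n)
  censored <- rep_len(censored, n)
  out <- rep(NA_integer_, n)
  known <- !censored
  out[known & los > s & los <= k + s] <- 1L
  out[known & los > k + s] <- 0L
  # censored at c: LOS > c, at risk at s iff c >= s; determinably 0 iff c >= k+s
  out[censored & los >= k + s] <- 0L
  out
}

# One row per (patient, day of stay s) for every s at which the patient was at
# risk, with the day-of-stay index; labels are added per horizon later.
person_day_table <- function(patients, spec) {
  at_risk_max <- ifelse(patients$censored, patients$los, patients$los - 1)
  idx <- rep(seq_len(nrow(patients)), times = pmax(at_risk_max + 1, 0))
  pd <- patients[idx, , drop = FALSE]
  pd$s <- as.integer(stats::ave(idx, idx, FUN = seq_along) - 1)
  pd$stratum <- stratum_of(pd$s, spec)
  tibble::as_tibble(pd)
}

#' Build a labeled training table for one (horizon, stratum) model
#'
#' One row per (patient, day of stay) pair falling in the stratum whose
#' departure label is determinable from information available by `cutoff_day`
#' and whose covariate set for that stratum is complete. The pooled stratum
#' takes every at-risk day of stay `s >= max_stratum` as a separate row.
#'
#' @inheritParams patient-records
#' @param k forecast horizon in days.
#' @param stratum stratum index (`0 ... max_stratum`, where `max_stratum`
#'   denotes the pooled `>= R` stratum).
#' @param cutoff_day labels are built only from information determinable by
#'   this day; the records are passed through [censor_at()].
#' @param spec a [stratum_spec()].
#' @return tibble with the stratum's covariates, `s`, and label `y`.
#' @export
departure_training_table <- function(patients, k, stratum, cutoff_day,
                                     spec = stratum_spec()) {
  stopifnot(stratum %in% stratum_levels(spec))
  patients <- censor_at(patients, cutoff_day)
  if (nrow(patients) == 0) {
    return(tibble::tibble())
  }
  pd <- person_day_table(patients, spec)
  pd <- pd[pd$stratum == stratum, , drop = FALSE]
  if (nrow(pd) == 0) return(pd)
  pd$y <- departure_label(pd$los, pd$censored, k = k, s = pd$s)
  pd <- pd[!is.na(pd$y), , drop = FALSE]
  covs <- stratum_covariates(stratum, spec)
  complete <- stats::complete.cases(pd[, covs, drop = FALSE])
  pd[complete, c("patient_id", "s", covs, "y"), drop = FALSE]
}

# Penalized logistic IRLS. penalty is a ridge coefficient applied to every
# non-intercept term. Returns NULL (caller falls back) when the data cannot
# support a fit.
logistic_irls <- function(X, y, penalty = 1e-4, max_iter = 80, tol = 1e-10) {
  P <- diag(c(0, rep(penalty, ncol(X) - 1)), ncol(X))
  beta <- rep(0, ncol(X))
  pll <- function(b) {
    eta <- clip_lp(drop(X %*% b))
    sum(y * eta - log1p(exp(eta))) - 0.5 * drop(t(b) %*% P %*% b)
  }
  ll <- pll(beta)
  for (iter in seq_len(max_iter)) {
    eta <- clip_lp(drop(X %*% beta))
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    info <- crossprod(X * w, X) + P
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- pll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) return(NULL)
    }
    converged <- max(abs(lambda * step)) < tol || abs(ll_new - ll) < 1e-13
    beta <- cand
    ll <- ll_new
    if (converged) {
      mu <- stats::plogis(clip_lp(drop(X %*% beta)))
      info <- crossprod(X * (mu * (1 - mu)), X) + P
      V <- tryCatch(ensure_psd(solve(info)), error = function(e) NULL)
      if (is.null(V)) return(NULL)
      return(list(coef = beta, vcov = V, loglik = ll))
    }
  }
  NULL
}

# Intercept-only fallback at the clamped empirical event rate; variance from
# the binomial information at that rate (capped when there is no data).
intercept_only_block <- function(y, covs, fallback) {
  n <- length(y)
  rate <- if (n == 0) 0.5 else mean(y)
  rate <- min(max(rate, 1 / (n + 2)), 1 - 1 / (n + 2))
  v <- if (n == 0) 25 else min(1 / (n * rate * (1 - rate)), 25)
  coef <- stats::setNames(c(stats::qlogis(rate), rep(0, length(covs))),
                          c("intercept", covs))
  V <- diag(c(v, rep(0, length(covs))), length(coef))
  dimnames(V) <- list(names(coef), names(coef))
  list(coef = coef, vcov = V, factor = psd_factor(V), covariates = covs,
       n = n, events = sum(y), fallback = fallback)
}

fit_block <- function(tab, covs, penalty) {
  if (nrow(tab) < 10 || length(unique(tab$y)) < 2) return(NULL)
  X <- cbind(intercept = 1, as.matrix(tab[, covs, drop = FALSE]))
  fit <- logistic_irls(X, tab$y, penalty = penalty)
  if (is.null(fit)) return(NULL)
  names(fit$coef) <- colnames(X)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  list(coef = fit$coef, vcov = fit$vcov, factor = psd_factor(fit$vcov),
       covariates = covs, n = nrow(tab), events = sum(tab$y), fallback = "none")
}

#' Fit stratified departure-probability models
#'
#' For every horizon `k` and day-of-stay stratum `s`, fits a logistic
#' regression of the departure label `Y^(k,s)` on the covariates available at
#' day of stay `s`, by maximum likelihood with a small ridge penalty on
#' non-intercept terms (guarding against separation in sparse strata). The
#' coefficient covariance is the inverse penalized observed information.
#'
#' Strata with fewer than 10 usable rows, no outcome variation, or a failed
#' fit fall back, in order, to (i) a refit on the rows pooled with the
#' adjacent smaller-`s` stratum using that stratum's (intersection) covariate
#' set, then (ii) an intercept-only model at the stratum's clamped empirical
#' event rate. Fallbacks are flagged in the result.
#'
#' @inheritParams departure_training_table
#' @param horizons integer horizons to fit (the forecaster needs every horizon
#'   `1 ... max(k)` for its interim-day pseudo-subjects).
#' @param penalty ridge penalty on non-intercept coefficients.
#' @return an object of class `departure_models`: a list of per-(k, stratum)
#'   blocks (`coef`, `vcov`, `covariates`, `n`, `events`, `fallback`) plus the
#'   `spec`, `horizons` and `cutoff_day`.
#' @export
fit_departures <- function(patients, horizons = 1:7, spec = stratum_spec(),
                           cutoff_day, penalty = 1e-4) {
  stopifnot(all(horizons >= 1))
  patients <- censor_at(patients, cutoff_day)
  if (nrow(patients) == 0) stop("no usable training records", call. = FALSE)
  pd <- person_day_table(patients, spec)
  blocks <- list()
  any_rows <- FALSE
  for (k in sort(unique(as.integer(horizons)))) {
    yk <- departure_label(pd$los, pd$censored, k = k, s = pd$s)
    for (st in stratum_levels(spec)) {
      rows <- pd$stratum == st & !is.na(yk)
      covs <- stratum_covariates(st, spec)
      tab <- pd[rows, , drop = FALSE]
      tab$y <- yk[rows]
      tab <- tab[stats::complete.cases(tab[, covs, drop = FALSE]), , drop = FALSE]
      blk <- fit_block(tab, covs, penalty)
      if (is.null(blk) && st > 0) {
        # (i) pool with the adjacent smaller-s stratum, intersection covariates
        covs_lo <- stratum_covariates(st - 1, spec)
        rows2 <- pd$stratum %in% c(st - 1, st) & !is.na(yk)
        tab2 <- pd[rows2, , drop = FALSE]
        tab2$y <- yk[rows2]
        tab2 <- tab2[stats::complete.cases(tab2[, covs_lo, drop = FALSE]), ,
                     drop = FALSE]
        blk <- fit_block(tab2, covs_lo, penalty)
        if (!is.null(blk)) blk$fallback <- "pooled_adjacent"
      }
      if (is.null(blk)) {
        blk <- intercept_only_block(tab$y, covs, fallback = "intercept_only")
      }
      if (blk$n > 0) any_rows <- TRUE
      blocks[[block_key(k, st)]] <- c(blk, list(k = k, stratum = st))
    }
  }
  if (!any_rows) stop("no usable departure labels by the cutoff", call. = FALSE)
  structure(
    list(blocks = blocks, spec = spec,
         horizons = sort(unique(as.integer(horizons))),
         cutoff_day = cutoff_day),
    class = "departure_models"
  )
}

block_key <- function(k, stratum) paste0("k", k, ".s", stratum)

#' @export
print.departure_models <- function(x, ...) {
  nfb <- sum(vapply(x$blocks, function(b) b$fallback != "none", logical(1)))
  cat("<departure_models>", length(x$blocks), "blocks (horizons",
      paste(range(x$horizons), collapse = "-"), "x strata 0-",
      x$spec$max_stratum, "), ", nfb, "fallback(s)\n")
  invisible(x)
}

#' Departure probability for a covariate vector
#'
#' Inverse-logit of the stratum model's linear predictor:
#' \eqn{\pi = \exp(z\beta) / (1 + \exp(z\beta))}.
#'
#' @param models a [fit_departures()] object.
#' @param z named covariate values (or a data frame of rows) matching the
#'   stratum's covariate set; the intercept is added automatically.
#' @param k horizon.
#' @param stratum stratum index (use [stratum_of()] for a day of stay).
#' @param coef optional replacement coefficient vector (e.g. an ensemble
#'   parameter draw).
#' @return departure probabilities in (0, 1).
#' @export
departure_prob <- function(models, z, k, stratum, coef = NULL) {
  blk <- models$blocks[[block_key(k, stratum)]]
  if (is.null(blk)) {
    stop("no fitted model for horizon ", k, ", stratum ", stratum, call. = FALSE)
  }
  if (is.null(coef)) coef <- blk$coef
  if (!is.data.frame(z)) z <- tibble::as_tibble(as.list(z))
  missing_covs <- setdiff(blk$covariates, names(z))
  if (length(missing_covs) > 0) {
    stop("covariate(s) missing for stratum ", stratum, ": ",
         paste(missing_covs, collapse = ", "), call. = FALSE)
  }
  X <- cbind(1, as.matrix(z[, blk$covariates, drop = FALSE]))
  if (ncol(X) != length(coef)) stop("coefficient length mismatch", call. = FALSE)
  unname(stats::plogis(clip_lp(drop(X %*% coef))))
}

#' Sample departures from the current census
#'
#' For every patient present in the census state, draws
#' \eqn{\hat Y_i^{(k,s)} \sim Bernoulli(\hat\pi_i)} from the patient's
#' stratum model at horizon `k` and sums the indicators — the sampled number
#' of current-census patients departing within `k` days.
#'
#' @param state a [census_state()].
#' @param models a [fit_departures()] object.
#' @param k horizon.
#' @param coef_draws optional named list of coefficient vectors per block key
#'   (ensemble draws); defaults to the fitted coefficients.
#' @return list with `draws` (tibble: `patient_id`, `s`, `stratum`, `pi`, `y`)
#'   and `total` (the sampled departure count, `<= census_count`).
#' @export
sample_departures <- function(state, models, k, coef_draws = NULL) {
  present <- state$present
  if (nrow(present) == 0) {
    return(list(draws = tibble::tibble(), total = 0L))
  }
  spec <- models$spec
  present$stratum <- stratum_of(present$s, spec)
  out <- vector("list", length(unique(present$stratum)))
  i <- 1
  for (st in sort(unique(present$stratum))) {
    rows <- present[present$stratum == st, , drop = FALSE]
    covs <- stratum_covariates(st, spec)
    for (cv in covs) {
      if (anyNA(rows[[cv]])) {
        bad <- rows$patient_id[is.na(rows[[cv]])][1]
        stop("patient ", bad, " lacks covariate '", cv,
             "' required by stratum ", st, call. = FALSE)
      }
    }
    coef <- if (!is.null(coef_draws)) coef_draws[[block_key(k, st)]] else NULL
    pi_hat <- departure_prob(models, rows, k = k, stratum = st, coef = coef)
    out[[i]] <- tibble::tibble(patient_id = rows$patient_id, s = rows$s,
                               stratum = st, pi = pi_hat,
                               y = stats::rbinom(nrow(rows), 1, pi_hat))
    i <- i + 1
  }
  draws <- dplyr::bind_rows(out)
  list(draws = draws, total = as.integer(sum(draws$y)))
}

#' Resample baseline covariates for pseudo-subjects
#'
#' Patients arriving between the forecast origin and the target day are not
#' yet observed; their departure probabilities are computed from baseline
#' covariates resampled jointly (birth weight with its gestational age) with
#' replacement from the training pool.
#'
#' @inheritParams patient-records
#' @param n number of pseudo-subjects.
#' @return tibble with `n` rows of `bweight`, `gestage`.
#' @export
sample_pseudo_subjects <- function(patients, n) {
  stopifnot(n >= 0)
  pool <- patients[!is.na(patients$bweight) & !is.na(patients$gestage), ,
                   drop = FALSE]
  if (n == 0) {
    return(tibble::tibble(bweight = numeric(), gestage = numeric()))
  }
  if (nrow(pool) == 0) stop("empty training pool", call. = FALSE)
  idx <- sample.int(nrow(pool), n, replace = TRUE)
  tibble::tibble(bweight = pool$bweight[idx], gestage = pool$gestage[idx])
}
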