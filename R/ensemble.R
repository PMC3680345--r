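#' Ensemble configuration
#'
#' @param n_realizations `M`, the ensemble size.
#' @param horizons forecast horizons in days.
#' @param quantiles lower/upper percentile for the prediction interval.
#' @param point point summary over the ensemble: `"median"` (default) or
#'   `"mean"`.
#' @param seed master seed; each realization derives its own substream so the
#'   ensemble is bit-reproducible and extending `M` never reshuffles earlier
#'   realizations. `NULL` draws a master seed from the ambient RNG.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_realizations = 1000, horizons = c(1, 3, 5, 7),
                            quantiles = c(0.025, 0.975),
                            point = c("median", "mean"), seed = NULL) {
  stopifnot(n_realizations >= 1, all(horizons >= 1),
            length(quantiles) == 2, all(quantiles > 0), all(quantiles < 1),
            quantiles[1] < quantiles[2])
  structure(
    list(n_realizations = as.integer(n_realizations),
         horizons = sort(unique(as.integer(horizons))),
         quantiles = quantiles, point = match.arg(point), seed = seed),
    class = "ensemble_config"
  )
}

#' Summarize an ensemble of census realizations
#'
#' Point summary plus empirical percentile interval. Quantiles use the default
#' interpolation convention of [stats::quantile()] (type 7).
#'
#' @param realizations numeric vector of ensemble realizations.
#' @param point `"median"` or `"mean"`.
#' @param quantiles lower/upper interval percentiles.
#' @return named numeric vector `point`, `lo`, `hi`.
#' @export
summarize_ensemble <- function(realizations, point = "median",
                               quantiles = c(0.025, 0.975)) {
  if (length(realizations) == 0) stop("empty ensemble", call. = FALSE)
  pt <- if (point == "mean") mean(realizations) else stats::median(realizations)
  qs <- stats::quantile(realizations, probs = quantiles, names = FALSE, type = 7)
  c(point = pt, lo = qs[1], hi = qs[2])
}

#' Ensemble census forecast
#'
#' Generates `M` stochastic realizations of the census `k` days ahead, jointly
#' propagating parameter uncertainty and arrival/departure randomness. For
#' each realization `r`:
#' \enumerate{
#'   \item draw arrival parameters \eqn{\lambda^{(r)} \sim MVN(\hat\lambda,
#'     V_\lambda)} and departure coefficients \eqn{\beta^{(r)(k,s)} \sim
#'     MVN(\hat\beta^{(k,s)}, V_\beta^{(k,s)})} for every horizon/stratum
#'     block;
#'   \item simulate arrivals \eqn{\hat A^{(r)}(t+1..t+k)} sequentially from
#'     the Poisson autoregression under \eqn{\lambda^{(r)}};
#'   \item draw a Bernoulli departure indicator for every patient currently in
#'     the census from its stratum model at horizon `k`;
#'   \item for each interim day `t+j` (`j = 1..k-1`) create
#'     \eqn{\hat A^{(r)}(t+j)} pseudo-subjects (baseline covariates resampled
#'     from the training pool) and draw their departure-within-`k-j`
#'     indicators from the day-of-stay-0 model; arrivals on day `t+k` itself
#'     cannot have departed;
#'   \item the realization is \eqn{\hat C^{(r)}(t+k) = C(t) + \sum_j \hat
#'     A^{(r)}(t+j) - } (census draws + pseudo draws).
#' }
#' Each requested horizon uses its own departure draws (departures are
#' cumulative within-`k` indicators, never double-counted across days), while
#' the arrival trajectory is shared within a realization. Realizations are
#' non-negative by construction.
#'
#' @param state the current [census_state()] at the forecast origin `t`.
#' @param par_fit a fitted arrival model ([fit_par()]).
#' @param dep_models fitted departure models ([fit_departures()]); must cover
#'   horizons `1 ... max(config$horizons)`.
#' @param training_patients patient table supplying the pseudo-subject
#'   baseline-covariate pool.
#' @param config an [ensemble_config()].
#' @param arrival_history observed arrival counts for days `1 ... t` (the
#'   forecast origin). Defaults to the series stored in `par_fit`, which is
#'   correct when the model was fitted at the origin; supply it explicitly
#'   when forecasting from a later day than the last refit.
#' @return an object of class `census_forecast`: `summary` tibble (`origin`,
#'   `horizon`, `point`, `lo`, `hi`), `realizations` matrix (`M` x horizons),
#'   `arrivals` matrix of per-realization arrival trajectories, and the
#'   config/seed used.
#' @export
forecast_census <- function(state, par_fit, dep_models, training_patients,
                            config = ensemble_config(),
                            arrival_history = NULL) {
  if (is.null(arrival_history)) arrival_history <- par_fit$series
  horizons <- config$horizons
  kmax <- max(horizons)
  need_k <- seq_len(kmax)
  have_k <- dep_models$horizons
  if (!all(need_k %in% have_k)) {
    stop("departure models must cover horizons 1..", kmax, "; missing: ",
         paste(setdiff(need_k, have_k), collapse = ", "), call. = FALSE)
  }
  spec <- dep_models$spec
  M <- config$n_realizations
  seed <- master_seed(config$seed)

  present <- state$present
  present$stratum <- if (nrow(present)) stratum_of(present$s, spec) else integer()
  strata_present <- sort(unique(present$stratum))
  # per-stratum design matrices of the current census (intercept included)
  Z_by_stratum <- lapply(strata_present, function(st) {
    rows <- present[present$stratum == st, , drop = FALSE]
    covs <- stratum_covariates(st, spec)
    for (cv in covs) {
      if (anyNA(rows[[cv]])) {
        stop("patient ", rows$patient_id[is.na(rows[[cv]])][1],
             " lacks covariate '", cv, "' required by stratum ", st,
             call. = FALSE)
      }
    }
    cbind(1, as.matrix(rows[, covs, drop = FALSE]))
  })
  names(Z_by_stratum) <- as.character(strata_present)

  pool <- training_patients[!is.na(training_patients$bweight) &
                              !is.na(training_patients$gestage), , drop = FALSE]
  if (nrow(pool) == 0 && kmax > 1) {
    stop("empty pseudo-subject pool", call. = FALSE)
  }
  # blocks whose coefficients are drawn each realization: every needed horizon
  # for the strata in the census, plus day-of-stay 0 for pseudo-subjects
  draw_strata <- sort(unique(c(strata_present, 0L)))
  block_keys <- as.vector(outer(need_k, draw_strata, block_key))

  C_t <- state$census_count
  realizations <- matrix(NA_real_, nrow = M, ncol = length(horizons),
                         dimnames = list(NULL, paste0("k", horizons)))
  arrivals_mat <- matrix(NA_integer_, nrow = M, ncol = kmax)

  for (r in seq_len(M)) {
    set.seed(substream_seed(seed, r))
    lambda_r <- mvn_draw(par_fit$coef, par_fit$factor)
    beta_r <- lapply(dep_models$blocks[block_keys], function(b) {
      mvn_draw(b$coef, b$factor)
    })
    a_r <- simulate_arrivals(par_fit, arrival_history, kmax, coef = lambda_r)
    arrivals_mat[r, ] <- a_r
    # pseudo-subject pool indices per interim day, shared across horizons so a
    # day's arrivals are the same individuals whichever horizon looks at them
    pseudo_idx <- lapply(seq_len(kmax), function(j) {
      if (a_r[j] > 0) sample.int(nrow(pool), a_r[j], replace = TRUE)
      else integer()
    })
    for (h in seq_along(horizons)) {
      k <- horizons[h]
      # departures among the current census within k days
      d_census <- 0L
      for (st in strata_present) {
        Z <- Z_by_stratum[[as.character(st)]]
        pi_hat <- stats::plogis(clip_lp(drop(Z %*% beta_r[[block_key(k, st)]])))
        d_census <- d_census + sum(stats::rbinom(nrow(Z), 1, pi_hat))
      }
      # departures among interim-day pseudo-subjects (arrivals on t+k excluded)
      d_pseudo <- 0L
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          idx <- pseudo_idx[[j]]
          if (length(idx) == 0) next
          Zs <- cbind(1, pool$bweight[idx], pool$gestage[idx])
          pi_s <- stats::plogis(clip_lp(drop(Zs %*% beta_r[[block_key(k - j, 0L)]])))
          d_pseudo <- d_pseudo + sum(stats::rbinom(length(idx), 1, pi_s))
        }
      }
      realizations[r, h] <- C_t + sum(a_r[seq_len(k)]) - d_census - d_pseudo
    }
  }

  summary <- purrr::map_dfr(seq_along(horizons), function(h) {
    sm <- summarize_ensemble(realizations[, h], config$point, config$quantiles)
    tibble::tibble(origin = state$day, horizon = horizons[h],
                   point = sm[["point"]], lo = sm[["lo"]], hi = sm[["hi"]])
  })
  structure(
    list(summary = summary, realizations = realizations,
         arrivals = arrivals_mat, origin = state$day, census = C_t,
         config = config, seed = seed),
    class = "census_forecast"
  )
}

#' @export
print.census_forecast <- function(x, ...) {
  cat("<census_forecast> origin day", x$origin, "- census", x$census,
      "- M =", nrow(x$realizations), "\n")
  print(x$summary)
  invisible(x)
}
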