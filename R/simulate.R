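#' Synthetic unit-history generator configuration
#'
#' Defaults emulate a busy level-III NICU over roughly a year and a half:
#' seasonal Poisson arrivals around 2.7 admissions/day with a semi-annual
#' harmonic, jointly distributed birth weight (mean 2418 g, SD 940 g) and
#' gestational age (mean 34.6 completed weeks, SD 4.0, correlation 0.8),
#' zero-inflated severity scores that worsen with prematurity, and length of
#' stay driven by a covariate-dependent discrete-time logistic departure
#' hazard calibrated to a right-skewed LOS distribution (median near 10 days,
#' mean near 20, capped at 120).
#'
#' The hazard at day of stay `j` (probability of departing during day `j`
#' given survival of `j - 1` days) is
#' `plogis(h0(j) + coefs . z)` with a log-quadratic baseline
#' `h0(j) = hazard_a + hazard_b * log(j) + hazard_c * j` and covariate vector
#' `z = (bweight_kg - 2.418, gestage - 34.6, snapdol1, main1, snapdol3,
#' main7)`. Scores are generated for every patient (they are fixed at
#' admission and merely revealed on their collection day) but masked in the
#' output whenever the realized stay never reaches the collection day.
#'
#' @param arrival_beta0 intercept of the true arrival log-mean.
#' @param arrival_ar autoregressive coefficients of the true arrival process.
#' @param arrival_phi,arrival_alpha cosine/sine amplitudes of the seasonal
#'   harmonic(s).
#' @param arrival_freq harmonic frequency in cycles per simulated series.
#' @param hazard_a,hazard_b,hazard_c baseline logit-hazard parameters.
#' @param hazard_coefs named numeric effects on the logit hazard for
#'   `bweight_kg` (per kg, centered), `gestage` (per week, centered),
#'   `snapdol1`, `main1`, `snapdol3`, `main7`.
#' @param max_los administrative cap on length of stay (days).
#' @return an object of class `unit_sim_config`.
#' @export
unit_sim_config <- function(arrival_beta0 = 0.858,
                            arrival_ar = 0.05,
                            arrival_phi = 0.18,
                            arrival_alpha = 0,
                            arrival_freq = 3,
                            hazard_a = -3.10,
                            hazard_b = 0.70,
                            hazard_c = -0.047,
                            hazard_coefs = c(bweight_kg = 0.30,
                                             gestage = 0.08,
                                             snapdol1 = -0.015,
                                             main1 = -0.0006,
                                             snapdol3 = 0,
                                             main7 = 0),
                            max_los = 120) {
  stopifnot(max_los >= 2, length(arrival_phi) == length(arrival_alpha))
  structure(
    list(arrival_beta0 = arrival_beta0, arrival_ar = arrival_ar,
         arrival_phi = arrival_phi, arrival_alpha = arrival_alpha,
         arrival_freq = arrival_freq,
         hazard_a = hazard_a, hazard_b = hazard_b, hazard_c = hazard_c,
         hazard_coefs = hazard_coefs, max_los = as.integer(max_los)),
    class = "unit_sim_config"
  )
}

# Centered covariate vector entering the hazard, in hazard_coefs order.
hazard_z <- function(bweight, gestage, snapdol1, main1, snapdol3, main7) {
  cbind(bweight_kg = bweight / 1000 - 2.418, gestage = gestage - 34.6,
        snapdol1 = snapdol1, main1 = main1, snapdol3 = snapdol3, main7 = main7)
}

# Per-day departure hazards h(j, z) for j = 1..max_los (matrix: n x max_los).
hazard_matrix <- function(config, z) {
  j <- seq_len(config$max_los)
  base <- config$hazard_a + config$hazard_b * log(j) + config$hazard_c * j
  lp_z <- drop(z %*% config$hazard_coefs[colnames(z)])
  stats::plogis(outer(lp_z, base, `+`))
}

#' True conditional departure probability under the generator's hazard
#'
#' Closed-form discrete-time survival:
#' \deqn{P(LOS \le k + s \mid LOS > s, z) =
#'   1 - \prod_{j=s+1}^{s+k} (1 - h(j, z)),}
#' the oracle the stratified departure models estimate when well specified.
#' Days beyond the LOS cap have hazard 1 (administrative discharge).
#'
#' @param config a [unit_sim_config()].
#' @param z named covariates `bweight` (g), `gestage` (weeks), and scores
#'   `snapdol1`, `main1`, `snapdol3`, `main7` (defaults 0).
#' @param k horizon (days), `>= 1`.
#' @param s days already spent in the unit, `>= 0`.
#' @return the probability of departure within `k` further days.
#' @export
true_departure_prob <- function(config, z, k, s) {
  stopifnot(k >= 1, s >= 0)
  z <- as.list(z)
  for (nm in c("snapdol1", "main1", "snapdol3", "main7")) {
    if (is.null(z[[nm]])) z[[nm]] <- 0
  }
  zz <- hazard_z(z$bweight, z$gestage, z$snapdol1, z$main1, z$snapdol3, z$main7)
  h <- drop(hazard_matrix(config, zz))
  h <- c(h, 1)  # day max_los + 1: cap forces departure
  days <- pmin(s + seq_len(k), config$max_los + 1)
  1 - prod(1 - h[days])
}

# Draw patient covariates calibrated to typical level-III NICU marginals.
draw_covariates <- function(n) {
  # truncated-normal gestational age in completed weeks; pre-truncation mean
  # compensates for the asymmetric truncation so the realized mean is ~34.6
  gestage <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    g <- stats::rnorm(length(todo), 34.88, 4.0)
    ok <- g >= 22.5 & g <= 42.49
    gestage[todo[ok]] <- g[ok]
    todo <- todo[!ok]
  }
  gestage <- round(gestage)
  # birth weight conditionally normal given gestational age (correlation 0.8)
  bw_mu <- 2418 + 0.8 * (939.8 / 4.0) * (gestage - 34.6)
  bweight <- round(bw_mu + stats::rnorm(n, 0, 939.8 * sqrt(1 - 0.8^2)))
  bweight <- pmin(pmax(bweight, 360), 5493)
  # day-1 severity: zero-inflated, worse with prematurity (median 0)
  p_pos <- stats::plogis(-0.80 - 0.45 * (gestage - 34.6))
  pos <- stats::rbinom(n, 1, p_pos)
  snapdol1 <- pos * round(stats::rgamma(n, shape = 1.3,
                                        scale = pmax(4, 18 - 2.2 * (gestage - 34.6)) / 1.3))
  # day-3 severity: damped version of day 1 (binomial thinning)
  snapdol3 <- stats::rbinom(n, snapdol1, 0.6)
  # day-1 morbidity index: continuous, floored at 0, worse with prematurity
  main1 <- pmax(0, round(stats::rnorm(n, 485 - 40 * (gestage - 34.6), 270)))
  # day-7 morbidity index: inflated relative to day 1
  main7 <- pmax(0, round(0.95 * main1 + 200 + stats::rnorm(n, 0, 120)))
  tibble::tibble(bweight = bweight, gestage = gestage, snapdol1 = snapdol1,
                 main1 = main1, snapdol3 = snapdol3, main7 = main7)
}

#' Simulate a complete synthetic unit history
#'
#' Simulates daily arrivals from the configured seasonal Poisson
#' autoregression, gives each admission covariates from the configured laws,
#' and draws each length of stay by iterating the discrete-time departure
#' hazard. Scores a patient's stay never reached are masked (`NA`) in the
#' patient table, per the day-1/3/7 availability rules. Truth tables needed
#' by oracle checks (daily census and flows, the realized arrival series) are
#' returned alongside.
#'
#' @param n_days length of the simulated calendar (days).
#' @param config a [unit_sim_config()].
#' @param seed integer seed; the history is fully reproducible given
#'   (`n_days`, `config`, `seed`).
#' @return an object of class `unit_history`: `patients` (patient table),
#'   `arrivals` (tibble `day`, `arrivals` over the calendar), `truth` (tibble
#'   `day`, `census`, `arrivals`, `departures` from the realized records),
#'   plus the `config` and `seed`.
#' @export
simulate_unit_history <- function(n_days = 560, config = unit_sim_config(),
                                  seed = NULL) {
  stopifnot(n_days >= 2 * config$max_los)
  seed <- master_seed(seed)
  set.seed(seed)
  p <- length(config$arrival_ar)
  hspec <- harmonic_spec(config$arrival_freq, n_days)
  coef <- c(config$arrival_beta0, config$arrival_ar,
            as.vector(rbind(config$arrival_phi, config$arrival_alpha)))
  # pre-sample lags initialized at the unconditional intercept-scale mean
  a_full <- c(rep(round(exp(config$arrival_beta0)), p), integer(n_days))
  for (t in seq_len(n_days)) {
    i <- p + t
    lags <- if (p > 0) a_full[i - seq_len(p)] else numeric(0)
    x <- c(1, lags, if (hspec$n_harmonics > 0)
      as.vector(t(harmonic_design(hspec, t))))
    # cap guards against explosive autoregressive configurations
    mu <- min(exp(clip_lp(sum(x * coef))), 1e6)
    a_full[i] <- stats::rpois(1, mu)
  }
  arrivals <- as.integer(a_full[p + seq_len(n_days)])
  n_pat <- sum(arrivals)
  admit_day <- rep(seq_len(n_days), times = arrivals)
  covs <- draw_covariates(n_pat)
  # length of stay by iterating the daily hazard; cap forces discharge
  H <- hazard_matrix(config, hazard_z(covs$bweight, covs$gestage,
                                      covs$snapdol1, covs$main1,
                                      covs$snapdol3, covs$main7))
  U <- matrix(stats::runif(n_pat * config$max_los), n_pat, config$max_los)
  departed <- U < H
  los <- apply(departed, 1, function(d) {
    w <- which(d)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  los[is.na(los)] <- config$max_los
  patients <- dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("P%05d", seq_len(n_pat)),
                   admit_day = admit_day, los = as.integer(los),
                   censored = FALSE),
    covs
  )
  # mask scores the realized stay never revealed (patient departed before the
  # collection day: at risk at day-of-stay d requires LOS > d)
  for (sc in names(SCORE_DAYS)) {
    patients[[sc]][patients$los <= SCORE_DAYS[[sc]]] <- NA
  }
  truth <- dplyr::left_join(
    census_series(patients, seq_len(n_days)),
    daily_flows(patients, seq_len(n_days)),
    by = "day"
  )
  structure(
    list(patients = patients,
         arrivals = tibble::tibble(day = seq_len(n_days), arrivals = arrivals),
         truth = truth, config = config, seed = seed,
         true_harmonic = hspec, true_coef = coef),
    class = "unit_history"
  )
}

#' @export
print.unit_history <- function(x, ...) {
  cat("<unit_history>", nrow(x$arrivals), "days,", nrow(x$patients),
      "patients, seed", x$seed, "\n")
  invisible(x)
}
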