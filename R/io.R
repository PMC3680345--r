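#' Read and write patient and arrival files
#'
#' Patient files are delimited text (CSV) with columns `patient_id`,
#' `admit_date` (ISO-8601), `los_days`, `censored` (0/1), `bweight`,
#' `gestage`, `snapdol1`, `main1`, `snapdol3`, `main7`; an empty field means
#' the score is unavailable. Arrival files have columns `date`, `count` and
#' must be gap-free and daily. Dates are mapped to 1-based internal day
#' indices relative to `start_date` (day 1 = `start_date`).
#'
#' @param path file path.
#' @param start_date `Date` mapped to internal day 1; defaults to the earliest
#'   date in the file.
#' @return `read_patients()`: a validated patient tibble (with a
#'   `start_date` attribute); `read_arrivals()`: a tibble `day`, `arrivals`
#'   (with a `start_date` attribute).
#' @name census-files
NULL

#' @rdname census-files
#' @export
read_patients <- function(path, start_date = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           admit_date = readr::col_date(),
                           los_days = readr::col_double(),
                           censored = readr::col_double(),
                           .default = readr::col_double()))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed patient file ", path, ": ",
         paste0("line ", prob$row, ": ", prob$expected, " vs ", prob$actual,
                collapse = "; "), call. = FALSE)
  }
  if (is.null(start_date)) start_date <- min(raw$admit_date)
  patients <- tibble::tibble(
    patient_id = raw$patient_id,
    admit_day = as.integer(raw$admit_date - as.Date(start_date)) + 1L,
    los = as.integer(raw$los_days),
    censored = raw$censored != 0,
    bweight = raw$bweight, gestage = raw$gestage,
    snapdol1 = raw$snapdol1, main1 = raw$main1,
    snapdol3 = raw$snapdol3, main7 = raw$main7
  )
  patients <- validate_patients(patients)
  attr(patients, "start_date") <- as.Date(start_date)
  patients
}

#' @rdname census-files
#' @inheritParams patient-records
#' @export
write_patients <- function(patients, path, start_date = as.Date("2000-01-01")) {
  patients <- validate_patients(patients)
  out <- tibble::tibble(
    patient_id = patients$patient_id,
    admit_date = as.Date(start_date) + patients$admit_day - 1L,
    los_days = patients$los,
    censored = as.integer(patients$censored),
    bweight = patients$bweight, gestage = patients$gestage,
    snapdol1 = patients$snapdol1, main1 = patients$main1,
    snapdol3 = patients$snapdol3, main7 = patients$main7
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname census-files
#' @export
read_arrivals <- function(path, start_date = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(date = readr::col_date(),
                                                 count = readr::col_double()))
  if (is.null(start_date)) start_date <- min(raw$date)
  day <- as.integer(raw$date - as.Date(start_date)) + 1L
  if (!identical(sort(day), seq_len(length(day)) + min(day) - 1L) ||
      anyNA(raw$count)) {
    stop("arrival file must be gap-free, daily and complete", call. = FALSE)
  }
  assert_count_series(raw$count, "arrival counts")
  out <- tibble::tibble(day = day, arrivals = as.integer(raw$count))
  out <- out[order(out$day), ]
  attr(out, "start_date") <- as.Date(start_date)
  out
}

#' @rdname census-files
#' @param arrivals tibble `day`, `arrivals`.
#' @export
write_arrivals <- function(arrivals, path, start_date = as.Date("2000-01-01")) {
  out <- tibble::tibble(date = as.Date(start_date) + arrivals$day - 1L,
                        count = arrivals$arrivals)
  readr::write_csv(out, path)
  invisible(path)
}

#' Serialize fitted models to plain text
#'
#' Fitted arrival and departure models round-trip through JSON so a fit can be
#' reused by later runs of the command-line workflows.
#'
#' @param fit a [fit_par()] object.
#' @param models a [fit_departures()] object.
#' @param path file path.
#' @name model-serialization
NULL

#' @rdname model-serialization
#' @export
write_par_fit <- function(fit, path) {
  obj <- list(order = fit$order, coef = as.list(fit$coef),
              vcov = fit$vcov, loglik = fit$loglik, bic = fit$bic,
              n_eff = fit$n_eff, cond_start = fit$cond_start,
              harmonic = list(frequencies = fit$harmonic$frequencies,
                              series_length = fit$harmonic$series_length),
              series = fit$series)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model-serialization
#' @export
read_par_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- unlist(obj$coef)
  V <- ensure_psd(matrix(as.numeric(obj$vcov), length(coef), length(coef)))
  dimnames(V) <- list(names(coef), names(coef))
  structure(
    list(coef = coef, vcov = V, factor = psd_factor(V), loglik = obj$loglik,
         bic = obj$bic, order = as.integer(obj$order),
         harmonic = harmonic_spec(obj$harmonic$frequencies,
                                  obj$harmonic$series_length),
         n_eff = obj$n_eff, cond_start = obj$cond_start,
         series = as.numeric(obj$series)),
    class = "par_fit"
  )
}

#' @rdname model-serialization
#' @export
write_departure_models <- function(models, path) {
  blocks <- lapply(models$blocks, function(b) {
    list(k = b$k, stratum = b$stratum, covariates = b$covariates,
         coef = as.list(b$coef), vcov = b$vcov, n = b$n, events = b$events,
         fallback = b$fallback)
  })
  obj <- list(max_stratum = models$spec$max_stratum, horizons = models$horizons,
              cutoff_day = models$cutoff_day, blocks = blocks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model-serialization
#' @export
read_departure_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  blocks <- lapply(obj$blocks, function(b) {
    coef <- unlist(b$coef)
    V <- ensure_psd(matrix(as.numeric(b$vcov), length(coef), length(coef)))
    dimnames(V) <- list(names(coef), names(coef))
    list(coef = coef, vcov = V, factor = psd_factor(V),
         covariates = b$covariates, n = b$n, events = b$events,
         fallback = b$fallback, k = b$k, stratum = b$stratum)
  })
  structure(
    list(blocks = blocks, spec = stratum_spec(obj$max_stratum),
         horizons = as.integer(obj$horizons), cutoff_day = obj$cutoff_day),
    class = "departure_models"
  )
}

#' Write a forecast result as delimited text
#'
#' One row per (origin, horizon) with the point forecast, interval bounds,
#' ensemble size and seed.
#'
#' @param forecast a [forecast_census()] result.
#' @param path file path.
#' @export
write_forecast <- function(forecast, path) {
  out <- forecast$summary
  out$m <- nrow(forecast$realizations)
  out$seed <- forecast$seed
  readr::write_csv(out, path)
  invisible(path)
}
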