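#' Patient records and the census ledger
#'
#' A patient table has one row per admitted patient with columns
#' `patient_id`, `admit_day` (integer calendar day, 1-based), `los`
#' (length of stay in whole days; for censored rows the number of days the
#' patient is *known* to have exceeded), `censored` (logical), the baseline
#' covariates `bweight` (grams) and `gestage` (completed weeks), and the
#' time-varying severity scores `snapdol1`, `main1` (collected on day 1 of
#' stay), `snapdol3` (day 3) and `main7` (day 7). A score is `NA` whenever the
#' patient's (possibly censored) stay never reached the score's collection day.
#'
#' Day convention: a patient admitted on day `a` with length of stay `L` is in
#' the end-of-day (11:59pm) census on days `a, a+1, ..., a+L-1`; day of stay
#' `s = day - a`, so the admission day is `s = 0`. The departure is recorded in
#' the daily flow of day `a+L`, the first day the patient is absent. A row
#' censored at `c` means `LOS > c`: the patient was still present at end of
#' day `a + c`. Stays under 24 hours (`los = 0`) are excluded by validation.
#'
#' @param patients a patient table as described above.
#' @name patient-records
NULL

PATIENT_COLS <- c("patient_id", "admit_day", "los", "censored",
                  "bweight", "gestage", "snapdol1", "main1", "snapdol3", "main7")

# Collection day (day of stay s at which a score becomes available).
SCORE_DAYS <- c(snapdol1 = 1, main1 = 1, snapdol3 = 3, main7 = 7)

#' Validate a patient table
#'
#' Checks column presence and types, the `los >= 1` inclusion rule (stays must
#' exceed 24 hours), and the availability rules for time-varying scores: a
#' score collected on day of stay `d` may only be non-missing when the patient
#' was still present at day of stay `d` (known `LOS > d`, or censoring bound
#' `>= d`).
#'
#' @inheritParams patient-records
#' @return the table, invisibly, as a tibble; errors list offending rows.
#' @export
validate_patients <- function(patients) {
  patients <- tibble::as_tibble(patients)
  missing_cols <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_cols) > 0) {
    stop("patient table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop(msg, " (row", if (length(idx) > 1) "s", " ",
           paste(utils::head(idx, 10), collapse = ", "),
           if (length(idx) > 10) ", ...", ")", call. = FALSE)
    }
  }
  bad(is.na(patients$admit_day) | patients$admit_day != round(patients$admit_day),
      "admit_day must be an integer day index")
  bad(is.na(patients$los) | patients$los != round(patients$los),
      "los must be a whole number of days")
  bad(!patients$censored & patients$los < 1,
      "stays must exceed 24 hours (los >= 1)")
  bad(patients$censored & patients$los < 0,
      "censoring bound must be >= 0 days")
  bad(duplicated(patients$patient_id), "duplicated patient_id")
  # score availability: non-missing score requires presence at day-of-stay d
  for (sc in names(SCORE_DAYS)) {
    d <- SCORE_DAYS[[sc]]
    reached <- ifelse(patients$censored, patients$los >= d, patients$los > d)
    bad(!is.na(patients[[sc]]) & !reached,
        sprintf("%s recorded for a stay that never reached day %d", sc, d))
  }
  invisible(patients)
}

# Last calendar day on which the patient is known to be present in the
# end-of-day census.
last_present_day <- function(patients) {
  ifelse(patients$censored,
         patients$admit_day + patients$los,
         patients$admit_day + patients$los - 1)
}

#' Census state at a given day
#'
#' Reconstructs the end-of-day unit census at calendar day `day` from patient
#' records: everyone with `admit_day <= day` who had not yet departed. Censored
#' patients count as present through their last known-present day.
#'
#' @inheritParams patient-records
#' @param day integer calendar day within the range covered by the records.
#' @return an object of class `census_state`: a list with `day`, `present`
#'   (tibble of present patients with their day of stay `s`), `census_count`
#'   \eqn{C(t)} and `occupancy` (tibble of counts \eqn{H_s(t)} by `s`).
#' @export
census_state <- function(patients, day) {
  patients <- validate_patients(patients)
  if (nrow(patients) == 0) stop("no patient records", call. = FALSE)
  last_day <- last_present_day(patients)
  if (day < min(patients$admit_day) || day > max(last_day)) {
    stop("day ", day, " outside the calendar range covered by the records [",
         min(patients$admit_day), ", ", max(last_day), "]", call. = FALSE)
  }
  present <- patients[patients$admit_day <= day & last_day >= day, , drop = FALSE]
  present <- dplyr::mutate(present, s = as.integer(day - .data$admit_day))
  occupancy <- dplyr::count(present, .data$s, name = "n")
  structure(
    list(day = as.integer(day),
         present = present,
         census_count = nrow(present),
         occupancy = occupancy),
    class = "census_state"
  )
}

#' @export
print.census_state <- function(x, ...) {
  cat("<census_state> day", x$day, "- census", x$census_count, "patients\n")
  print(x$occupancy, n = 5)
  invisible(x)
}

#' Daily census series
#'
#' @inheritParams patient-records
#' @param days integer vector of calendar days (default: the full range the
#'   records cover).
#' @return tibble with columns `day`, `census`.
#' @export
census_series <- function(patients, days = NULL) {
  patients <- validate_patients(patients)
  last_day <- last_present_day(patients)
  if (is.null(days)) days <- seq(min(patients$admit_day), max(last_day))
  census <- vapply(days, function(d) {
    sum(patients$admit_day <= d & last_day >= d)
  }, integer(1))
  tibble::tibble(day = as.integer(days), census = census)
}

#' Daily arrival and departure flows
#'
#' Arrivals on day `d` are admissions with `admit_day == d`; departures on day
#' `d` are patients whose last present day was `d - 1` (the departure is
#' recorded on the first day the patient is absent). Censored patients never
#' contribute a departure.
#'
#' @inheritParams census_series
#' @return tibble with columns `day`, `arrivals`, `departures`.
#' @export
daily_flows <- function(patients, days = NULL) {
  patients <- validate_patients(patients)
  last_day <- last_present_day(patients)
  if (is.null(days)) days <- seq(min(patients$admit_day), max(last_day))
  depart_day <- ifelse(patients$censored, NA_integer_, last_day + 1L)
  tibble::tibble(
    day = as.integer(days),
    arrivals = vapply(days, function(d) sum(patients$admit_day == d), integer(1)),
    departures = vapply(days, function(d) sum(depart_day == d, na.rm = TRUE),
                        integer(1))
  )
}

#' Census accounting identity
#'
#' The census `k` days ahead equals the current census plus all interim
#' arrivals minus all interim departures:
#' \deqn{C(t+k) = C(t) + \sum_{i=1}^{k} A(t+i) - \sum_{i=1}^{k} D(t+i).}
#'
#' @param c_t current census count \eqn{C(t)}.
#' @param arrivals vector of arrival counts on days `t+1 ... t+k` (may be
#'   empty for `k = 0`).
#' @param cum_departures total departures over days `t+1 ... t+k`.
#' @return the implied census count at `t + k`.
#' @export
census_identity <- function(c_t, arrivals = integer(), cum_departures = 0) {
  stopifnot(c_t >= 0, cum_departures >= 0, all(arrivals >= 0))
  if (cum_departures > c_t + sum(arrivals)) {
    stop("more departures (", cum_departures, ") than patients ever present (",
         c_t + sum(arrivals), ")", call. = FALSE)
  }
  as.integer(c_t + sum(arrivals) - cum_departures)
}

#' Censor patient records at a cutoff day
#'
#' Restricts a patient table to the information determinable by end of
#' `cutoff_day`: patients admitted after the cutoff are dropped, and patients
#' still present at the cutoff become censored with bound `cutoff_day -
#' admit_day` (LOS is known only once the first absent day has been observed).
#' Time-varying scores not yet collected by the cutoff are masked.
#'
#' @inheritParams patient-records
#' @param cutoff_day last calendar day whose information is available.
#' @return a patient tibble as observable at `cutoff_day`.
#' @export
censor_at <- function(patients, cutoff_day) {
  patients <- validate_patients(patients)
  patients <- patients[patients$admit_day <= cutoff_day, , drop = FALSE]
  known <- !patients$censored &
    (patients$admit_day + patients$los - 1) < cutoff_day
  bound <- pmin(ifelse(patients$censored, patients$los, Inf),
                cutoff_day - patients$admit_day)
  patients$los <- ifelse(known, patients$los, as.integer(bound))
  patients$censored <- !known
  # mask scores whose collection day falls after the cutoff
  for (sc in names(SCORE_DAYS)) {
    d <- SCORE_DAYS[[sc]]
    reached <- ifelse(patients$censored, patients$los >= d, patients$los > d)
    patients[[sc]][!reached] <- NA
  }
  patients
}
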