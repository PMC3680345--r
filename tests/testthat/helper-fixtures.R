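# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk.

make_patient <- function(patient_id = "P1", admit_day = 1, los = 5,
                         censored = FALSE, bweight = 2400, gestage = 35,
                         snapdol1 = NA, main1 = NA, snapdol3 = NA, main7 = NA) {
  # fill time-varying scores the stay actually revealed, unless overridden
  reached <- function(d) if (censored) los >= d else los > d
  if (is.na(snapdol1) && reached(1)) snapdol1 <- 5
  if (is.na(main1) && reached(1)) main1 <- 400
  if (is.na(snapdol3) && reached(3)) snapdol3 <- 3
  if (is.na(main7) && reached(7)) main7 <- 500
  tibble::tibble(patient_id = patient_id, admit_day = as.integer(admit_day),
                 los = as.integer(los), censored = censored,
                 bweight = bweight, gestage = gestage, snapdol1 = snapdol1,
                 main1 = main1, snapdol3 = snapdol3, main7 = main7)
}

make_patients <- function(admit_days, los, censored = FALSE,
                          bweight = 2400, gestage = 35) {
  n <- max(length(admit_days), length(los))
  purrr::pmap_dfr(
    list(sprintf("P%03d", seq_len(n)), rep_len(admit_days, n),
         rep_len(los, n), rep_len(censored, n),
         rep_len(bweight, n), rep_len(gestage, n)),
    function(id, a, l, cen, bw, ga) make_patient(id, a, l, cen, bw, ga)
  )
}

# One moderately sized synthetic history, computed once per test run and
# shared across test files (read-only).
shared_history <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_unit_history(n_days = 400, seed = 4242)
    cache
  }
})

# A small fitted model pair on the shared history, cutoff day 320.
shared_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      h <- shared_history()
      train_a <- h$arrivals$arrivals[1:320]
      par_fit <- fit_par(train_a, order = 1,
                         harmonic = harmonic_spec(3 * 320 / 400, 320))
      dep <- fit_departures(h$patients, horizons = 1:7, cutoff_day = 320)
      cache <<- list(history = h, cutoff = 320, par_fit = par_fit, dep = dep,
                     train_a = train_a,
                     state = census_state(censor_at(h$patients, 320), 320),
                     train_pat = censor_at(h$patients, 320))
    }
    cache
  }
})
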