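test_that("departure labels follow the LOS <= k+s coding with undefined at LOS <= s", {
  expect_equal(departure_label(3, FALSE, k = 1, s = 2), 1L)
  expect_equal(departure_label(3, FALSE, k = 2, s = 3), NA_integer_)
  expect_equal(departure_label(5, FALSE, k = 1, s = 0), 0L)
  # censored at 6: LOS > 6 >= k+s = 5, so determinably 0
  expect_equal(departure_label(6, TRUE, k = 2, s = 3), 0L)
  # censored at 4 < k+s: indeterminable
  expect_equal(departure_label(4, TRUE, k = 2, s = 3), NA_integer_)
})

test_that("labels are monotone in horizon where defined", {
  set.seed(21)
  for (i in 1:200) {
    los <- sample(1:15, 1)
    s <- sample(0:10, 1)
    y <- departure_label(rep(los, 8), FALSE, k = 1, s = s)
    labs <- vapply(1:8, function(k) departure_label(los, FALSE, k, s), integer(1))
    defined <- !is.na(labs)
    if (any(defined & labs == 1)) {
      k1 <- min(which(labs == 1))
      expect_true(all(labs[defined & seq_along(labs) > k1] == 1))
    }
  }
})

test_that("training tables enumerate exactly the determinable (patient, s) pairs", {
  # one patient, LOS 2: at risk at s = 0 and 1; k=1, stratum 0 -> one row, y = 0
  p <- make_patient(los = 2, admit_day = 1)
  tab <- departure_training_table(p, k = 1, stratum = 0, cutoff_day = 50)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$y, 0L)
  # pooled stratum: LOS 12, R = 10 -> s = 10, 11 defined; s = 12 undefined
  p2 <- make_patient(los = 12, admit_day = 1)
  tab2 <- departure_training_table(p2, k = 1, stratum = 10, cutoff_day = 50)
  expect_equal(sort(tab2$s), c(10L, 11L))
  # cutoff before any outcome is known -> no rows
  p3 <- make_patient(los = 12, admit_day = 1)
  tab3 <- departure_training_table(p3, k = 3, stratum = 0, cutoff_day = 2)
  expect_equal(nrow(tab3), 0)
})

test_that("covariate sets grow with day of stay per the availability narrative", {
  expect_equal(covariate_set(0), c("bweight", "gestage"))
  expect_setequal(covariate_set(1), c("bweight", "gestage", "snapdol1", "main1"))
  expect_true("snapdol3" %in% covariate_set(3) && !"snapdol3" %in% covariate_set(2))
  expect_true("main7" %in% covariate_set(7) && !"main7" %in% covariate_set(6))
  expect_equal(stratum_of(c(0, 5, 9, 10, 40)), c(0L, 5L, 9L, 10L, 10L))
})

test_that("unpenalized logistic fits match an independent oracle; penalty default is negligible", {
  h <- shared_history()
  fit0 <- fit_departures(h$patients, horizons = 3, cutoff_day = 350,
                         penalty = 0)
  blk <- fit0$blocks[["k3.s0"]]
  expect_equal(blk$fallback, "none")
  tab <- departure_training_table(h$patients, k = 3, stratum = 0,
                                  cutoff_day = 350)
  g <- stats::glm(y ~ bweight + gestage, family = binomial(), data = tab)
  expect_equal(unname(blk$coef), unname(coef(g)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(blk$vcov))),
               unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-4)
})

test_that("degenerate strata engage the documented fallback chain", {
  # a cohort where every label is 1 in stratum 0 at k = 30 (everyone leaves)
  p <- make_patients(admit_days = 1:40, los = rep(2:3, 20))
  m <- fit_departures(p, horizons = 30, cutoff_day = 200)
  blk <- m$blocks[["k30.s0"]]
  expect_true(blk$fallback %in% c("pooled_adjacent", "intercept_only"))
  # intercept-only rate is clamped into (0, 1)
  io <- m$blocks[["k30.s10"]]  # far stratum: no rows at all
  expect_equal(io$fallback, "intercept_only")
  pr <- departure_prob(m, c(bweight = 2000, gestage = 30, snapdol1 = 1,
                            main1 = 100, snapdol3 = 1, main7 = 100),
                       k = 30, stratum = 10)
  expect_true(pr > 0 && pr < 1)
})

test_that("departure_prob is the inverse logit with its symmetry", {
  h <- shared_fits()
  m <- h$dep
  blk <- m$blocks[["k1.s0"]]
  z <- c(bweight = 2400, gestage = 34)
  lp <- unname(blk$coef[1] + sum(blk$coef[-1] * z))
  expect_equal(departure_prob(m, z, k = 1, stratum = 0),
               exp(lp) / (1 + exp(lp)), tolerance = 1e-12)
  # beta = 0 -> 0.5; z*beta = log 3 -> 0.75; symmetry
  expect_equal(departure_prob(m, z, k = 1, stratum = 0,
                              coef = c(0, 0, 0)), 0.5)
  expect_equal(departure_prob(m, c(bweight = 1, gestage = 0), k = 1,
                              stratum = 0, coef = c(0, log(3), 0)), 0.75)
  p1 <- departure_prob(m, z, k = 1, stratum = 0, coef = c(0.3, 1e-4, -0.02))
  p2 <- departure_prob(m, z, k = 1, stratum = 0, coef = -c(0.3, 1e-4, -0.02))
  expect_equal(p1 + p2, 1, tolerance = 1e-12)
  expect_error(departure_prob(m, c(bweight = 1), k = 1, stratum = 0), "gestage")
})

test_that("census departure draws respect the at-risk bound and expectation", {
  fits <- shared_fits()
  st <- fits$state
  # forced certainty: intercept-only huge coefficients per needed block
  force_coef <- lapply(fits$dep$blocks, function(b) {
    c(50, rep(0, length(b$coef) - 1))
  })
  set.seed(5)
  d <- sample_departures(st, fits$dep, k = 1, coef_draws = force_coef)
  expect_equal(d$total, st$census_count)
  # empty census
  gap <- make_patients(admit_days = c(1, 10), los = c(1, 2))
  st0 <- census_state(gap, 5)
  expect_equal(sample_departures(st0, fits$dep, k = 1)$total, 0L)
  # expectation oracle on a fixed 5-patient census
  p5 <- make_patients(admit_days = rep(1, 5), los = rep(9, 5),
                      bweight = c(1500, 2000, 2500, 3000, 3500),
                      gestage = c(30, 32, 34, 36, 38))
  st5 <- census_state(censor_at(p5, 3), 3)
  expect_equal(unique(st5$present$s), 2L)
  pi_hat <- departure_prob(fits$dep, st5$present, k = 2, stratum = 2)
  set.seed(6)
  tot <- vapply(1:10000, function(i) {
    sample_departures(st5, fits$dep, k = 2)$total
  }, integer(1))
  expect_lt(abs(mean(tot) - sum(pi_hat)),
            4 * sqrt(sum(pi_hat * (1 - pi_hat)) / 10000) + 1e-6)
  expect_true(all(tot <= st5$census_count))
})

test_that("pseudo-subject resampling preserves the joint baseline pool", {
  pool <- make_patients(admit_days = 1:3, los = 5,
                        bweight = c(1000, 2000, 3000), gestage = c(28, 33, 38))
  expect_equal(nrow(sample_pseudo_subjects(pool, 0)), 0)
  one <- pool[2, ]
  expect_equal(unique(sample_pseudo_subjects(one, 5)$bweight), 2000)
  expect_error(sample_pseudo_subjects(pool[0, ], 2), "empty")
  # joint resampling: every (bweight, gestage) pair exists in the pool
  set.seed(8)
  ps <- sample_pseudo_subjects(pool, 500)
  pairs <- paste(ps$bweight, ps$gestage)
  expect_true(all(pairs %in% paste(pool$bweight, pool$gestage)))
  expect_lt(abs(mean(ps$bweight) - 2000), 4 * stats::sd(pool$bweight) / sqrt(500))
})

test_that("fitted one-day departure probabilities track the generator's true hazard", {
  # hazard depending only on always-available baseline covariates: the k = 1
  # stratum model is exactly the true discrete hazard at day s + 1
  cfg <- unit_sim_config(hazard_coefs = c(bweight_kg = 0.30, gestage = 0.08,
                                          snapdol1 = 0, main1 = 0,
                                          snapdol3 = 0, main7 = 0))
  h <- simulate_unit_history(n_days = 2500, config = cfg, seed = 99)
  m <- fit_departures(h$patients, horizons = 1, cutoff_day = 2450)
  z <- c(bweight = 2418, gestage = 34.6)
  for (s in c(0, 2, 5)) {
    truth <- true_departure_prob(cfg, c(z, snapdol1 = 0, main1 = 0,
                                        snapdol3 = 0, main7 = 0), k = 1, s = s)
    est <- departure_prob(m, c(z, snapdol1 = 0, main1 = 0, snapdol3 = 0,
                               main7 = 0), k = 1, stratum = s)
    expect_lt(abs(est - truth), 0.035)
  }
})
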