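test_that("the staying-probability transform gives the tabulated durations", {
  expect_equal(round(sod_from_phi(0.7), 2), 2.80)
  expect_equal(round(sod_from_phi(0.96), 2), 24.50)
  expect_equal(sod_from_phi(exp(-1)), 1)
  expect_error(sod_from_phi(0), "undefined")
  expect_error(sod_from_phi(1), "undefined")
  # strictly increasing in phi, and an exact inverse relation
  phis <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(sod_from_phi(phis)) > 0))
  expect_equal(sod_from_phi(phis) * log(phis), rep(-1, length(phis)),
               tolerance = 1e-12)
})

test_that("arrival day-50 follows the cumulative-entry rule", {
  expect_identical(arrival_day50(rep(1 / 15, 15)), 8L)
  expect_identical(arrival_day50(c(1, rep(0, 9))), 1L)
  expect_identical(arrival_day50(c(0.49, 0.01, 0.5, rep(0, 4) / 4)), 3L)
  # invariant to appending zero-probability occasions
  b <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  expect_identical(arrival_day50(c(b, 0, 0)), arrival_day50(b))
  # matrix input: one value per draw
  m <- rbind(rep(1 / 15, 15), c(0.6, rep(0.4 / 14, 14)))
  expect_identical(arrival_day50(m), c(8L, 1L))
  expect_error(arrival_day50(c(0.3, 0.3)), "sum to 1")
})

test_that("minimal stopover uses the documented inclusive convention", {
  y <- matrix(0L, 2, 10)
  y[1, c(3, 7)] <- 1L
  y[2, 5] <- 1L
  eh <- encounter_histories(y)
  ms <- minimal_sod(eh)
  expect_equal(unname(ms$per_individual), c(5, 1))
  expect_equal(ms$mean, 3)
  expect_equal(unname(minimal_sod(eh, inclusive = FALSE)$per_individual),
               c(4, 0))
})

test_that("imperfect detection makes minimal stopover an underestimate", {
  sim <- simulate_histories(make_scenario(2, seed = 23))
  realized_obs <- mean(sim$truth$realized_sod[sim$truth$observed])
  expect_lt(minimal_sod(sim$histories)$mean, realized_obs)
})

test_that("summaries collect the derived quantities from both engines", {
  sim <- simulate_histories(make_scenario(1, seed = 15))
  fit <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1)
  sm <- stopover_summary(fit)
  expect_s3_class(sm, "stopover_summary")
  expect_true(all(c("M_star", "arrival_day50", "sod_from_phi",
                    "minimal_sod_mean") %in% sm$quantity))
  expect_equal(sm$estimate[sm$quantity == "M_star"], fit$N_hat)

  eh <- encounter_histories(sim$histories$y[1:60, ])
  scans <- simulate_scans(sim$truth, seed = 2)
  dr <- run_mcmc(augment(eh), "bt_phih_p.+h", n_iter = 1500, n_burn = 500,
                 seed = 3, scans = scans)
  sb <- stopover_summary(dr)
  expect_true(all(c("M_star", "mean_sod_realized", "mean_sod_from_phi",
                    "arrival_day50", "pi_hat", "N_star") %in% sb$quantity))
  # mean realized stopover of included birds is never below one day and
  # not below the minimal stopover of the observed histories
  expect_gte(sb$estimate[sb$quantity == "mean_sod_realized"], 1)
  expect_gte(sb$estimate[sb$quantity == "mean_sod_realized"],
             minimal_sod(eh)$mean)
  # N* draws equal M*/pi exactly, draw by draw
  expect_equal(dr$Nstar, dr$Mstar / dr$pi)
})
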