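test_that("degenerate scenarios force their trivial outcomes", {
  # depart immediately + perfect detection: everyone observed exactly once,
  # on the arrival day
  scn <- mixture_scenario(200, 10, omega = c(0.5, 0.5),
                          phi_by_class = c(0, 0), p_by_class = c(1, 1),
                          seed = 4)
  sim <- simulate_histories(scn)
  expect_true(all(sim$truth$observed))
  expect_true(all(rowSums(sim$histories$y) == 1L))
  expect_equal(unname(apply(sim$histories$y, 1L, function(r) which(r == 1L))),
               unname(sim$truth$arrival_day))
  expect_true(all(sim$truth$realized_sod == 1L))

  # degenerate categorical: omega = (1, 0) puts everyone in class 1
  scn2 <- mixture_scenario(300, 8, omega = c(1, 0), phi_by_class = c(0.6, 0.9),
                           p_by_class = c(0.4, 0.9), seed = 5)
  expect_true(all(simulate_histories(scn2)$truth$class_of == 1L))
})

test_that("detections imply presence and presence rows are contiguous", {
  for (sid in c(1, 5, 9)) {
    sim <- simulate_histories(make_scenario(sid, seed = 100 + sid))
    z <- sim$truth$presence
    yfull <- matrix(0L, nrow(z), ncol(z))
    yfull[sim$truth$observed, ] <- sim$histories$y
    expect_true(all(z[yfull == 1L] == 1L))
    runs <- apply(z, 1L, function(r) sum(diff(c(0L, r, 0L)) == 1L))
    expect_true(all(runs == 1L))   # arrive once, depart once, no re-entry
    expect_equal(rowSums(z), as.numeric(sim$truth$realized_sod))
    expect_true(all(z[cbind(seq_len(nrow(z)), sim$truth$arrival_day)] == 1L))
  }
})

test_that("class frequencies and arrival timing match the generative truth", {
  scn <- mixture_scenario(100000, 15, omega = c(0.2, 0.8),
                          phi_by_class = c(0.7, 0.7),
                          p_by_class = c(0.8, 0.2), seed = 77)
  sim <- simulate_histories(scn)
  # empirical class-1 share within 3 binomial SE of Omega
  se <- sqrt(0.2 * 0.8 / scn$n_individuals)
  expect_lt(abs(mean(sim$truth$class_of == 1L) - 0.2), 3 * se)
  # uniform entry over 15 occasions: median arrival day is 8
  expect_identical(median(sim$truth$arrival_day), 8)
  # realized stopover matches the exact truncated-geometric expectation
  exact <- brute_expected_sod(scn$omega, scn$phi_by_class, scn$entry_probs)
  mc_se <- sd(sim$truth$realized_sod) / sqrt(scn$n_individuals)
  expect_lt(abs(mean(sim$truth$realized_sod) - exact), 3 * mc_se)
})

test_that("seeded simulation is bit-reproducible", {
  a <- simulate_histories(make_scenario(2), seed = 123)
  b <- simulate_histories(make_scenario(2), seed = 123)
  expect_identical(a$histories$y, b$histories$y)
  expect_identical(a$truth$presence, b$truth$presence)
  s1 <- simulate_scans(a$truth, seed = 9)
  s2 <- simulate_scans(b$truth, seed = 9)
  expect_identical(s1, s2)
})

test_that("scan generator respects its marked-fraction construction", {
  sim <- simulate_histories(make_scenario(1), seed = 31)
  # multiplier 0: everyone in the flock is marked, so m_s = N_s
  s0 <- simulate_scans(sim$truth, n_unmarked_multiplier = 0, seed = 1)
  expect_equal(s0$n_marked, s0$n_scanned)
  # long-run marked fraction 1/200 under multiplier 199
  big <- mixture_scenario(20000, 15, omega = 1, phi_by_class = 0.7,
                          p_by_class = 0.5, seed = 8)
  bt <- simulate_histories(big)$truth
  sc <- simulate_scans(bt, n_unmarked_multiplier = 199, scan_fraction = 0.5,
                       seed = 2)
  expect_lt(abs(sum(sc$n_marked) / sum(sc$n_scanned) - 1 / 200), 5e-4)
  expect_true(all(sc$n_marked <= sc$n_scanned))
  # bad inputs
  expect_error(simulate_scans(bt, scan_fraction = 0), "scan_fraction")
  expect_error(simulate_scans(bt, n_unmarked_multiplier = -1), "multiplier")
})
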