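test_that("augmentation builds the padded state the model expects", {
  sim <- simulate_histories(mixture_scenario(120, 6, omega = 1,
    phi_by_class = 0.6, p_by_class = 0.7, seed = 10))
  n <- nrow(sim$histories$y)
  aug <- augment(sim$histories, factor = 3)
  expect_identical(aug$A, as.integer(ceiling(3 * n)))
  expect_identical(aug$n_obs, n)
  pseudo <- aug$y[(n + 1):aug$A, , drop = FALSE]
  expect_true(all(pseudo == 0L))
  expect_identical(aug$w, c(rep(1L, n), rep(0L, aug$A - n)))
  # initial presence spans first to last detection
  i <- which(rowSums(sim$histories$y) >= 2L)[1L]
  dets <- which(sim$histories$y[i, ] == 1L)
  expect_true(all(aug$z[i, dets[1L]:dets[length(dets)]] == 1L))
  expect_error(augment(sim$histories, factor = 1), "exceed 1")
  expect_error(augment(sim$histories, factor = 0.5), "exceed 1")
})

test_that("per-draw invariants hold: M* accounting and presence windows", {
  sim <- simulate_histories(make_scenario(1, seed = 19))
  eh <- encounter_histories(sim$histories$y[1:80, ])
  aug <- augment(eh)
  dr <- run_mcmc(aug, "bt_phih_p.+h", n_iter = 1200, n_burn = 300, seed = 8,
                 store_latent = TRUE)
  # M* = sum of inclusion indicators, bounded by n_obs and A
  expect_identical(unname(rowSums(dr$w)), as.numeric(dr$Mstar))
  expect_true(all(dr$Mstar >= aug$n_obs & dr$Mstar <= aug$A))
  # observed rows stay included with windows covering their detections
  f <- apply(eh$y, 1L, function(r) which(r == 1L)[1L])
  l <- apply(eh$y, 1L, function(r) max(which(r == 1L)))
  obs <- seq_len(aug$n_obs)
  expect_true(all(dr$w[, obs] == 1L))
  expect_true(all(t(dr$entry[, obs]) <= f))
  expect_true(all(t(dr$depart[, obs]) >= l))
  # derived stopover reproduces the stored summaries
  ds <- derived_stopover(dr)
  expect_equal(ds$Sbar, dr$Sbar)
  expect_true(all(ds$S[dr$w == 0L] == 0))
})

test_that("derived stopover follows the inclusion-weighted definition", {
  # three draws over A = 3, K = 15: w gates S_i; empty draws are missing
  draws <- list(
    w = rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L)),
    entry = rbind(c(4L, NA, NA), c(4L, 1L, NA), c(NA, NA, NA)),
    depart = rbind(c(9L, NA, NA), c(9L, 1L, NA), c(NA, NA, NA)))
  ds <- derived_stopover(draws)
  expect_equal(ds$S[1L, ], c(6, 0, 0))
  expect_equal(ds$Sbar, c(6, 3.5, NA))
  expect_error(derived_stopover(list(Mstar = 1)), "store_latent")
})

test_that("complete detection concentrates M* at the observed count", {
  y <- matrix(1L, 25, 5)
  dr <- run_mcmc(augment(encounter_histories(y)), "bt_phi._p.",
                 n_iter = 3000, n_burn = 500, seed = 12)
  expect_gt(mean(dr$Mstar == 25), 0.9)
  expect_gt(mean(dr$Sbar), 4.7)   # everyone present essentially all K days
})

test_that("MCMC matches the exact enumerated posterior on tiny instances", {
  eh <- encounter_histories(matrix(c(0L, 1L, 0L,
                                     1L, 1L, 0L), 2, 3, byrow = TRUE))
  aug <- augment(eh, factor = 3)  # A = 6
  for (st in c("bt_phi._p.", "bt_phih_p.+h")) {
    exact <- exact_mstar_posterior(aug, st)
    dr <- run_mcmc(aug, st, n_iter = 60000, n_burn = 10000, n_chains = 2,
                   seed = 99)
    emp <- tabulate(dr$Mstar - 1L, nbins = 5)[1:5] / length(dr$Mstar)
    tv <- 0.5 * sum(abs(exact - emp))
    expect_lt(tv, 0.02)
  }
})

test_that("fixing the class weights reproduces the no-mixture posterior", {
  sim <- simulate_histories(make_scenario(1, seed = 3))
  eh <- encounter_histories(sim$histories$y[1:60, ])
  aug <- augment(eh)
  d1 <- run_mcmc(aug, "bt_phi._p.", n_iter = 6000, n_burn = 1500, seed = 5)
  d2 <- run_mcmc(aug, "bt_phih_p.+h", n_iter = 6000, n_burn = 1500, seed = 5,
                 fix_omega = c(1, 0))
  # class-1 marginals coincide within Monte Carlo error
  expect_lt(abs(mean(d1$phi[, 1]) - mean(d2$phi[, 1])), 0.02)
  expect_lt(abs(mean(d1$p[, 1:15]) - mean(d2$p[, 1:15])), 0.02)
  expect_lt(abs(mean(d1$Mstar) - mean(d2$Mstar)) / mean(d1$Mstar), 0.05)
  expect_lt(abs(sd(d1$Mstar) - sd(d2$Mstar)) / sd(d1$Mstar), 0.25)
})

test_that("posterior draws flatten to a tidy long table", {
  sim <- simulate_histories(make_scenario(2, seed = 2))
  eh <- encounter_histories(sim$histories$y[1:40, ])
  dr <- run_mcmc(augment(eh), "bt_phi._pt", n_iter = 800, n_burn = 200,
                 seed = 1)
  long <- posterior_long(dr)
  expect_setequal(names(long), c("chain", "iter", "parameter", "value"))
  expect_true(all(c("psi", "Mstar", "Sbar", "beta1", "beta15",
                    "arrival_day50") %in% long$parameter))
  n_keep <- sum(dr$chain == 1L)
  expect_identical(nrow(long[long$parameter == "psi", ]), 2L * n_keep)
})
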