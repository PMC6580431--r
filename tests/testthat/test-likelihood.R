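test_that("history probabilities equal brute-force path enumeration", {
  K <- 3L
  ah <- all_histories(K)
  nz <- ah[rowSums(ah) > 0, , drop = FALSE]
  cases <- list(
    list(structure = "b._phi._p.", beta = rep(1 / 3, 3),
         params = list(phi = 0.6, p = 0.35),
         bphi = 0.6, bp = 0.35, bomega = 1),
    list(structure = "bt_phi._p.", beta = c(0.5, 0.3, 0.2),
         params = list(beta = c(0.5, 0.3, 0.2), phi = 0.8, p = 0.2),
         bphi = 0.8, bp = 0.2, bomega = 1),
    list(structure = "bt_phih_p.+h", beta = c(0.2, 0.5, 0.3),
         params = list(beta = c(0.2, 0.5, 0.3), phi = c(0.9, 0.4),
                       p = 0.15, p_delta = 2.2, omega = c(0.3, 0.7)),
         bphi = c(0.9, 0.4),
         bp = plogis(qlogis(0.15) + c(0, 2.2)), bomega = c(0.3, 0.7)),
    list(structure = "bt_phit_pt", beta = c(0.1, 0.6, 0.3),
         params = list(beta = c(0.1, 0.6, 0.3), phi = c(0.7, 0.3),
                       p = c(0.2, 0.5, 0.8)),
         bphi = matrix(c(0.7, 0.3), 1), bp = matrix(c(0.2, 0.5, 0.8), 1),
         bomega = 1))
  for (cs in cases) {
    got <- history_probs(cs$params, nz, cs$structure)
    want <- apply(nz, 1L, brute_history_prob, beta = cs$beta, phi = cs$bphi,
                  p = cs$bp, omega = cs$bomega)
    expect_equal(got$probs, want, tolerance = 1e-10, info = cs$structure)
    # probability conservation over the full outcome space
    expect_equal(sum(want) + got$p0, 1, tolerance = 1e-10,
                 info = cs$structure)
    expect_equal(got$p0,
                 brute_history_prob(rep(0L, K), cs$beta, cs$bphi, cs$bp,
                                    cs$bomega),
                 tolerance = 1e-12)
  }
})

test_that("conditional log-likelihood matches the normalized oracle", {
  eh <- tiny_histories()
  params <- list(beta = c(0.5, 0.3, 0.2), phi = 0.7, p = 0.4)
  probs <- apply(eh$y, 1L, brute_history_prob, beta = params$beta, phi = 0.7,
                 p = 0.4)
  p0 <- brute_history_prob(c(0L, 0L, 0L), params$beta, 0.7, 0.4)
  expect_equal(mixture_loglik(params, eh, "bt_phi._p."),
               sum(log(probs / (1 - p0))), tolerance = 1e-10)
})

test_that("degenerate mixture weights collapse onto one class", {
  eh <- tiny_histories()
  one <- mixture_loglik(list(beta = c(0.2, 0.5, 0.3), phi = 0.75, p = 0.3),
                        eh, "bt_phi._p.")
  mix <- mixture_loglik(list(beta = c(0.2, 0.5, 0.3), phi = c(0.75, 0.1),
                             p = 0.3, p_delta = 0, omega = c(1, 0)),
                        eh, "bt_phih_p.+h")
  expect_equal(mix, one, tolerance = 1e-12)
})

test_that("edge cases follow the likelihood contract", {
  # empty dataset: log-likelihood 0
  empty <- matrix(integer(0), 0, 4)
  expect_identical(mixture_loglik(list(phi = 0.5, p = 0.5), empty,
                                  "b._phi._p."), 0)
  # p = 0 on a detection day makes the history impossible: -Inf, no error
  y <- matrix(c(0L, 1L, 0L), 1)
  expect_identical(mixture_loglik(list(phi = 0.5, p = 0), y, "b._phi._p."),
                   -Inf)
  # boundary p = 1 with a miss inside the span is impossible too
  y2 <- matrix(c(1L, 0L, 1L), 1)
  expect_identical(mixture_loglik(list(phi = 1, p = 1), y2, "b._phi._p."),
                   -Inf)
  # but a solid span under p = 1, phi = 1 is certain given entry at day 1
  y3 <- matrix(c(1L, 1L, 1L), 1)
  ll <- mixture_loglik(list(beta = c(1, 0, 0), phi = 1, p = 1), y3,
                       "bt_phi._p.")
  expect_equal(ll, 0, tolerance = 1e-12)
})

test_that("likelihood is invariant to row order of the data", {
  sim <- simulate_histories(make_scenario(2, seed = 17))
  y <- sim$histories$y
  params <- list(beta = rep(1 / 15, 15), phi = 0.65, p = 0.45)
  ll1 <- mixture_loglik(params, y, "bt_phi._p.")
  ll2 <- mixture_loglik(params, y[sample.int(nrow(y)), ], "bt_phi._p.")
  expect_equal(ll1, ll2, tolerance = 1e-10)
})
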