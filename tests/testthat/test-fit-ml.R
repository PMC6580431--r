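test_that("complete detection pins the superpopulation at the observed count", {
  scn <- mixture_scenario(150, 8, omega = 1, phi_by_class = 0, p_by_class = 1,
                          seed = 21)
  sim <- simulate_histories(scn)
  fit <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 2, compute_se = FALSE)
  expect_lt(abs(fit$N_hat - nrow(sim$histories$y)), 0.5)
  expect_gt(fit$estimates$p[1, 1], 0.99)
})

test_that("AICc matches its closed form and the fit records it", {
  expect_equal(aicc(-100, 5, 50), 200 + 10 + 2 * 5 * 6 / 44)
  expect_identical(aicc(-100, 49, 50), Inf)
  sim <- simulate_histories(make_scenario(2, seed = 6))
  fit <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1, compute_se = FALSE)
  expect_equal(fit$aicc, aicc(fit$loglik, fit$n_params, fit$n_obs))
  expect_identical(fit$n_params,
                   stopmix:::n_free_params("bt_phi._p.", 15L) + 1L)
  # estimated entry distribution is a distribution
  expect_equal(sum(fit$estimates$beta), 1, tolerance = 1e-8)
  expect_true(all(fit$estimates$beta >= 0))
})

test_that("no-mixture fit is invariant to row permutation", {
  sim <- simulate_histories(make_scenario(4, seed = 13))
  f1 <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1, compute_se = FALSE)
  perm <- sim$histories
  ord <- rev(seq_len(nrow(perm$y)))
  perm$y <- perm$y[ord, ]
  perm$id <- perm$id[ord]
  f2 <- fit_ml(perm, "bt_phi._p.", n_starts = 1, compute_se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$N_hat, f2$N_hat, tolerance = 1e-4)
})

test_that("a two-class model with identical classes matches the single class", {
  sim <- simulate_histories(make_scenario(2, seed = 41))
  fit1 <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1,
                 compute_se = FALSE)
  est <- fit1$estimates
  ll_mix <- mixture_loglik(list(beta = est$beta, phi = est$phi[1, 1],
                                p = est$p[1, 1], p_delta = 0,
                                omega = c(0.5, 0.5)),
                           sim$histories, "bt_phih_p.+h")
  expect_equal(ll_mix, fit1$loglik, tolerance = 1e-8)
  # the mixture's maximized likelihood can only improve on the nested model
  fit2 <- fit_ml(sim$histories, "bt_phih_p.+h", n_starts = 3, seed = 2,
                 compute_se = FALSE)
  expect_gte(fit2$loglik, fit1$loglik - 1e-4)
})

test_that("correctly specified fits recover the truth on large samples", {
  scn <- mixture_scenario(8000, 15, omega = 1, phi_by_class = 0.7,
                          p_by_class = 0.5, seed = 3)
  sim <- simulate_histories(scn)
  fit <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1)
  expect_lt(abs(fit$estimates$phi[1, 1] - 0.7), 0.015)
  expect_lt(abs(fit$estimates$p[1, 1] - 0.5), 0.015)
  expect_lt(abs(fit$N_hat - 8000) / 8000, 0.02)
  expect_lt(abs(fit$N_hat - 8000), 3 * fit$N_se)
  expect_true(fit$converged)
})

test_that("model selection applies the parsimony-within-window rule", {
  fake <- function(aicc, k, string) {
    structure(list(aicc = aicc, n_params = k, converged = TRUE,
                   structure = model_structure(string)),
              class = "ml_fit")
  }
  f1 <- fake(100.0, 40L, "bt_phih_pt")
  f2 <- fake(100.5, 38L, "bt_phi._pt")
  f3 <- fake(103.0, 37L, "bt_phi._p.")
  expect_identical(select_model(list(f1, f2, f3))$n_params, 38L)
  # single fit returns itself
  expect_identical(select_model(list(f1))$aicc, 100.0)
  # equal AICc and parameters: deterministic structure-string tie-break
  g1 <- fake(50, 10L, "bt_phih_pt")
  g2 <- fake(50, 10L, "bt_phi._pt")
  expect_identical(select_model(list(g1, g2))$structure$string, "bt_phi._pt")
  expect_identical(select_model(list(g2, g1))$structure$string, "bt_phi._pt")
  # non-converged fits are not eligible
  f1$converged <- FALSE; f2$converged <- FALSE; f3$converged <- FALSE
  expect_error(select_model(list(f1, f2, f3)), "no converged fits")
})
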