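test_that("the ten benchmark scenarios carry their tabulated parameterizations", {
  s1 <- make_scenario(1)
  expect_equal(s1$omega, c(0.2, 0.8))
  expect_equal(s1$p_by_class, c(0.8, 0.2))
  expect_equal(s1$phi_by_class, c(0.7, 0.7))
  expect_identical(s1$n_individuals, 500L)
  expect_identical(s1$n_occasions, 15L)
  expect_equal(s1$entry_probs, rep(1 / 15, 15))

  s3 <- make_scenario(3)
  expect_equal(s3$phi_by_class, c(0.9, 0.5))
  expect_equal(s3$p_by_class, c(0.5, 0.5))

  s9 <- make_scenario(9)
  expect_equal(s9$omega, c(0.36, 0.64))
  expect_equal(s9$phi_by_class, c(0.96, 0.96))
  expect_equal(s9$p_by_class, c(0.4, 0.15))

  expect_error(make_scenario(11), "unknown scenario")
  expect_error(make_scenario(0), "unknown scenario")
})

test_that("scenario invariants are enforced", {
  expect_error(mixture_scenario(10, 5, omega = c(0.3, 0.6), phi_by_class =
    c(0.5, 0.5), p_by_class = c(0.5, 0.5)), "sum to 1")
  expect_error(mixture_scenario(10, 5, omega = c(0.5, 0.5), phi_by_class =
    c(0.5, 1.2), p_by_class = c(0.5, 0.5)), "probabilities")
  expect_error(mixture_scenario(10, 5, omega = c(0.5, 0.5), phi_by_class =
    c(0.5, 0.5), p_by_class = 0.5), "equal lengths")
  expect_error(mixture_scenario(10, 5, omega = 1, phi_by_class = 0.5,
    p_by_class = 0.5, entry_probs = c(0.5, 0.5)), "length")
})

test_that("population-level aggregates behave", {
  # single class: aggregate phi is the class phi, reference day-50 is 8
  scn <- mixture_scenario(500, 15, omega = 1, phi_by_class = 0.7,
                          p_by_class = 0.5)
  expect_equal(aggregate_phi(scn), 0.7, tolerance = 1e-12)
  expect_equal(scn$reference$arrival_day, 8L)
  expect_equal(scn$reference$sod, -1 / log(0.7))
  # the two-class aggregates agree with the tabulated rounded values
  expect_equal(round(aggregate_phi(make_scenario(3)), 2), 0.66)
  expect_equal(round(aggregate_phi(make_scenario(4)), 2), 0.87)
  expect_equal(aggregate_phi(make_scenario(9)), 0.96, tolerance = 1e-12)
  # expected realized stay matches the brute-force enumeration
  s5 <- make_scenario(5)
  expect_equal(expected_realized_sod(s5),
               brute_expected_sod(s5$omega, s5$phi_by_class, s5$entry_probs),
               tolerance = 1e-12)
})

test_that("scenario YAML files round-trip", {
  scn <- make_scenario(7, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, path)
  back <- read_scenario(path)
  for (f in c("n_individuals", "n_occasions", "omega", "phi_by_class",
              "p_by_class", "entry_probs", "seed", "scenario_id"))
    expect_equal(back[[f]], scn[[f]], info = f)
})
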