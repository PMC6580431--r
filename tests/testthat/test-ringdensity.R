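test_that("without-replacement scans pool per day; others stay separate", {
  scans <- scan_samples(day = c(3, 3, 3, 4, 5, 5),
                        n_scanned = c(200, 300, 150, 400, 100, 120),
                        n_marked = c(1, 2, 3, 2, 1, 0),
                        with_replacement = c(FALSE, FALSE, TRUE, TRUE,
                                             FALSE, FALSE))
  m <- merge_scans(scans)
  d3wo <- m[m$day == 3 & !m$with_replacement, ]
  expect_identical(nrow(d3wo), 1L)
  expect_identical(d3wo$n_scanned, 500L)
  expect_identical(d3wo$n_marked, 3L)
  # the with-replacement record on day 3 survives untouched
  d3wi <- m[m$day == 3 & m$with_replacement, ]
  expect_identical(d3wi$n_scanned, 150L)
  # a day with only a with-replacement scan is unchanged
  expect_identical(m[m$day == 4, ]$n_scanned, 400L)
  # day 5: two without-replacement records collapse
  expect_identical(m[m$day == 5, ]$n_scanned, 220L)
  expect_identical(nrow(m), 4L)
})

test_that("the marked-proportion posterior has its conjugate closed form", {
  s1 <- scan_samples(1, 1000, 0)
  post <- estimate_pi(s1)
  expect_equal(post$mean, 1 / 1002)
  s2 <- scan_samples(1:2, c(6000, 4000), c(30, 20))
  post2 <- estimate_pi(s2)
  expect_equal(post2$mean, 51 / 10002)
  expect_equal(post2$shape1, 51)
  expect_equal(post2$shape2, 9951)
  expect_error(estimate_pi(scan_samples(1, 0, 0)), "no scan data")
})

test_that("pi interval coverage is nominal at realistic mark densities", {
  set.seed(404)
  pi_true <- 0.005
  hits <- replicate(1000, {
    m <- rbinom(1, 1e5, pi_true)
    ci <- qbeta(c(0.025, 0.975), 1 + m, 1 + 1e5 - m)
    ci[1] <= pi_true && pi_true <= ci[2]
  })
  expect_gte(mean(hits), 0.93)
})

test_that("N* is the draw-wise ratio M*/pi", {
  expect_equal(total_population(300, 0.005)$draws, 60000)
  expect_equal(total_population(412, 1)$draws, 412)
  M <- c(300, 310, 290, 305)
  pi <- c(0.005, 0.004, 0.006, 0.005)
  tp <- total_population(M, pi)
  expect_equal(tp$draws, M / pi)           # exact pairing, no resampling
  expect_equal(total_population(M, pi / 2)$draws, 2 * M / pi)
  expect_error(total_population(M, pi[1:2]), "paired")
  expect_warning(out <- total_population(c(10, 20), c(0.1, 0)), "pi = 0")
  expect_identical(out$n_dropped, 1L)
  expect_true(is.na(out$draws[2]))
})

test_that("a lower marked proportion widens the relative interval of N*", {
  relwidth <- function(pi_true) {
    n <- 20000
    m <- round(pi_true * n)
    set.seed(7)
    pis <- rbeta(20000, 1 + m, 1 + n - m)
    ns <- 300 / pis
    diff(quantile(ns, c(0.025, 0.975))) / mean(ns)
  }
  expect_gt(relwidth(0.005), relwidth(0.05))
})
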