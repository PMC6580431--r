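#' Merge same-day scans taken without replacement
#'
#' Scans of distinct parts of the population (sampling without
#' replacement) taken on the same day are additive and are pooled into
#' one large sample per day; with-replacement scans are random samples
#' of the whole population and are kept as separate records.
#'
#' @param scans a [scan_samples()].
#' @return a [scan_samples()] with at most one without-replacement
#'   record per day.
#' @export
merge_scans <- function(scans) {
  stopifnot(inherits(scans, "scan_samples"))
  wo <- scans[!scans$with_replacement, , drop = FALSE]
  wi <- scans[scans$with_replacement, , drop = FALSE]
  if (nrow(wo)) {
    ns <- tapply(wo$n_scanned, wo$day, sum)
    nm <- tapply(wo$n_marked, wo$day, sum)
    wo <- scan_samples(as.integer(names(ns)), as.integer(ns), as.integer(nm),
                       with_replacement = FALSE)
  }
  out <- rbind(wo, wi)
  out <- out[order(out$day, out$with_replacement), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_samples", "data.frame")
  out
}

#' Posterior of the marked proportion from scan samples
#'
#' The number of marked birds in each scan is binomial in the total
#' scanned with a season-constant marked proportion pi, so with a
#' conjugate Beta(a, b) prior the posterior is
#' `Beta(a + sum(m_s), b + sum(N_s - m_s))`.  Same-day with-replacement
#' scans are treated as independent binomial records (under a constant
#' pi the pooled and record-wise likelihoods coincide).
#'
#' @param scans a [scan_samples()].
#' @param prior length-2 vector, the Beta prior shapes (default flat
#'   `c(1, 1)`).
#' @return list with `shape1`, `shape2` (posterior shapes), `mean`,
#'   `ci95`, and the scan totals `n_scanned`, `n_marked`.
#' @export
estimate_pi <- function(scans, prior = c(1, 1)) {
  stopifnot(inherits(scans, "scan_samples"), length(prior) == 2L,
            all(prior > 0))
  Ns <- sum(scans$n_scanned)
  ms <- sum(scans$n_marked)
  if (Ns <= 0)
    stop("no scan data: total population size cannot be estimated")
  shape1 <- prior[1L] + ms
  shape2 <- prior[2L] + Ns - ms
  list(shape1 = shape1, shape2 = shape2,
       mean = shape1 / (shape1 + shape2),
       ci95 = qbeta(c(0.025, 0.975), shape1, shape2),
       n_scanned = Ns, n_marked = ms)
}

#' Total stopover population size from marked birds and mark ratio
#'
#' Scales the marked superpopulation size to the whole population:
#' `N* = M* / pi`, applied element-wise to paired posterior draws so
#' that the uncertainty in both components propagates (draws are never
#' re-paired).  Draws with pi = 0 are excluded and counted.
#'
#' @param M_star_draws draws (or a point estimate) of the marked
#'   superpopulation size.
#' @param pi_draws paired draws (or a point estimate) of the marked
#'   proportion; must have the same length as `M_star_draws`.
#' @return list with `draws` (N* per draw, `NA` where pi = 0), `mean`,
#'   `ci95` and `n_dropped` (zero-pi draws).
#' @export
total_population <- function(M_star_draws, pi_draws) {
  if (length(M_star_draws) != length(pi_draws))
    stop("M* and pi draws must be paired (equal length)")
  bad <- pi_draws == 0
  n_dropped <- sum(bad)
  if (n_dropped > 0)
    warning(n_dropped, " draws with pi = 0 excluded from N*")
  draws <- ifelse(bad, NA_real_, M_star_draws / pi_draws)
  list(draws = draws, mean = mean(draws, na.rm = TRUE),
       ci95 = unname(quantile(draws, c(0.025, 0.975), na.rm = TRUE)),
       n_dropped = n_dropped)
}
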