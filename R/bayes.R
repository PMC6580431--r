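#' Augment observed histories with all-zero pseudo-individuals
#'
#' Parameter-expanded data augmentation: the observed encounter
#' histories are padded with all-zero pseudo-histories up to size
#' `A = ceiling(factor * n_observed)`, and each augmented individual
#' carries an inclusion indicator `w_i ~ Bernoulli(Psi)` so that the
#' marked superpopulation size `M* = sum(w_i)` becomes estimable.  A
#' factor of 3 is the default; the sampler flags runs where the
#' posterior of M* piles up near A (augmentation chosen too small).
#'
#' @param data an [encounter_histories()].
#' @param factor augmentation factor (> 1).
#' @return an object of class `augmented_histories`: `y` (A x K matrix,
#'   pseudo-rows all zero), `n_obs`, `A`, `w` (initial inclusion:
#'   observed rows 1, pseudo rows 0), `z` (initial presence: 1 between
#'   first and last detection of observed rows).
#' @export
augment <- function(data, factor = 3.0) {
  stopifnot(inherits(data, "encounter_histories"))
  if (factor <= 1) stop("augmentation factor must exceed 1")
  n <- nrow(data$y)
  if (n < 1L) stop("no observed individuals to augment")
  K <- ncol(data$y)
  A <- as.integer(ceiling(factor * n))
  y <- rbind(data$y, matrix(0L, A - n, K))
  z <- matrix(0L, A, K)
  for (i in seq_len(n)) {
    w <- which(data$y[i, ] == 1L)
    z[i, w[1L]:w[length(w)]] <- 1L
  }
  structure(list(y = y, n_obs = n, A = A, K = K,
                 w = c(rep(1L, n), rep(0L, A - n)), z = z,
                 occasions = data$occasions),
            class = "augmented_histories")
}

#' @export
print.augmented_histories <- function(x, ...) {
  cat(sprintf("Augmented histories: %d observed + %d pseudo = %d rows, K = %d\n",
              x$n_obs, x$A - x$n_obs, x$A, x$K))
  invisible(x)
}

bayes_modes <- function(structure) {
  s <- model_structure(structure)
  if (s$entry != "bt")
    stop("the Bayesian sampler models day-specific entry (structure 'bt_...')")
  phi_mode <- switch(s$staying,
    "phi." = 0L, "phih" = 1L,
    stop("Bayesian staying structures supported: phi. or phih"))
  det_mode <- switch(s$detection,
    "p." = 0L, "p.+h" = 1L, "pt" = 2L, "pt+h" = 3L)
  list(s = s, phi_mode = phi_mode, det_mode = det_mode)
}

#' Sample the posterior of the Bayesian mixture JS model
#'
#' Markov chain Monte Carlo for the state-space Jolly-Seber
#' superpopulation model with data augmentation and (optionally) two
#' latent classes differing in staying and/or encounter probability.
#' Priors are uninformative: Uniform(0,1) on the inclusion probability,
#' on each staying and encounter probability and on the class
#' proportion, and a flat Dirichlet on the entry distribution.  Latent
#' presence is updated per individual by an exact draw of (class, entry
#' day, departure day) from its joint conditional (the presence row is
#' the contiguous run between entry and departure, so no re-entry is
#' ever proposed); parameter updates are conjugate, except the additive
#' day + class detection structure (`pt+h`) which uses Metropolis steps
#' on the logit scale.
#'
#' Convergence is summarized by split R-hat over chains; values above
#' 1.2 are flagged, not errored.  A second flag reports when the
#' posterior mass of M* near the augmented size A exceeds 1 percent
#' (augmentation too small).
#'
#' @param aug an `augmented_histories` from [augment()] (an
#'   [encounter_histories()] is accepted and augmented with the default
#'   factor).
#' @param structure structure string; the Bayesian engine supports
#'   `bt_phi._p.`, `bt_phih_p.`, `bt_phi._p.+h`, `bt_phih_p.+h`,
#'   `bt_phi._pt`, `bt_phih_pt`, `bt_phi._pt+h`, `bt_phih_pt+h`.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded per chain.
#' @param n_chains number of chains (overdispersed starts).
#' @param seed RNG seed.
#' @param thin keep every `thin`-th draw.
#' @param scans optional [scan_samples()]; adds a conjugate Beta node
#'   for the marked proportion pi and per-draw total population size
#'   N* = M*/pi (see [estimate_pi()]).
#' @param store_latent also store per-draw inclusion and presence
#'   windows (needed by [derived_stopover()]; memory-heavy for large A).
#' @param fix_omega optional length-2 vector: hold the class proportions
#'   fixed instead of sampling them (e.g. `c(1, 0)` collapses a
#'   two-class structure onto its first class, which reproduces the
#'   corresponding no-mixture posterior).
#' @return an object of class `jse_draws` with per-draw vectors/matrices
#'   `psi`, `omega`, `phi`, `p` (K x H, flattened), `beta`, `Mstar`,
#'   `Sbar`, optionally `pi`/`Nstar` and latent draws; plus `rhat`,
#'   `flags`, `chain` index and the call settings.
#' @examples
#' \donttest{
#' sim <- simulate_histories(make_scenario(1, seed = 7))
#' draws <- run_mcmc(augment(sim$histories), "bt_phih_p.+h",
#'                   n_iter = 2000, n_burn = 500, seed = 7)
#' summary(draws$Mstar)
#' }
#' @export
run_mcmc <- function(aug, structure = "bt_phih_p.+h", n_iter = 30000,
                     n_burn = 10000, n_chains = 2, seed = NULL, thin = 1,
                     scans = NULL, store_latent = FALSE, fix_omega = NULL) {
  if (inherits(aug, "encounter_histories")) aug <- augment(aug)
  stopifnot(inherits(aug, "augmented_histories"))
  md <- bayes_modes(structure)
  H <- md$s$n_classes
  K <- aug$K
  yobs <- aug$y[seq_len(aug$n_obs), , drop = FALSE]
  if (!is.null(seed)) set.seed(as.integer(seed))
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    inits <- list(
      psi = runif(1, 0.3, 0.9),
      omega = if (!is.null(fix_omega)) fix_omega else if (H == 2) {
        o1 <- runif(1, 0.2, 0.8); c(o1, 1 - o1)
      } else 1,
      phi = runif(H, 0.3, 0.9),
      beta = rep(1 / K, K),
      p = runif(if (md$det_mode %in% c(2L, 3L)) K else H, 0.1, 0.6),
      delta = if (md$det_mode == 3L) rnorm(1, 0, 0.5) else 0)
    chains[[ch]] <- jse_mcmc_core(yobs, aug$A, H, md$phi_mode, md$det_mode,
                                  as.integer(n_iter), as.integer(n_burn),
                                  as.integer(thin), inits, 0.5, 0.3,
                                  store_latent, is.null(fix_omega))
  }
  n_keep <- length(chains[[1L]]$psi)
  res <- list(
    psi = unlist(lapply(chains, `[[`, "psi")),
    omega = do.call(rbind, lapply(chains, `[[`, "omega")),
    phi = do.call(rbind, lapply(chains, `[[`, "phi")),
    p = do.call(rbind, lapply(chains, `[[`, "p")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    Mstar = unlist(lapply(chains, `[[`, "Mstar")),
    Sbar = unlist(lapply(chains, `[[`, "Sbar")),
    delta = unlist(lapply(chains, `[[`, "delta")),
    chain = rep(seq_len(n_chains), each = n_keep),
    accept = chains[[1L]]$accept)
  if (store_latent) {
    res$w <- do.call(rbind, lapply(chains, `[[`, "w"))
    res$entry <- do.call(rbind, lapply(chains, `[[`, "entry"))
    res$depart <- do.call(rbind, lapply(chains, `[[`, "depart"))
  }
  # relabel classes per draw: class 2 is the high-detection class (or the
  # high-staying class for mixtures in phi only); skipped when the class
  # proportions are held fixed (class roles are then user-defined)
  if (H == 2L && is.null(fix_omega)) {
    keyed <- if (md$det_mode %in% c(1L, 3L))
      rowMeans(res$p[, seq_len(K), drop = FALSE]) >
        rowMeans(res$p[, K + seq_len(K), drop = FALSE])
    else if (md$phi_mode == 1L) res$phi[, 1L] > res$phi[, 2L]
    else rep(FALSE, length(res$psi))
    if (any(keyed)) {
      res$omega[keyed, ] <- res$omega[keyed, 2:1]
      res$phi[keyed, ] <- res$phi[keyed, 2:1]
      res$p[keyed, ] <- res$p[keyed, c(K + seq_len(K), seq_len(K))]
      res$delta[keyed] <- -res$delta[keyed]
    }
  }
  res$K <- K; res$H <- H; res$A <- aug$A; res$n_obs <- aug$n_obs
  res$structure <- md$s
  res$settings <- list(n_iter = n_iter, n_burn = n_burn, n_chains = n_chains,
                       thin = thin, seed = seed)
  # convergence and truncation diagnostics
  scal <- cbind(psi = res$psi, Mstar = res$Mstar, Sbar = res$Sbar,
                phi1 = res$phi[, 1L],
                p_mean1 = rowMeans(res$p[, seq_len(K), drop = FALSE]))
  if (H == 2L) scal <- cbind(scal, omega1 = res$omega[, 1L],
                             phi2 = res$phi[, 2L])
  res$rhat <- apply(scal, 2L, split_rhat, chain = res$chain)
  res$flags <- list(
    rhat_above_1.2 = names(res$rhat)[!is.na(res$rhat) & res$rhat > 1.2],
    mstar_truncated = mean(res$Mstar > 0.95 * aug$A) > 0.01)
  if (!is.null(scans)) {
    post <- estimate_pi(scans)
    res$pi <- rbeta(length(res$Mstar), post$shape1, post$shape2)
    res$Nstar <- total_population(res$Mstar, res$pi)$draws
  }
  class(res) <- "jse_draws"
  res
}

# split R-hat (each chain halved) for one scalar
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    m <- length(v) %/% 2L
    if (m < 2L) return(NULL)
    list(v[seq_len(m)], v[m + seq_len(m)])
  })
  parts <- unlist(halves, recursive = FALSE)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) < 2L) return(NA_real_)
  m <- length(parts); n <- length(parts[[1L]])
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, var, 0)
  B <- n * var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' @export
print.jse_draws <- function(x, ...) {
  cat("Posterior draws, Bayesian mixture JS model:", x$structure$string, "\n")
  cat(sprintf("  %d chains x %d kept draws; A = %d (n observed = %d)\n",
              x$settings$n_chains, sum(x$chain == 1L), x$A, x$n_obs))
  cat(sprintf("  M* posterior mean %.1f (95%% CI %.0f-%.0f)\n", mean(x$Mstar),
              quantile(x$Mstar, 0.025), quantile(x$Mstar, 0.975)))
  cat(sprintf("  mean stopover (realized) %.2f days\n",
              mean(x$Sbar, na.rm = TRUE)))
  bad <- x$flags$rhat_above_1.2
  if (length(bad)) cat("  R-hat > 1.2 for:", paste(bad, collapse = ", "), "\n")
  if (x$flags$mstar_truncated)
    cat("  WARNING: posterior of M* accumulates near A; increase augmentation\n")
  invisible(x)
}

#' Flatten posterior draws to a long table
#'
#' One row per (chain, iteration, parameter): scalar parameters, the
#' class-level staying/encounter summaries, entry probabilities per day,
#' and the derived M*, mean stopover duration and arrival day.
#'
#' @param draws a `jse_draws` from [run_mcmc()].
#' @return data frame with columns `chain`, `iter`, `parameter`, `value`.
#' @export
posterior_long <- function(draws) {
  stopifnot(inherits(draws, "jse_draws"))
  K <- draws$K
  iter <- stats::ave(seq_along(draws$chain), draws$chain, FUN = seq_along)
  cols <- list(psi = draws$psi, Mstar = draws$Mstar, Sbar = draws$Sbar,
               arrival_day50 = arrival_day50(draws$beta))
  for (h in seq_len(draws$H)) {
    cols[[paste0("omega", h)]] <- draws$omega[, h]
    cols[[paste0("phi", h)]] <- draws$phi[, h]
    cols[[paste0("p_mean", h)]] <-
      rowMeans(draws$p[, (h - 1) * K + seq_len(K), drop = FALSE])
  }
  for (t in seq_len(K)) cols[[paste0("beta", t)]] <- draws$beta[, t]
  if (!is.null(draws$pi)) {
    cols$pi <- draws$pi
    cols$Nstar <- draws$Nstar
  }
  do.call(rbind, lapply(names(cols), function(nm)
    data.frame(chain = draws$chain, iter = iter, parameter = nm,
               value = cols[[nm]], stringsAsFactors = FALSE)))
}

#' Per-draw stopover durations from stored latent states
#'
#' Computes, for each posterior draw, the individual stopover durations
#' `S_i = w_i * sum_t z_{i,t}` and their mean over included individuals
#' `S_bar = sum_i S_i / M*`.  The mean is taken over all individuals
#' estimated to have stayed at least one day, including never-observed
#' ones; draws with M* = 0 yield a missing mean.
#'
#' @param draws a `jse_draws` fitted with `store_latent = TRUE`, or any
#'   list with per-draw inclusion `w` (draws x A matrix) and either
#'   presence `z` (draws x A x K array) or entry/departure day matrices
#'   `entry` and `depart`.
#' @return list with `S` (draws x A matrix of S_i) and `Sbar` (per-draw
#'   mean).
#' @export
derived_stopover <- function(draws) {
  w <- draws$w
  if (is.null(w)) stop("draws carry no latent states; rerun with store_latent = TRUE")
  if (!is.null(draws$z)) {
    S <- apply(draws$z, c(1L, 2L), sum) * w
  } else {
    dur <- draws$depart - draws$entry + 1L
    dur[is.na(dur)] <- 0L
    S <- dur * w
  }
  M <- rowSums(w)
  Sbar <- ifelse(M > 0, rowSums(S) / M, NA_real_)
  list(S = S, Sbar = Sbar)
}

#' Exact posterior of M* on small instances by exhaustive enumeration
#'
#' Independent oracle for validating the MCMC sampler: on instances
#' small enough to enumerate (a handful of augmented individuals, two or
#' three occasions), sums the marginal likelihood over every latent
#' configuration (inclusion, class, entry day, departure day per
#' individual), integrating all parameters analytically under their
#' conjugate priors, and returns the exact posterior distribution of the
#' marked superpopulation size M*.  Excluded individuals' class and
#' presence are marginalized (their factors integrate to one).
#'
#' Supported structures are the conjugate ones (`bt_phi._p.`,
#' `bt_phih_p.`, `bt_phi._p.+h`, `bt_phih_p.+h`).
#'
#' @param aug an `augmented_histories` (keep `A <= 10`, `K <= 3`).
#' @param structure structure string.
#' @return named numeric vector: `P(M* = m)` for `m = n_obs..A`.
#' @export
exact_mstar_posterior <- function(aug, structure = "bt_phih_p.+h") {
  stopifnot(inherits(aug, "augmented_histories"))
  md <- bayes_modes(structure)
  if (md$det_mode %in% c(2L, 3L))
    stop("enumeration supports constant detection structures only")
  H <- md$s$n_classes
  K <- aug$K; A <- aug$A; n <- aug$n_obs
  if (A > 10L || K > 4L) stop("instance too large to enumerate")
  yobs <- aug$y[seq_len(n), , drop = FALSE]

  # per-individual latent states and their sufficient-statistic increments:
  # columns: w, class count (h==1), entry day (1..K one-hot), stays_h, deps_h,
  # det_h, miss_h for h in 1..H
  state_rows <- function(first, last, ndet) {
    rows <- list()
    for (h in seq_len(H)) for (b in seq_len(first)) for (d in last:K) {
      if (d < b) next
      stays <- d - b
      deps <- as.integer(d < K)
      expo <- d - b + 1L
      v <- c(w = 1, h1 = as.integer(h == 1L),
             entry = as.integer(seq_len(K) == b),
             stays = as.integer(seq_len(H) == h) * stays,
             deps = as.integer(seq_len(H) == h) * deps,
             det = as.integer(seq_len(H) == h) * ndet,
             miss = as.integer(seq_len(H) == h) * (expo - ndet))
      rows[[length(rows) + 1L]] <- v
    }
    do.call(rbind, rows)
  }
  obs_states <- lapply(seq_len(n), function(i) {
    w <- which(yobs[i, ] == 1L)
    state_rows(w[1L], w[length(w)], length(w))
  })
  pseudo <- rbind(0, state_rows(K, 1L, 0L))  # w = 0 row first

  # accumulate count vectors over individuals, merging duplicates
  acc <- matrix(0, 1L, ncol(pseudo))
  colnames(acc) <- colnames(pseudo)
  logmult <- 0
  expand <- function(acc, logmult, states) {
    na <- nrow(acc); ns <- nrow(states)
    big <- acc[rep(seq_len(na), each = ns), , drop = FALSE] +
      states[rep(seq_len(ns), times = na), , drop = FALSE]
    lm <- rep(logmult, each = ns)
    key <- apply(big, 1L, paste, collapse = ",")
    grp <- match(key, unique(key))
    merged <- big[!duplicated(grp), , drop = FALSE]
    lmm <- vapply(split(lm, factor(grp, levels = seq_len(max(grp)))),
                  logsumexp, 0)
    list(acc = merged, logmult = as.numeric(lmm))
  }
  for (i in seq_len(n)) {
    st <- expand(acc, logmult, obs_states[[i]])
    acc <- st$acc; logmult <- st$logmult
  }
  for (i in seq_len(A - n)) {
    st <- expand(acc, logmult, pseudo)
    acc <- st$acc; logmult <- st$logmult
  }

  idx <- function(pre) grep(paste0("^", pre), colnames(acc))
  M <- acc[, "w"]
  c1 <- acc[, "h1"]
  entry <- acc[, idx("entry"), drop = FALSE]
  stays <- acc[, idx("stays"), drop = FALSE]
  deps <- acc[, idx("deps"), drop = FALSE]
  det <- acc[, idx("det"), drop = FALSE]
  miss <- acc[, idx("miss"), drop = FALSE]
  lml <- lbeta(1 + M, 1 + A - M) - lbeta(1, 1)          # Psi
  if (H == 2L) lml <- lml + lbeta(1 + c1, 1 + M - c1) - lbeta(1, 1)  # Omega
  lml <- lml + lgamma(K) + rowSums(lgamma(1 + entry)) - lgamma(K + M)  # beta
  if (md$phi_mode == 1L) {
    lml <- lml + rowSums(lbeta(1 + stays, 1 + deps)) - H * lbeta(1, 1)
  } else {
    lml <- lml + lbeta(1 + rowSums(stays), 1 + rowSums(deps)) - lbeta(1, 1)
  }
  if (md$det_mode == 1L) {
    lml <- lml + rowSums(lbeta(1 + det, 1 + miss)) - H * lbeta(1, 1)
  } else {
    lml <- lml + lbeta(1 + rowSums(det), 1 + rowSums(miss)) - lbeta(1, 1)
  }
  lp <- logmult + lml
  post <- vapply(n:A, function(m) {
    sel <- M == m
    if (!any(sel)) -Inf else logsumexp(lp[sel])
  }, 0)
  post <- exp(post - logsumexp(post))
  names(post) <- n:A
  post
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
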