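# Unconstrained reparameterization of a structure's free parameters:
# logits for probabilities, a multinomial logit (reference = last
# occasion) for the entry distribution, raw additive offsets for the
# logit-scale class terms.

theta_template <- function(structure, K) {
  s <- model_structure(structure)
  idx <- list(); pos <- 0L
  add <- function(name, len) {
    if (len > 0L) idx[[name]] <<- pos + seq_len(len)
    pos <<- pos + len
  }
  add("beta", if (s$entry == "bt") K - 1L else 0L)
  add("phi", switch(s$staying, "phi." = 1L, "phit" = K - 1L, "phih" = 2L,
                    "phit+h" = K - 1L))
  add("phi_delta", if (s$staying == "phit+h") 1L else 0L)
  add("p", switch(s$detection, "p." = 1L, "pt" = K, "p.+h" = 1L,
                  "pt+h" = K))
  add("p_delta", if (endsWith(s$detection, "+h")) 1L else 0L)
  add("omega", if (s$n_classes == 2L) 1L else 0L)
  list(idx = idx, n = pos, structure = s)
}

theta_to_params <- function(theta, tpl, K) {
  ix <- tpl$idx
  params <- list()
  if (!is.null(ix$beta)) {
    e <- exp(c(theta[ix$beta], 0))
    params$beta <- e / sum(e)
  }
  params$phi <- plogis(theta[ix$phi])
  if (!is.null(ix$phi_delta)) params$phi_delta <- theta[ix$phi_delta]
  params$p <- plogis(theta[ix$p])
  if (!is.null(ix$p_delta)) params$p_delta <- theta[ix$p_delta]
  if (!is.null(ix$omega)) params$omega <- plogis(theta[ix$omega])
  params
}

params_to_theta <- function(params, tpl, K) {
  ix <- tpl$idx
  theta <- numeric(tpl$n)
  if (!is.null(ix$beta))
    theta[ix$beta] <- log(params$beta[-K] / params$beta[K])
  theta[ix$phi] <- qlogis(params$phi)
  if (!is.null(ix$phi_delta))
    theta[ix$phi_delta] <- if (is.null(params$phi_delta)) 0 else params$phi_delta
  theta[ix$p] <- qlogis(params$p)
  if (!is.null(ix$p_delta))
    theta[ix$p_delta] <- if (is.null(params$p_delta)) 0 else params$p_delta
  if (!is.null(ix$omega)) theta[ix$omega] <- qlogis(params$omega[1L])
  theta
}

# lean theta -> (beta, phi, p, omega) arrays for the optimizer hot loop
# (no validation; mirrors theta_to_params + expand_params)
make_theta_expander <- function(tpl, K) {
  s <- tpl$structure
  ix <- tpl$idx
  H <- s$n_classes
  force(K)
  function(theta) {
    beta <- if (is.null(ix$beta)) rep.int(1 / K, K) else {
      e <- exp(c(theta[ix$beta], 0))
      e / sum(e)
    }
    phi <- switch(s$staying,
      "phi." = matrix(plogis(theta[ix$phi]), K - 1, H),
      "phit" = matrix(plogis(theta[ix$phi]), K - 1, H),
      "phih" = matrix(rep(plogis(theta[ix$phi]), each = K - 1), K - 1, 2),
      "phit+h" = {
        lg <- theta[ix$phi]
        cbind(plogis(lg), plogis(lg + theta[ix$phi_delta]),
              deparse.level = 0)
      })
    p <- switch(s$detection,
      "p." = matrix(plogis(theta[ix$p]), K, H),
      "pt" = matrix(plogis(theta[ix$p]), K, H),
      "p.+h" = matrix(plogis(theta[ix$p] + c(0, theta[ix$p_delta])), K, 2,
                      byrow = TRUE),
      "pt+h" = {
        lg <- theta[ix$p]
        cbind(plogis(lg), plogis(lg + theta[ix$p_delta]), deparse.level = 0)
      })
    omega <- if (H == 1L) 1 else {
      o1 <- plogis(theta[ix$omega])
      c(o1, 1 - o1)
    }
    list(beta = beta, phi = phi, p = p, omega = omega)
  }
}

random_start <- function(tpl, K) {
  ix <- tpl$idx
  theta <- numeric(tpl$n)
  if (!is.null(ix$beta)) theta[ix$beta] <- rnorm(length(ix$beta), 0, 0.5)
  theta[ix$phi] <- qlogis(runif(length(ix$phi), 0.2, 0.9))
  if (!is.null(ix$phi_delta)) theta[ix$phi_delta] <- rnorm(1, 0, 1)
  theta[ix$p] <- qlogis(runif(length(ix$p), 0.1, 0.9))
  if (!is.null(ix$p_delta)) theta[ix$p_delta] <- rnorm(1, 0, 1)
  if (!is.null(ix$omega)) theta[ix$omega] <- qlogis(runif(1, 0.2, 0.8))
  theta
}

# deterministic moderate start: uniform entry, phi 0.7, p set from the
# mean daily detection rate of the data
moment_start <- function(tpl, K, y) {
  ix <- tpl$idx
  theta <- numeric(tpl$n)
  prate <- min(max(mean(colMeans(y)) * 2, 0.05), 0.9)
  theta[ix$phi] <- qlogis(0.7)
  if (!is.null(ix$phi_delta)) theta[ix$phi_delta] <- 0.5
  theta[ix$p] <- qlogis(prate)
  if (!is.null(ix$p_delta)) theta[ix$p_delta] <- 1
  if (!is.null(ix$omega)) theta[ix$omega] <- qlogis(0.3)
  theta
}

# deterministic high-detection start: near-saturated p, short stays.  The
# likelihood surface has a flat valley along vanishing detection for
# degenerate data (every bird seen exactly once); starting on the other
# side of it lets the profile term select the right corner.
high_p_start <- function(tpl, K) {
  ix <- tpl$idx
  theta <- numeric(tpl$n)
  theta[ix$phi] <- qlogis(0.3)
  if (!is.null(ix$phi_delta)) theta[ix$phi_delta] <- 0.5
  theta[ix$p] <- qlogis(0.95)
  if (!is.null(ix$p_delta)) theta[ix$p_delta] <- 1
  if (!is.null(ix$omega)) theta[ix$omega] <- qlogis(0.5)
  theta
}

#' Small-sample corrected AIC
#'
#' `-2 loglik + 2k + 2k(k+1)/(n-k-1)`, with `n` the number of observed
#' encounter histories (the POPAN convention for the effective sample
#' size).  Returns `Inf` when `n <= k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of parameters.
#' @param n effective sample size.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the JS superpopulation model by maximum likelihood
#'
#' Maximizes the Schwarz-Arnason superpopulation likelihood — the
#' conditional history likelihood of [mixture_loglik()] together with
#' the binomial term for observing `n` of `N` individuals, with `N`
#' profiled out at `n / (1 - Pr(never detected))` — over an
#' unconstrained reparameterization (logits for probabilities, a
#' multinomial logit for the entry distribution, raw logit-scale class
#' offsets).  Mixture likelihoods
#' are prone to local maxima, so the optimizer is restarted `n_starts`
#' times from random initial values (the first start is a deterministic
#' moment-based one); the best solution is returned and the fit is
#' flagged unconverged when the two best optima differ by more than 0.01
#' deviance units.  The superpopulation size is recovered from the
#' number of observed individuals as `N_hat = n / (1 - Pr(never
#' detected))`.
#'
#' For two-class structures the latent classes are relabeled after
#' fitting so that class 2 carries the larger detection logit offset
#' (or, for mixtures in staying only, the larger staying probability).
#'
#' @param data an [encounter_histories()].
#' @param structure a [model_structure()] or structure string.
#' @param n_starts number of optimizer starts.
#' @param seed RNG seed for the random starts.
#' @param compute_se also compute standard errors (numerical Hessian);
#'   disable in large simulation studies for speed.
#' @return an object of class `ml_fit`: `structure`, `estimates` (list
#'   with `beta`, `phi` ((K-1) x H), `p` (K x H), `omega`), `loglik`,
#'   `n_params` (free parameters plus one for the superpopulation size,
#'   the POPAN counting convention), `aicc`, `N_hat`, `N_se`,
#'   `converged`, `n_starts_used`, `n_obs`.
#' @examples
#' scn <- make_scenario(1, seed = 1)
#' sim <- simulate_histories(scn)
#' fit <- fit_ml(sim$histories, "bt_phi._p.", n_starts = 1, compute_se = FALSE)
#' fit$N_hat   # underestimates the true 500 because heterogeneity is ignored
#' @export
fit_ml <- function(data, structure = "bt_phi._p.", n_starts = 5, seed = NULL,
                   compute_se = TRUE) {
  stopifnot(inherits(data, "encounter_histories"))
  y <- data$y
  K <- ncol(y)
  n <- nrow(y)
  if (n < 1L) stop("no observed individuals")
  if (K < 3L) stop("need at least 3 occasions")
  s <- model_structure(structure)
  tpl <- theta_template(s, K)
  uh <- unique_histories(y)
  if (!is.null(seed)) set.seed(seed)

  expander <- make_theta_expander(tpl, K)
  # Objective: the Schwarz-Arnason superpopulation likelihood with the
  # superpopulation size profiled out at N = n / (1 - p0).  This is the
  # conditional likelihood plus the binomial term for observing n of N
  # individuals; the extra term matters only where the conditional
  # likelihood is flat (e.g. data in which every bird is seen exactly
  # once), and there it uniquely selects the N = n corner.
  negll <- function(theta) {
    ex <- expander(theta)
    r <- js_lik_core(ex$beta, ex$phi, ex$p, ex$omega, uh$y, uh$first,
                     uh$last, uh$freq, TRUE)
    if (!is.finite(r$loglik) || r$p0 > 1 - 1e-10) return(1e10)
    extra <- if (r$p0 < 1e-12) lgamma(n + 1) else {
      N <- n / (1 - r$p0)
      n * log1p(-r$p0) + lgamma(N + 1) - lgamma(N - n + 1) +
        (N - n) * log(r$p0)
    }
    -(r$loglik + extra)
  }

  fits <- vector("list", n_starts)
  for (j in seq_len(n_starts)) {
    start <- if (j == 1L) moment_start(tpl, K, y)
             else if (j == 2L) high_p_start(tpl, K)
             else random_start(tpl, K)
    fits[[j]] <- tryCatch(
      nlminb(start, negll, control = list(iter.max = 1000, eval.max = 2000,
                                          rel.tol = 1e-10)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e)))
  }
  objs <- vapply(fits, function(f) f$objective, 0)
  if (all(!is.finite(objs)))
    stop("all optimizer starts failed: ",
         paste(vapply(fits, function(f)
           if (!is.null(f$message)) f$message else "non-finite objective",
           ""), collapse = "; "))
  best <- fits[[which.min(objs)]]
  converged <- is.finite(best$objective) && best$convergence == 0L
  if (n_starts > 1L) {
    dev <- sort(2 * objs[is.finite(objs)])
    if (length(dev) >= 2L && (dev[2L] - dev[1L]) > 0.01) converged <- FALSE
  }

  params <- theta_to_params(best$par, tpl, K)
  params <- relabel_classes(params, s)
  ex <- expand_params(params, s, K)
  lik <- js_lik_core(ex$beta, ex$phi, ex$p, ex$omega, uh$y, uh$first, uh$last,
                     uh$freq, TRUE)
  p0 <- lik$p0
  N_hat <- n / (1 - p0)
  k <- n_free_params(s, K) + 1L
  N_se <- NA_real_
  se_table <- NULL
  if (compute_se) {
    se <- tryCatch(ml_se(best$par, negll, tpl, s, K, n, uh),
                   error = function(e) NULL)
    if (!is.null(se)) {
      N_se <- se$N_se
      se_table <- se$table
    }
  }
  out <- list(structure = s, estimates = c(ex[c("beta", "phi", "p", "omega")],
                                           list(p_delta = params$p_delta,
                                                phi_delta = params$phi_delta)),
              loglik = lik$loglik, n_params = k,
              aicc = aicc(lik$loglik, k, n), N_hat = N_hat, N_se = N_se,
              p0 = p0, converged = converged, n_starts_used = n_starts,
              n_obs = n, se_table = se_table,
              minimal_sod_mean = minimal_sod(data)$mean)
  class(out) <- "ml_fit"
  out
}

# order latent classes: class 2 takes the larger detection logit offset;
# for staying-only mixtures, the larger staying probability
relabel_classes <- function(params, s) {
  if (s$n_classes != 2L) return(params)
  if (endsWith(s$detection, "+h")) {
    if (!is.null(params$p_delta) && params$p_delta < 0) {
      params$p <- plogis(qlogis(params$p) + params$p_delta)
      params$p_delta <- -params$p_delta
      if (s$staying == "phih") params$phi <- rev(params$phi)
      if (s$staying == "phit+h") {
        params$phi <- plogis(qlogis(params$phi) + params$phi_delta)
        params$phi_delta <- -params$phi_delta
      }
      params$omega <- 1 - params$omega
    }
  } else if (s$staying == "phih") {
    if (params$phi[1L] > params$phi[2L]) {
      params$phi <- rev(params$phi)
      params$omega <- 1 - params$omega
    }
  } else if (s$staying == "phit+h" && !is.null(params$phi_delta) &&
             params$phi_delta < 0) {
    params$phi <- plogis(qlogis(params$phi) + params$phi_delta)
    params$phi_delta <- -params$phi_delta
    params$omega <- 1 - params$omega
  }
  params
}

ml_se <- function(theta, negll, tpl, s, K, n, uh) {
  Hn <- optimHess(theta, negll)
  V <- tryCatch(solve(Hn), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  # delta method for N_hat = n / (1 - p0(theta)): binomial sampling of the
  # observed count plus parameter uncertainty in p0
  expander <- make_theta_expander(tpl, K)
  p0_of <- function(th) {
    ex <- expander(th)
    js_lik_core(ex$beta, ex$phi, ex$p, ex$omega, uh$y, uh$first, uh$last,
                uh$freq, TRUE)$p0
  }
  p0 <- p0_of(theta)
  eps <- 1e-6
  g <- vapply(seq_along(theta), function(i) {
    th <- theta; th[i] <- th[i] + eps
    (p0_of(th) - p0) / eps
  }, 0)
  gN <- n * g / (1 - p0)^2
  vN <- n * p0 / (1 - p0)^2 + drop(t(gN) %*% V %*% gN)
  se_link <- sqrt(pmax(diag(V), 0))
  table <- data.frame(parameter = names_from_template(tpl),
                      estimate_link = theta, se_link = se_link,
                      stringsAsFactors = FALSE)
  list(N_se = sqrt(max(vN, 0)), table = table)
}

names_from_template <- function(tpl) {
  out <- character(tpl$n)
  for (nm in names(tpl$idx))
    out[tpl$idx[[nm]]] <- if (length(tpl$idx[[nm]]) > 1L)
      paste0(nm, "_", seq_along(tpl$idx[[nm]])) else nm
  out
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("Maximum-likelihood JS superpopulation fit:", x$structure$string, "\n")
  cat(sprintf("  n observed = %d, loglik = %.3f, K params = %d, AICc = %.2f\n",
              x$n_obs, x$loglik, x$n_params, x$aicc))
  cat(sprintf("  N_hat = %.1f%s, phi = %s, p(mean) = %s\n", x$N_hat,
              if (!is.na(x$N_se)) sprintf(" (SE %.1f)", x$N_se) else "",
              paste(sprintf("%.3f", colMeans(x$estimates$phi)),
                    collapse = "/"),
              paste(sprintf("%.3f", colMeans(x$estimates$p)),
                    collapse = "/")))
  if (x$structure$n_classes == 2L)
    cat(sprintf("  omega = %.3f/%.3f\n", x$estimates$omega[1L],
                x$estimates$omega[2L]))
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' Select the most parsimonious adequately supported model
#'
#' Among converged fits whose AICc lies within `delta` (default 2) of
#' the minimum, returns the fit with the fewest parameters; ties are
#' broken by lower AICc, then by structure string order, so selection is
#' deterministic.
#'
#' @param fits list of `ml_fit` objects.
#' @param delta AICc window.
#' @return the selected `ml_fit`.
#' @export
select_model <- function(fits, delta = 2) {
  if (inherits(fits, "ml_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("no converged fits to select from")
  fits <- fits[ok]
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  cand <- which(aiccs - min(aiccs) < delta)
  k <- vapply(fits[cand], function(f) f$n_params, 0L)
  strs <- vapply(fits[cand], function(f) f$structure$string, "")
  ord <- order(k, aiccs[cand], strs)
  fits[[cand[ord[1L]]]]
}
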