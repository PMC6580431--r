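# Parameter handling for the JS superpopulation likelihood.
#
# The canonical internal representation expands any structure to full
# arrays: beta (K), phi ((K-1) x H), p (K x H), omega (H).  User-facing
# parameter lists may give scalars/vectors per the structure; additive
# class offsets are applied on the logit scale.

expand_params <- function(params, structure, K) {
  s <- model_structure(structure)
  H <- s$n_classes
  beta <- switch(s$entry,
    "b." = rep(1 / K, K),
    "bt" = {
      if (is.null(params$beta)) stop("structure needs `beta` (length K)")
      b <- as.numeric(params$beta)
      if (length(b) != K) stop("`beta` must have length K = ", K)
      if (abs(sum(b) - 1) > 1e-8) stop("`beta` must sum to 1")
      b
    })
  phi_in <- params$phi
  if (is.null(phi_in)) stop("parameter list needs `phi`")
  phi <- if (is.matrix(phi_in) && ncol(phi_in) == H && nrow(phi_in) == K - 1) {
    phi_in
  } else {
    switch(s$staying,
      "phi." = matrix(phi_in[1L], K - 1, H),
      "phit" = matrix(rep(as.numeric(phi_in), H), K - 1, H),
      "phih" = matrix(rep(as.numeric(phi_in), each = K - 1), K - 1, H),
      "phit+h" = {
        d <- if (is.null(params$phi_delta)) 0 else params$phi_delta
        base <- as.numeric(phi_in)
        if (length(base) != K - 1) stop("`phi` must have length K - 1")
        cbind(base, plogis(qlogis(base) + d), deparse.level = 0)
      })
  }
  p_in <- params$p
  if (is.null(p_in)) stop("parameter list needs `p`")
  p <- if (is.matrix(p_in) && ncol(p_in) == H && nrow(p_in) == K) {
    p_in
  } else {
    switch(s$detection,
      "p." = matrix(p_in[1L], K, H),
      "pt" = {
        if (length(p_in) != K) stop("`p` must have length K")
        matrix(rep(as.numeric(p_in), H), K, H)
      },
      "p.+h" = {
        d <- if (is.null(params$p_delta)) 0 else params$p_delta
        matrix(plogis(qlogis(p_in[1L]) + c(0, d)), K, H, byrow = TRUE)
      },
      "pt+h" = {
        d <- if (is.null(params$p_delta)) 0 else params$p_delta
        if (length(p_in) != K) stop("`p` must have length K")
        cbind(as.numeric(p_in), plogis(qlogis(as.numeric(p_in)) + d),
              deparse.level = 0)
      })
  }
  omega <- if (H == 1L) 1 else {
    om <- params$omega
    if (is.null(om)) stop("two-class structures need `omega`")
    if (length(om) == 1L) om <- c(om, 1 - om)
    if (abs(sum(om) - 1) > 1e-8) stop("`omega` must sum to 1")
    as.numeric(om)
  }
  rng <- c(beta, phi, p, omega)
  if (any(rng < 0 | rng > 1) || anyNA(rng))
    stop("all probabilities must lie in [0, 1]")
  list(beta = beta, phi = phi, p = p, omega = omega, H = H)
}

# collapse a history matrix to unique rows with frequencies
unique_histories <- function(y) {
  key <- apply(y, 1L, paste, collapse = "")
  tab <- table(key)
  uy <- y[match(names(tab), key), , drop = FALSE]
  # all-zero rows (possible when enumerating outcome spaces) get the full
  # (entry, departure) triangle: first = K, last = 1
  first <- apply(uy, 1L, function(r) {
    w <- which(r == 1L)
    if (length(w)) w[1L] else length(r)
  })
  last <- apply(uy, 1L, function(r) {
    w <- which(r == 1L)
    if (length(w)) w[length(w)] else 1L
  })
  list(y = uy, freq = as.numeric(tab), first = as.integer(first),
       last = as.integer(last))
}

js_lik <- function(params, data, structure, conditional = TRUE) {
  y <- if (inherits(data, "encounter_histories")) data$y else as.matrix(data)
  K <- ncol(y)
  ex <- expand_params(params, structure, K)
  if (nrow(y) == 0L)
    return(list(loglik = 0, probs = numeric(0), p0 = NA_real_))
  uh <- unique_histories(y)
  js_lik_core(ex$beta, ex$phi, ex$p, ex$omega, uh$y, uh$first, uh$last,
              uh$freq, conditional)
}

#' Mixture Jolly-Seber superpopulation log-likelihood
#'
#' Log-likelihood of a set of encounter histories under the
#' superpopulation Jolly-Seber model, with optional two-class finite
#' mixtures in the daily staying and/or encounter probabilities.  Each
#' observed individual contributes a mixture (over latent classes,
#' weights `omega`) of sums over all latent (entry day, departure day)
#' pairs consistent with its first and last detections; the likelihood
#' conditions on having been detected at least once by dividing by
#' 1 - Pr(never detected), which is also what links the number of
#' observed individuals to the superpopulation size.
#'
#' Parameters that make an observed history impossible (for example an
#' encounter probability of exactly 0 on a detection day) give `-Inf`,
#' not an error.
#'
#' @param params named list with `phi`, `p` and, depending on the
#'   structure, `beta` (length-K entry probabilities), `omega` (class
#'   proportions), `phi_delta`/`p_delta` (additive logit class offsets).
#'   Class-specific scalars may be given as length-2 vectors for the
#'   `h` structures, or full matrices ((K-1) x 2 for `phi`, K x 2 for
#'   `p`) may be supplied directly.
#' @param data an [encounter_histories()] (or plain 0/1 matrix).
#' @param structure a [model_structure()] or structure string.
#' @param conditional condition on >= 1 detection (the default; set
#'   `FALSE` for the unconditional history probabilities used in
#'   probability-conservation checks).
#' @return scalar log-likelihood.
#' @seealso [fit_ml()] to maximize it, [history_probs()] for
#'   per-history probabilities.
#' @export
mixture_loglik <- function(params, data, structure = "bt_phi._p.",
                           conditional = TRUE) {
  js_lik(params, data, structure, conditional)$loglik
}

#' Per-history probabilities under the mixture JS model
#'
#' Unconditional probabilities of each distinct encounter history in
#' `data`, plus the probability `p0` of a superpopulation member being
#' detected on no occasion.  Summing the probability of every possible
#' nonzero history together with `p0` gives 1, which is the basis of the
#' probability-conservation tests.
#'
#' @inheritParams mixture_loglik
#' @return list with `probs` (one entry per row of `data`, in row
#'   order), and `p0`.
#' @export
history_probs <- function(params, data, structure = "bt_phi._p.") {
  y <- if (inherits(data, "encounter_histories")) data$y else as.matrix(data)
  if (nrow(y) == 0L) return(list(probs = numeric(0), p0 = NA_real_))
  uh <- unique_histories(y)
  res <- js_lik(params, y, structure, conditional = FALSE)
  key <- apply(y, 1L, paste, collapse = "")
  ukey <- apply(uh$y, 1L, paste, collapse = "")
  list(probs = res$probs[match(key, ukey)], p0 = res$p0)
}
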