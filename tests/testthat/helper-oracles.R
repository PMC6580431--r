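# Independent oracles and tiny fixtures used across the test files.
# Everything here is deliberately brute-force and self-contained: no
# code path is shared with the package internals it checks.

# Probability of one encounter history by explicit enumeration of every
# latent (class, entry day, departure day) path.  phi/p are per-class
# vectors (time-constant) or K-vectors per class via matrices.
brute_history_prob <- function(y, beta, phi, p, omega = 1) {
  K <- length(beta)
  H <- length(omega)
  phi <- matrix(phi, nrow = H)   # H x 1 (constant) or H x (K-1)
  p <- matrix(p, nrow = H)       # H x 1 or H x K
  phi_at <- function(h, t) if (ncol(phi) == 1L) phi[h, 1L] else phi[h, t]
  p_at <- function(h, t) if (ncol(p) == 1L) p[h, 1L] else p[h, t]
  tot <- 0
  for (h in seq_len(H)) for (b in seq_len(K)) for (d in b:K) {
    out <- setdiff(seq_len(K), b:d)
    if (any(y[out] == 1L)) next
    pr <- omega[h] * beta[b]
    if (d > b) for (t in b:(d - 1)) pr <- pr * phi_at(h, t)
    if (d < K) pr <- pr * (1 - phi_at(h, d))
    for (t in b:d) pr <- pr * if (y[t] == 1L) p_at(h, t) else 1 - p_at(h, t)
    tot <- tot + pr
  }
  tot
}

# exact expected in-window stopover duration: entry-weighted truncated
# geometric, summed per class
brute_expected_sod <- function(omega, phi, entry) {
  K <- length(entry)
  sum(vapply(seq_along(omega), function(h) {
    omega[h] * sum(vapply(seq_len(K), function(a)
      entry[a] * sum(phi[h]^(0:(K - a))), 0))
  }, 0))
}

# all 2^K encounter histories at K occasions
all_histories <- function(K) {
  as.matrix(rev(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE])
}

tiny_histories <- function() {
  encounter_histories(matrix(c(0L, 1L, 0L,
                               1L, 1L, 0L,
                               0L, 0L, 1L), 3, 3, byrow = TRUE))
}

make_dated_csv <- function(path, dates, y, ids = NULL) {
  if (is.null(ids)) ids <- paste0("b", seq_len(nrow(y)))
  df <- data.frame(individual_id = ids, y, check.names = FALSE)
  colnames(df) <- c("individual_id", as.character(dates))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
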