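#' Simulate mark-resight encounter histories under a mixture scenario
#'
#' Generates one dataset from the scenario's generative model: each of
#' the `n_individuals` marked birds draws a latent class from `omega`, an
#' arrival day from `entry_probs`, stays each subsequent day with its
#' class's daily staying probability (geometric residency, right-
#' truncated at the last occasion), and while present is detected each
#' day with its class's encounter probability.  As in real data, the
#' returned encounter histories contain only individuals detected at
#' least once; the full truth (including never-detected birds) is
#' returned alongside.
#'
#' @param scn a [mixture_scenario()].
#' @param seed RNG seed; defaults to the seed stored in the scenario (if
#'   any).
#' @return a list with elements
#'   \describe{
#'     \item{histories}{[encounter_histories()] of the observed birds;}
#'     \item{truth}{a `sim_truth` object: `class_of`, `arrival_day`,
#'       `depart_day`, `presence` (N x K 0/1 matrix), `realized_sod`
#'       (in-window days present) and `observed` (logical) for every
#'       simulated individual.}
#'   }
#' @export
simulate_histories <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "mixture_scenario"))
  if (!is.null(seed)) set.seed(seed)
  N <- scn$n_individuals
  K <- scn$n_occasions
  H <- length(scn$omega)
  cls <- sample.int(H, N, replace = TRUE, prob = scn$omega)
  arrive <- sample.int(K, N, replace = TRUE, prob = scn$entry_probs)
  phi <- scn$phi_by_class[cls]
  # days stayed beyond arrival before departure, right-truncated at K
  extra <- ifelse(phi >= 1, K, rgeom(N, pmax(1 - phi, 1e-12)))
  depart <- pmin(arrive + extra, K)
  tgrid <- matrix(seq_len(K), N, K, byrow = TRUE)
  presence <- (tgrid >= arrive) & (tgrid <= depart)
  pdet <- matrix(scn$p_by_class[cls], N, K)
  y <- matrix(0L, N, K)
  y[presence] <- rbinom(sum(presence), 1L, pdet[presence])
  observed <- rowSums(y) > 0L
  truth <- structure(
    list(class_of = cls, arrival_day = arrive, depart_day = depart,
         presence = presence * 1L, realized_sod = as.integer(depart - arrive + 1L),
         observed = observed, scenario = scn),
    class = "sim_truth")
  hist <- encounter_histories(y[observed, , drop = FALSE],
                              id = paste0("bird", which(observed)),
                              occasions = seq_len(K))
  list(histories = hist, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d individuals (%d observed), K = %d\n",
              length(x$class_of), sum(x$observed), ncol(x$presence)))
  cat(sprintf("  mean realized stopover: %.2f days\n", mean(x$realized_sod)))
  invisible(x)
}

#' Scan samples of marked and unmarked birds
#'
#' A scan sample set records, per day, the total number of birds scanned
#' (`n_scanned`), how many of them carried marks (`n_marked`), and
#' whether the scan was a random sample of the population (with
#' replacement) or covered a distinct part of it (without replacement).
#'
#' @param day integer day index (occasion).
#' @param n_scanned total birds scanned.
#' @param n_marked marked birds among them.
#' @param with_replacement logical (or 0/1) per record.
#' @return an object of class `scan_samples` (a data frame).
#' @export
scan_samples <- function(day, n_scanned, n_marked,
                         with_replacement = TRUE) {
  df <- data.frame(day = as.integer(day),
                   n_scanned = as.integer(n_scanned),
                   n_marked = as.integer(n_marked),
                   with_replacement = as.logical(with_replacement))
  if (any(df$n_marked > df$n_scanned) || any(df$n_marked < 0))
    stop("scan records need 0 <= n_marked <= n_scanned")
  class(df) <- c("scan_samples", "data.frame")
  df
}

#' Simulate daily scan samples from a simulation truth
#'
#' Companion generator for the mark-ratio model: on each day the total
#' number of birds present is the number of marked birds present times
#' `1 + n_unmarked_multiplier`; a binomial fraction `scan_fraction` of
#' them is scanned and the number of marked birds in the scan is a
#' binomial draw at that day's marked fraction.  The defaults target the
#' order of magnitude of marked fractions seen in the field
#' (roughly 0.002-0.006).
#'
#' @param truth a `sim_truth` from [simulate_histories()].
#' @param n_unmarked_multiplier unmarked birds per marked bird
#'   (multiplier 199 gives a marked fraction of 1/200 = 0.005).
#' @param scan_fraction fraction of the birds present scanned each day,
#'   in (0, 1].
#' @param seed RNG seed.
#' @param with_replacement flag stored on the generated records.
#' @return a [scan_samples()] with one record per occasion; days with no
#'   marked birds present yield zero-count records.
#' @export
simulate_scans <- function(truth, n_unmarked_multiplier = 199,
                           scan_fraction = 0.1, seed = NULL,
                           with_replacement = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_unmarked_multiplier < 0) stop("multiplier must be >= 0")
  if (scan_fraction <= 0 || scan_fraction > 1)
    stop("scan_fraction must be in (0, 1]")
  if (sum(truth$presence) < 1) stop("truth has no bird-days")
  if (!is.null(seed)) set.seed(seed)
  marked <- colSums(truth$presence)
  total <- round(marked * (1 + n_unmarked_multiplier))
  n_s <- rbinom(length(total), total, scan_fraction)
  frac <- ifelse(total > 0, marked / total, 0)
  m_s <- rbinom(length(total), n_s, frac)
  scan_samples(seq_along(marked), n_s, m_s, with_replacement)
}

#' Read or write scan sample CSV files
#'
#' Columns: `day`, `n_scanned`, `n_marked`, `with_replacement` (0/1).
#'
#' @param path file path.
#' @param scans a [scan_samples()].
#' @return `read_scans()` returns a [scan_samples()]; `write_scans()`
#'   returns `path` invisibly.
#' @export
read_scans <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("day", "n_scanned", "n_marked", "with_replacement")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("scan CSV lacks columns: ", paste(missing, collapse = ", "))
  scan_samples(df$day, df$n_scanned, df$n_marked,
               as.logical(df$with_replacement))
}

#' @rdname read_scans
#' @export
write_scans <- function(scans, path) {
  stopifnot(inherits(scans, "scan_samples"))
  df <- as.data.frame(scans)
  df$with_replacement <- as.integer(df$with_replacement)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
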