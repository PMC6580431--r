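#' Model structure specifications
#'
#' A compact grammar describes which parameters of the Jolly-Seber
#' superpopulation model vary over time and/or between the two latent
#' mixture classes.  A structure string has three underscore-separated
#' components, `<entry>_<staying>_<detection>`:
#'
#' * entry: `"b."` (constant, beta_t = 1/K) or `"bt"` (day-specific entry
#'   probabilities);
#' * staying: `"phi."` (one constant), `"phit"` (day-specific),
#'   `"phih"` (class-specific constants), or `"phit+h"` (day-specific with
#'   an additive class offset on the logit scale);
#' * detection: `"p."`, `"pt"`, `"p.+h"`, or `"pt+h"`, analogous, where
#'   `+h` denotes an additive class offset on the logit scale.
#'
#' Any `h` term implies two latent classes with mixing proportions
#' `Omega`; without one the model has a single class.  Examples from the
#' field's notation: `"bt_phi._pt"` is the classic time-dependent POPAN
#' structure, `"bt_phih_pt+h"` allows heterogeneity in both staying and
#' detection.
#'
#' @param x a structure string, e.g. `"bt_phi._p."`.
#' @return an object of class `model_structure` with elements `entry`,
#'   `staying`, `detection` (component codes), `n_classes` (1 or 2) and
#'   `string` (the canonical string form).
#' @examples
#' s <- model_structure("bt_phih_pt+h")
#' s$n_classes
#' format(s)
#' @export
model_structure <- function(x) {
  if (inherits(x, "model_structure")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("structure string must have three components, e.g. \"bt_phi._p.\": ",
         x)
  entry <- match.arg(parts[1L], c("b.", "bt"))
  staying <- match.arg(parts[2L], c("phi.", "phit", "phih", "phit+h"))
  detection <- match.arg(parts[3L], c("p.", "pt", "p.+h", "pt+h"))
  n_classes <- if (staying %in% c("phih", "phit+h") ||
                   detection %in% c("p.+h", "pt+h")) 2L else 1L
  out <- list(entry = entry, staying = staying, detection = detection,
              n_classes = n_classes,
              string = paste(entry, staying, detection, sep = "_"))
  class(out) <- "model_structure"
  out
}

#' @export
format.model_structure <- function(x, ...) x$string

#' @export
print.model_structure <- function(x, ...) {
  cat("JS superpopulation structure:", x$string,
      sprintf("(%d class%s)\n", x$n_classes, if (x$n_classes > 1) "es" else ""))
  invisible(x)
}

#' @export
as.character.model_structure <- function(x, ...) x$string

# number of free parameters of a structure at K occasions (excluding the
# derived superpopulation size)
n_free_params <- function(structure, K) {
  s <- model_structure(structure)
  n <- 0L
  n <- n + switch(s$entry, "b." = 0L, "bt" = K - 1L)
  n <- n + switch(s$staying, "phi." = 1L, "phit" = K - 1L, "phih" = 2L,
                  "phit+h" = K)
  n <- n + switch(s$detection, "p." = 1L, "pt" = K, "p.+h" = 2L,
                  "pt+h" = K + 1L)
  if (s$n_classes == 2L) n <- n + 1L  # Omega
  n
}
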