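#' Kinetic and stress-response parameters of the P-C-S model
#'
#' Bundles the four first-order transition rates of the compartment model
#' with the constants of the stress-response dynamics.  All rates are per
#' day; the model time unit is days throughout the package (fitted
#' proliferation rates of 0.26--0.70 per day correspond to doubling times
#' of 1--2.7 days, the plausible range for fibroblast and HeLa cultures).
#'
#' The stress response F obeys
#' \deqn{dF/dt = \gamma(t) + a F^2 / (b^2 + F^2) - c F,}
#' a saturating positive feedback with linear decay.  With the default
#' shape constants the healthy state F = 0 is the only fixed point at
#' gamma = 0, and an intermediate band of constant gamma supports three
#' fixed points (bistability with hysteresis; see [bifurcation_scan()]).
#' `K` is the normalization scale of the response: the arrest flux in the
#' population equations is `f1 * (F/K) * P`.
#'
#' @param r proliferation rate of P cells (per day, >= 0).
#' @param f1 P -> C transition rate scale (per day, >= 0); the realized
#'   flux is `f1 * (F/K) * P`.
#' @param f2 C -> P return rate (per day, >= 0).
#' @param f3 C -> S senescence-commitment rate (per day, >= 0).
#' @param K response normalization scale (> 0).
#' @param a feedback amplitude of the F dynamics (response units per day).
#' @param b half-saturation level of the feedback (response units).
#' @param c linear decay rate of F (per day); the slow relaxation of the
#'   switched-on response back to the healthy state is set by `c` and by
#'   the saddle-node ghost of the feedback term.
#'
#' @return An object of class `pcs_params` (a named list).
#' @examples
#' p <- pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26)
#' p
#' @seealso [cell_state()], [simulate_pcs()], [stress_response_rhs()]
#' @export
pcs_params <- function(r, f1 = 0, f2 = 0, f3 = 0, K = 1,
                       a = 39.6, b = 20, c = 1) {
  vals <- c(r = unname(r), f1 = unname(f1), f2 = unname(f2),
            f3 = unname(f3), K = unname(K), a = unname(a), b = unname(b),
            c = unname(c))
  if (!all(is.finite(vals))) {
    stop("all model parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals[c("r", "f1", "f2", "f3")] < 0)) {
    stop("rates r, f1, f2, f3 must be non-negative", call. = FALSE)
  }
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (a < 0 || b <= 0 || c <= 0) {
    stop("F-shape constants require a >= 0, b > 0, c > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "pcs_params")
}

#' @export
print.pcs_params <- function(x, ...) {
  cat("P-C-S model parameters (per day):\n")
  cat(sprintf("  r = %g, f1 = %g, f2 = %g, f3 = %g\n", x$r, x$f1, x$f2, x$f3))
  cat(sprintf("  stress response: K = %g, a = %g, b = %g, c = %g\n",
              x$K, x$a, x$b, x$c))
  invisible(x)
}

#' Instantaneous state of the P-C-S model
#'
#' @param P proliferating-cell count (>= 0).
#' @param C reversibly arrested cell count (>= 0).
#' @param S senescent cell count (>= 0).
#' @param F stress-response level (dimensionless, >= 0).
#' @return A named numeric vector of class `cell_state` with components
#'   P, C, S, F.
#' @examples
#' cell_state(P = 1e5)
#' @export
cell_state <- function(P, C = 0, S = 0, F = 0) {
  y <- c(P = P, C = C, S = S, F = F)
  if (!all(is.finite(y))) stop("state components must be finite", call. = FALSE)
  if (any(y < 0)) stop("state components must be non-negative", call. = FALSE)
  structure(y, class = "cell_state")
}

as_cell_state <- function(x) {
  if (inherits(x, "cell_state")) return(x)
  x <- unlist(x)
  cell_state(P = x[["P"]],
             C = if ("C" %in% names(x)) x[["C"]] else 0,
             S = if ("S" %in% names(x)) x[["S"]] else 0,
             F = if ("F" %in% names(x)) x[["F"]] else 0)
}
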