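#' Right-hand sides of the model equations (reference implementations)
#'
#' Pure-R implementations of the model derivatives.  Production
#' integration ([simulate_pcs()]) uses the identical compiled right-hand
#' side; these functions document the equations, serve small analytic
#' computations and act as the reference for the solver-equivalence tests.
#'
#' `constant_growth_rhs()` is the one-compartment limit `dP/dt = r P`
#' (closed form `P(t) = P(0) exp(r t)`, i.e. a PD-vs-time line of slope
#' `r / ln 2`).
#'
#' `pcs_rhs()` returns the four derivatives of the full model:
#' \deqn{dP/dt = r P - f_1 \hat F P + f_2 C}
#' \deqn{dC/dt = f_1 \hat F P - f_2 C - f_3 C}
#' \deqn{dS/dt = f_3 C}
#' \deqn{dF/dt = \gamma + a F^2/(b^2 + F^2) - c F}
#' with the normalized response \eqn{\hat F = F / K} (or held at a fixed
#' value via `f_hat`, the constant-stress reduced model).  Note the mass
#' exchange is conservative: `dP + dC + dS = r P`.
#'
#' @param state a [cell_state()] (or named vector with components P, C, S, F).
#' @param params a [pcs_params()] object.
#' @param gamma_now instantaneous stress level (>= 0).
#' @param f_hat optional fixed value for the normalized response; `NULL`
#'   (default) uses the dynamic `F / K`.
#' @return `constant_growth_rhs()`: dP/dt.  `pcs_rhs()`: named numeric
#'   vector `c(P=, C=, S=, F=)` of derivatives.  `stress_response_rhs()`:
#'   dF/dt.
#' @examples
#' p <- pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26)
#' pcs_rhs(cell_state(P = 100), p, gamma_now = 0)
#' @export
pcs_rhs <- function(state, params, gamma_now, f_hat = NULL) {
  state <- as_cell_state(state)
  stopifnot(inherits(params, "pcs_params"))
  if (!is.finite(gamma_now) || gamma_now < 0) {
    stop("gamma_now must be a non-negative number", call. = FALSE)
  }
  P <- state[["P"]]; C <- state[["C"]]; F <- state[["F"]]
  fhat <- if (is.null(f_hat)) F / params$K else f_hat
  flux_in <- params$f1 * fhat * P
  flux_out <- params$f2 * C
  c(P = params$r * P - flux_in + flux_out,
    C = flux_in - flux_out - params$f3 * C,
    S = params$f3 * C,
    F = if (is.null(f_hat)) {
      stress_response_rhs(F, gamma_now, params)
    } else 0)
}

#' @rdname pcs_rhs
#' @export
constant_growth_rhs <- function(state, params) {
  state <- as_cell_state(state)
  stopifnot(inherits(params, "pcs_params"))
  params$r * state[["P"]]
}

#' @rdname pcs_rhs
#' @param F stress-response level (>= 0, vectorized).
#' @export
stress_response_rhs <- function(F, gamma_now, params) {
  stopifnot(inherits(params, "pcs_params"))
  if (any(!is.finite(F)) || any(F < 0)) {
    stop("F must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(gamma_now)) || any(gamma_now < 0)) {
    stop("gamma_now must be non-negative and finite", call. = FALSE)
  }
  gamma_now + params$a * F^2 / (params$b^2 + F^2) - params$c * F
}

# d(dF/dt)/dF, used for fixed-point stability in the bifurcation scan.
stress_response_dfdF <- function(F, params) {
  params$a * 2 * F * params$b^2 / (params$b^2 + F^2)^2 - params$c
}
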