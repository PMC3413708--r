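#' Stress protocols gamma(t)
#'
#' A stress protocol specifies the exogenous/endogenous stress input
#' gamma(t) >= 0 driving the cellular stress response:
#'
#' * `stress_none()` — no stress, gamma(t) = 0;
#' * `stress_pulse()` — an irradiation-like square pulse: gamma(t) = `gamma`
#'   on `[start, start + duration)` and 0 otherwise (right-continuous at
#'   the edges);
#' * `stress_constant()` — gamma(t) = `gamma` for all t (e.g. constantly
#'   high ambient oxygen);
#' * `stress_linear()` — linearly accumulating replicative stress
#'   gamma(t) = `alpha + beta * t`, with a time-independent offset `alpha`
#'   and accrual slope `beta` (telomere shortening, cumulative oxidative
#'   damage).
#'
#' Pulses are represented exactly: [simulate_pcs()] restarts the solver at
#' the pulse edges, so even 27-second exposures are never stepped over.
#'
#' @param gamma pulse or constant amplitude (stress units per day, >= 0).
#' @param start pulse onset time (days, >= 0).
#' @param duration pulse length (days, >= 0).
#' @param alpha offset of the linear protocol (stress units per day, >= 0).
#' @param beta accrual slope of the linear protocol (stress units per
#'   day^2, >= 0).
#' @return An object of class `stress_protocol`.
#' @examples
#' gamma_at(stress_linear(alpha = 0.002, beta = 0.028), t = 0)
#' gamma_at(stress_pulse(gamma = 8000, start = 1, duration = 27 / 86400), t = 2)
#' @name stress_protocol
NULL

new_stress_protocol <- function(kind, gamma = 0, start = 0, duration = 0,
                                alpha = 0, beta = 0) {
  structure(list(kind = kind, gamma = gamma, start = start,
                 duration = duration, alpha = alpha, beta = beta),
            class = "stress_protocol")
}

#' @rdname stress_protocol
#' @export
stress_none <- function() new_stress_protocol("none")

#' @rdname stress_protocol
#' @export
stress_pulse <- function(gamma, start = 1, duration) {
  if (!is.finite(gamma) || gamma < 0) {
    stop("pulse amplitude must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(start) || start < 0) stop("pulse start must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0) {
    stop("pulse duration must be >= 0", call. = FALSE)
  }
  if (duration == 0 || gamma == 0) return(stress_none())
  new_stress_protocol("pulse", gamma = gamma, start = start, duration = duration)
}

#' @rdname stress_protocol
#' @export
stress_constant <- function(gamma) {
  if (!is.finite(gamma) || gamma < 0) {
    stop("constant stress level must be a non-negative number", call. = FALSE)
  }
  new_stress_protocol("constant", gamma = gamma)
}

#' @rdname stress_protocol
#' @export
stress_linear <- function(alpha, beta) {
  if (!all(is.finite(c(alpha, beta))) || alpha < 0 || beta < 0) {
    stop("alpha and beta must be non-negative numbers", call. = FALSE)
  }
  new_stress_protocol("linear", alpha = alpha, beta = beta)
}

#' @export
print.stress_protocol <- function(x, ...) {
  desc <- switch(x$kind,
    none = "none (gamma = 0)",
    pulse = sprintf("pulse: gamma = %g on [%g, %g) days", x$gamma, x$start,
                    x$start + x$duration),
    constant = sprintf("constant: gamma = %g", x$gamma),
    linear = sprintf("linear: gamma(t) = %g + %g t", x$alpha, x$beta))
  cat("Stress protocol —", desc, "\n")
  invisible(x)
}

#' Evaluate a stress protocol at time t
#'
#' @param protocol a [stress_protocol] object.
#' @param t time in days (vectorized, all >= 0).
#' @return gamma(t), a numeric vector the length of `t`.
#' @examples
#' gamma_at(stress_none(), 3)
#' @export
gamma_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "stress_protocol"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be non-negative and finite", call. = FALSE)
  }
  switch(protocol$kind,
    none = rep(0, length(t)),
    pulse = ifelse(t >= protocol$start &
                     t < protocol$start + protocol$duration,
                   protocol$gamma, 0),
    constant = rep(protocol$gamma, length(t)),
    linear = protocol$alpha + protocol$beta * t)
}

#' Irradiation pulse protocol for a labelled dose
#'
#' Convenience constructor for the pulse protocols used in the irradiation
#' experiment designs: cells are seeded one day before exposure, so the
#' pulse starts at `exposure_time = 1` day by default.  A zero duration (or
#' zero amplitude) yields the unirradiated control, i.e. no stress.
#'
#' @param dose_label a label such as `"0Gy"`, `"2Gy"`, `"15Gy"` (carried
#'   along as an attribute; not interpreted).
#' @param gamma_amplitude stress level during exposure (>= 0).
#' @param duration exposure time in days (e.g. `108/86400` for 108 s).
#' @param exposure_time pulse onset in days after seeding.
#' @return A [stress_protocol] with attribute `dose_label`.
#' @examples
#' irradiation_protocol("2Gy", 2800, 108 / 86400)
#' @export
irradiation_protocol <- function(dose_label, gamma_amplitude, duration,
                                 exposure_time = 1) {
  if (!is.finite(gamma_amplitude) || gamma_amplitude < 0) {
    stop("gamma amplitude must be non-negative", call. = FALSE)
  }
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be non-negative", call. = FALSE)
  }
  p <- if (duration == 0 || gamma_amplitude == 0) {
    stress_none()
  } else {
    stress_pulse(gamma = gamma_amplitude, start = exposure_time,
                 duration = duration)
  }
  attr(p, "dose_label") <- dose_label
  p
}

# Breakpoints where gamma(t) is discontinuous on (t0, t1); used by the
# solver driver to restart integration at pulse edges.
protocol_breaks <- function(protocol, t0, t1) {
  if (protocol$kind != "pulse") return(numeric(0))
  br <- c(protocol$start, protocol$start + protocol$duration)
  sort(br[br > t0 & br < t1])
}

# Piecewise-linear coefficients (g0, g1) with gamma(t) = g0 + g1 * t on a
# segment that contains no discontinuity.
protocol_segment_coef <- function(protocol, t_mid) {
  switch(protocol$kind,
    none = c(0, 0),
    constant = c(protocol$gamma, 0),
    linear = c(protocol$alpha, protocol$beta),
    pulse = if (t_mid >= protocol$start &&
                  t_mid < protocol$start + protocol$duration) {
      c(protocol$gamma, 0)
    } else {
      c(0, 0)
    })
}
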