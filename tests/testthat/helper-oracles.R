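# Independent oracles used across the test files.  These deliberately do
# not share code with the package internals they check.

# Fixed-step classical Runge-Kutta integration of the full model.
rk4_trajectory <- function(params, protocol, initial, times, dt = 1e-4) {
  y <- unclass(pcskinetics::cell_state(P = initial[["P"]], C = initial[["C"]],
                                       S = initial[["S"]], F = initial[["F"]]))
  deriv <- function(t, y) {
    gam <- pcskinetics::gamma_at(protocol, t)
    st <- pcskinetics::cell_state(P = max(y[1], 0), C = max(y[2], 0),
                                  S = max(y[3], 0), F = max(y[4], 0))
    unname(pcskinetics::pcs_rhs(st, params, gam))
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = 4)
  t <- times[1]
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  colnames(out) <- c("P", "C", "S", "F")
  out
}

# Forward-Euler relaxation of the stress response alone at constant gamma.
relax_F <- function(F0, gam, params, t_end, dt = 1e-3) {
  F <- F0
  for (i in seq_len(ceiling(t_end / dt))) {
    F <- F + dt * (gam + params$a * F^2 / (params$b^2 + F^2) - params$c * F)
    F <- max(F, 0)
  }
  F
}

# Quasi-static sweep of gamma; returns the F level tracked at each gamma.
sweep_F <- function(gammas, params, relax_time = 40) {
  F <- 0
  vapply(gammas, function(g) {
    F <<- relax_F(F, g, params, relax_time)
    F
  }, numeric(1))
}

# Closed-form PD curve of the two-state reduced model via eigendecomposition
# of [[r - f1, f2], [f1, -f2]] (independent of the ODE solver).
two_state_pd_closed <- function(r, f1, f2, times) {
  A <- matrix(c(r - f1, f2, f1, -f2), nrow = 2, byrow = TRUE)
  e <- eigen(A)
  x0 <- solve(e$vectors, c(1, 0))
  tot <- vapply(times - times[1], function(t) {
    y <- e$vectors %*% (x0 * exp(e$values * t))
    sum(y)
  }, numeric(1))
  log2(tot / tot[1])
}

# Mean binomial sampling noise floor for a fraction estimated from
# n_rep replicates of n cells at success probabilities p.
binomial_floor <- function(p, n = 100, n_rep = 3) {
  mean(sqrt(p * (1 - p) / (n * n_rep)))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
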