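#' Analytic fate classification under constant saturated stress
#'
#' When the stress response is pinned at its saturated level (normalized
#' response 1), the (P, C) subsystem is linear and the population grows
#' if and only if the proliferation rate exceeds the critical rate
#' `r_crit = f1 * f3 / (f2 + f3)`: growth must outpace the net drain of
#' cycling cells through arrest into senescence.  The classification
#' equals the sign of the dominant eigenvalue of the subsystem Jacobian
#' `[[r - f1, f2], [f1, -(f2 + f3)]]`.
#'
#' @param params a [pcs_params()] with `f2 + f3 > 0` (the degenerate case
#'   `f2 = f3 = 0` is classified with `r_crit = f1` and flagged).
#' @return An object of class `fate_classification`: list with `r_crit`,
#'   `grows` (TRUE iff `r > r_crit` strictly), `dominant_eigenvalue`, and
#'   `degenerate`.
#' @examples
#' classify_fate(pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26))
#' @export
classify_fate <- function(params) {
  stopifnot(inherits(params, "pcs_params"))
  degenerate <- (params$f2 + params$f3) == 0
  r_crit <- if (degenerate) params$f1 else {
    params$f1 * params$f3 / (params$f2 + params$f3)
  }
  J <- matrix(c(params$r - params$f1, params$f2,
                params$f1, -(params$f2 + params$f3)),
              nrow = 2, byrow = TRUE)
  lam <- max(Re(eigen(J, only.values = TRUE)$values))
  structure(list(r_crit = r_crit, grows = params$r > r_crit,
                 dominant_eigenvalue = lam, degenerate = degenerate),
            class = "fate_classification")
}

#' @export
print.fate_classification <- function(x, ...) {
  cat(sprintf("Fate under constant saturated stress: r_crit = %.4g -> %s\n",
              x$r_crit, if (x$grows) "population grows" else
                "population cannot grow"))
  if (x$degenerate) cat("  (degenerate: f2 + f3 = 0)\n")
  invisible(x)
}

#' Bifurcation scan of the stress-response fixed points
#'
#' For each stress level on `gamma_grid`, locates all fixed points of the
#' response dynamics dF/dt = gamma + a F^2/(b^2 + F^2) - c F by sign-change
#' bracketing on a fine F grid followed by root polishing, and classifies
#' their stability by the sign of d(dF/dt)/dF.  Saddle-node (fold) points,
#' where the fixed-point count changes, are located by bisection on gamma.
#' Under the default response shape there is a single (healthy, F = 0)
#' state at gamma = 0, a bistable band of three fixed points at
#' intermediate gamma (hysteresis), and a single high state at large
#' gamma.
#'
#' @param params a [pcs_params()] (only the response constants are used).
#' @param gamma_grid sorted stress levels to scan (default 0 to 5).
#' @param f_max upper end of the F search range; default covers all roots,
#'   `1.5 * (max(gamma) + a) / c`.
#' @return An object of class `bifurcation_diagram`: `fixed_points` (a
#'   data.frame gamma, F, stable), `fold_points` (gamma values of the
#'   saddle-nodes), `gamma_grid`.
#' @examples
#' bd <- bifurcation_scan(pcs_params(r = 0.5), gamma_grid = seq(0, 4, 0.1))
#' bd$fold_points
#' @export
bifurcation_scan <- function(params, gamma_grid = seq(0, 5, by = 0.05),
                             f_max = NULL) {
  stopifnot(inherits(params, "pcs_params"))
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("gamma_grid must be sorted increasing", call. = FALSE)
  }
  if (is.null(f_max)) f_max <- 1.5 * (max(gamma_grid) + params$a) / params$c

  roots_at <- function(gam) {
    g <- function(F) gam + params$a * F^2 / (params$b^2 + F^2) - params$c * F
    Fs <- seq(0, f_max, length.out = 2000)
    gv <- g(Fs)
    roots <- numeric(0)
    if (abs(gv[1]) < 1e-12) roots <- 0
    sgn <- sign(gv)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in flips) {
      roots <- c(roots, stats::uniroot(g, c(Fs[i], Fs[i + 1]),
                                       tol = 1e-12)$root)
    }
    # grid points that are themselves numerical zeros (tangencies)
    roots <- sort(unique(signif(roots, 10)))
    if (length(roots) == 0) {
      stop("no fixed point found: response-shape contract violated",
           call. = FALSE)
    }
    roots
  }

  fps <- do.call(rbind, lapply(gamma_grid, function(gam) {
    Fst <- roots_at(gam)
    data.frame(gamma = gam, F = Fst,
               stable = stress_response_dfdF(Fst, params) < 0)
  }))

  counts <- vapply(gamma_grid, function(gam) length(roots_at(gam)),
                   integer(1))
  folds <- numeric(0)
  for (i in which(diff(counts) != 0)) {
    lo <- gamma_grid[i]; hi <- gamma_grid[i + 1]
    n_lo <- counts[i]
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      if (length(roots_at(mid)) == n_lo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }

  structure(list(fixed_points = fps, fold_points = folds,
                 gamma_grid = gamma_grid, params = params),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation scan over gamma in [%g, %g] (%d levels)\n",
              min(x$gamma_grid), max(x$gamma_grid), length(x$gamma_grid)))
  cat(sprintf("  fold (saddle-node) points: %s\n",
              if (length(x$fold_points)) {
                paste(sprintf("%.4g", x$fold_points), collapse = ", ")
              } else "none in range"))
  invisible(x)
}

#' One-at-a-time parameter sensitivity of the PD curve
#'
#' Perturbs each applicable parameter (r, f1, f2, f3, K, and alpha/beta
#' for a linear accumulating-stress protocol) up and down by a fraction
#' `perturbation`, re-simulates, and reports the L2 distance between
#' perturbed and baseline PD curves together with the largest change in
#' terminal state fractions.  Parameters are ranked by the mean of the
#' up/down PD-curve distances.
#'
#' @param params baseline [pcs_params()].
#' @param protocol a [stress_protocol].
#' @param perturbation relative perturbation (default 0.1, i.e. +/-10%).
#' @param initial,grid,t_end simulation settings as in [simulate_pcs()].
#' @return An object of class `sensitivity_report`: data.frame `deltas`
#'   (parameter, delta_pd_up/down, mean delta, terminal-fraction delta,
#'   rank) sorted by rank, and the simulation failures (if any) excluded
#'   from the ranking with a warning.
#' @export
sensitivity_analysis <- function(params, protocol, perturbation = 0.1,
                                 initial = cell_state(P = 1e5),
                                 t_end = NULL, grid = NULL) {
  stopifnot(inherits(params, "pcs_params"), inherits(protocol, "stress_protocol"))
  base <- simulate_pcs(params, protocol, initial = initial, t_end = t_end,
                       grid = grid)
  grid <- base$trajectory$time
  base_pd <- base$trajectory$pd
  base_fr <- state_fractions(base)
  nlast <- nrow(base_fr)

  pnames <- c("r", "f1", "f2", "f3", "K")
  if (protocol$kind == "linear") pnames <- c(pnames, "alpha", "beta")

  one <- function(name, fac) {
    p2 <- params; prot2 <- protocol
    if (name %in% c("alpha", "beta")) {
      prot2[[name]] <- protocol[[name]] * fac
      class(prot2) <- "stress_protocol"
    } else {
      p2[[name]] <- params[[name]] * fac
      class(p2) <- "pcs_params"
    }
    sim <- try(simulate_pcs(p2, prot2, initial = initial, grid = grid),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(NULL)
    fr <- state_fractions(sim)
    list(pd = sqrt(sum((sim$trajectory$pd - base_pd)^2)),
         frac = max(abs(unlist(fr[nlast, -1]) - unlist(base_fr[nlast, -1]))))
  }

  rows <- list(); failed <- character(0)
  for (nm in pnames) {
    up <- one(nm, 1 + perturbation)
    dn <- one(nm, 1 - perturbation)
    if (is.null(up) || is.null(dn)) {
      failed <- c(failed, nm)
      next
    }
    rows[[nm]] <- data.frame(
      parameter = nm,
      delta_pd_up = up$pd, delta_pd_down = dn$pd,
      delta_pd = (up$pd + dn$pd) / 2,
      delta_frac = max(up$frac, dn$frac))
  }
  if (length(failed)) {
    warning("simulation failed for perturbed parameter(s): ",
            paste(failed, collapse = ", "), "; excluded from ranking")
  }
  deltas <- do.call(rbind, rows)
  deltas <- deltas[order(-deltas$delta_pd), , drop = FALSE]
  deltas$rank <- seq_len(nrow(deltas))
  rownames(deltas) <- NULL
  structure(list(deltas = deltas, perturbation = perturbation,
                 failed = failed, baseline_pd_norm = sqrt(sum(base_pd^2))),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity (one-at-a-time, +/-%g%%), ranked by PD-curve L2:\n",
              100 * x$perturbation))
  print(x$deltas[, c("parameter", "delta_pd", "delta_frac", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' Compare model state fractions with marker-positive fractions
#'
#' Pairs simulated compartment fractions with observed (or synthetic)
#' marker-positive fractions under the mapping p21 -> arrested (C + S)
#' and SA-b-Gal -> senescent (S): p21 marks cell-cycle arrest generally,
#' SA-b-Gal specifically marks the senescent state.  p16 and SAHF are
#' treated as qualitative markers and are not mapped.  A small RMSE
#' supports the marker as a quantitative readout of the mapped state.
#'
#' @param result a `pcs_sim` from [simulate_pcs()].
#' @param markers list of `marker_series` (see [generate_marker_series()]).
#' @param mapping named character vector marker -> one of `"arrested"`,
#'   `"senescent"`, `"proliferating"`.
#' @return data.frame with one row per marker: marker, n_times, rmse,
#'   plus a `residuals` attribute holding the per-time residual table.
#' @export
marker_comparison <- function(result, markers,
                              mapping = c(p21 = "arrested",
                                          `SA-b-Gal` = "senescent")) {
  stopifnot(inherits(result, "pcs_sim"))
  fr <- state_fractions(result)
  model_col <- c(proliferating = "frac_P", arrested = "frac_arrested",
                 senescent = "frac_S")
  res_rows <- list(); summ <- list()
  for (m in markers) {
    stopifnot(inherits(m, "marker_series"))
    if (!m$marker %in% names(mapping)) {
      stop(sprintf("no state mapping for marker '%s'", m$marker),
           call. = FALSE)
    }
    if (min(m$times) < min(fr$time) || max(m$times) > max(fr$time)) {
      stop("marker times outside the simulation horizon", call. = FALSE)
    }
    target <- model_col[[mapping[[m$marker]]]]
    model_frac <- stats::approx(fr$time, fr[[target]], xout = m$times)$y
    resid <- m$fraction_positive - model_frac
    res_rows[[m$marker]] <- data.frame(marker = m$marker, time = m$times,
                                       observed = m$fraction_positive,
                                       model = model_frac, residual = resid)
    summ[[m$marker]] <- data.frame(marker = m$marker,
                                   n_times = length(m$times),
                                   rmse = sqrt(mean(resid^2)))
  }
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  attr(out, "residuals") <- do.call(rbind, res_rows)
  out
}
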