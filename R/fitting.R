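#' Observed or simulated growth curve
#'
#' A growth curve is a (time, PD) series for one experimental condition,
#' the primary observable of the study designs emulated here.
#'
#' @param condition condition label (character scalar).
#' @param times sampling times in days (strictly increasing).
#' @param pd cumulative population doublings at `times` (finite).
#' @return An object of class `growth_curve`.
#' @examples
#' growth_curve("control", 0:5, 0.7 * (0:5) / log(2))
#' @export
growth_curve <- function(condition, times, pd) {
  times <- as.numeric(times); pd <- as.numeric(pd)
  if (length(times) != length(pd)) {
    stop("times and pd must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(pd))) stop("pd values must be finite", call. = FALSE)
  structure(list(condition = as.character(condition)[1], times = times,
                 pd = pd), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve '%s': %d points, t in [%g, %g] d, PD in [%g, %g]\n",
              x$condition, length(x$times), min(x$times), max(x$times),
              min(x$pd), max(x$pd)))
  invisible(x)
}

new_fit_result <- function(params, extra = list(), residual_norm, n_starts,
                           converged, per_start = NULL, identifiable = NULL) {
  structure(list(params = params, extra = extra,
                 residual_norm = residual_norm, n_starts = n_starts,
                 converged = converged, per_start = per_start,
                 identifiable = identifiable),
            class = "pcs_fit")
}

#' @export
print.pcs_fit <- function(x, ...) {
  cat("P-C-S least-squares fit\n")
  est <- c(unlist(x$params[c("r", "f1", "f2", "f3")]), unlist(x$extra))
  cat("  estimates:", paste(sprintf("%s = %.4g", names(est), est),
                            collapse = ", "), "\n")
  cat(sprintf("  residual norm (SSR on PD): %.4g; %d start(s); converged: %s\n",
              x$residual_norm, x$n_starts, x$converged))
  if (!is.null(x$identifiable) && !all(x$identifiable)) {
    cat("  WARNING: flat directions flagged for:",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the constant-growth model to a PD curve
#'
#' Estimates the single proliferation rate `r` of the one-compartment
#' exponential model by least squares on the PD scale: the model PD curve
#' is the line `r * t / ln 2` through the origin, so the estimate has the
#' closed form `r = ln 2 * sum(t * pd) / sum(t^2)`.  The fit is performed
#' numerically (1-D minimization of the PD residual sum of squares) so it
#' shares the code path of the other fitters; the closed form is the
#' independent check used in the package tests.
#'
#' @param curve a [growth_curve()] with at least two points.
#' @return A `pcs_fit` object; the estimate is `$params$r`.
#' @examples
#' cv <- growth_curve("HeLa", 0:9, 0.70 * (0:9) / log(2))
#' fit_constant_growth(cv)$params$r
#' @export
fit_constant_growth <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$times) < 2) {
    stop("need at least two points to fit a growth rate", call. = FALSE)
  }
  tt <- curve$times - curve$times[1]
  ssr <- function(r) sum((curve$pd - (curve$pd[1] + r * tt / log(2)))^2)
  opt <- stats::optimize(ssr, interval = c(0, 100), tol = 1e-12)
  r_hat <- opt$minimum
  # polish the flat-curve boundary: optimize() cannot land exactly on 0
  if (ssr(0) <= opt$objective) r_hat <- 0
  fit <- new_fit_result(pcs_params(r = r_hat), residual_norm = ssr(r_hat),
                        n_starts = 1, converged = TRUE,
                        identifiable = c(r = TRUE))
  fit
}

#' Fit the two-state arrest extension with r and f2 fixed
#'
#' Reduced model without senescence (f3 = 0) and with the stress response
#' saturated (normalized response fixed at 1): P cells leave the cycle at
#' rate `f1` and return at `f2`.  With `r` pinned to a reference maximal
#' rate (0.70 per day, the fastest observed constant-growth rate) the
#' apparent growth rate of a slower line is explained by its standing
#' arrested fraction, and `f1` is the single fitted parameter.  The
#' asymptotic PD slope is the dominant eigenvalue of
#' `[[r - f1, f2], [f1, -f2]]` divided by ln 2, monotonically decreasing
#' in `f1`.
#'
#' @param curve a [growth_curve()].
#' @param r_fixed fixed proliferation rate (default 0.70 per day).
#' @param f2_fixed fixed return rate (default 1 per day).
#' @return A `pcs_fit`; the estimate is `$params$f1`.
#' @examples
#' cv <- two_state_curve(f1 = 2, times = 0:12)
#' fit_two_state_f1(cv)$params$f1
#' @export
fit_two_state_f1 <- function(curve, r_fixed = 0.70, f2_fixed = 1) {
  stopifnot(inherits(curve, "growth_curve"))
  if (r_fixed <= 0) stop("r_fixed must be positive", call. = FALSE)
  if (length(curve$times) < 2) {
    stop("need at least two points to fit f1", call. = FALSE)
  }
  ssr <- function(f1) {
    pd <- two_state_pd(r_fixed, f1, f2_fixed, curve$times)
    sum((curve$pd - pd)^2)
  }
  opt <- stats::optimize(ssr, interval = c(0, 100), tol = 1e-10)
  f1_hat <- opt$minimum
  if (ssr(0) <= opt$objective) f1_hat <- 0
  new_fit_result(pcs_params(r = r_fixed, f1 = f1_hat, f2 = f2_fixed),
                 residual_norm = ssr(f1_hat), n_starts = 1, converged = TRUE,
                 identifiable = c(f1 = TRUE))
}

# PD curve of the two-state model (f3 = 0, response saturated), via the
# production solver.
two_state_pd <- function(r, f1, f2, times) {
  p <- pcs_params(r = r, f1 = f1, f2 = f2, f3 = 0)
  sim <- simulate_pcs(p, stress_none(), initial = cell_state(P = 1),
                      grid = times, f_hat = 1, extinction = FALSE)
  sim$trajectory$pd
}

#' Noiseless two-state PD curve (helper for recovery studies)
#'
#' @param f1 arrest rate used to generate the curve.
#' @param times sampling times (days).
#' @param r,f2 fixed rates of the reduced model.
#' @return A [growth_curve()].
#' @export
two_state_curve <- function(f1, times, r = 0.70, f2 = 1) {
  growth_curve(sprintf("two_state_f1_%g", f1), times,
               two_state_pd(r, f1, f2, times))
}

# ---- multi-start least squares machinery -------------------------------

# Residual-based multi-start Levenberg-Marquardt in log10 parameter space.
# resid_fn(par_natural) -> numeric residual vector (PD scale).
multistart_lm <- function(resid_fn, par_names, lower, upper, n_starts, seed,
                          n_resid, maxiter = 200, ridge = NULL) {
  np <- length(par_names)
  llo <- log10(lower); lhi <- log10(upper)
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, np)
  starts <- sweep(sweep(starts, 2, lhi - llo, "*"), 2, llo, "+")

  run_one <- function(lpar0) {
    fn <- function(lpar) {
      r <- try(resid_fn(10^lpar), silent = TRUE)
      if (inherits(r, "try-error") || length(r) != n_resid ||
            any(!is.finite(r))) {
        return(rep(1e3, n_resid))
      }
      r
    }
    fit <- try(minpack.lm::nls.lm(
      par = lpar0, lower = llo, upper = lhi, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(fit$par)) ||
          !is.finite(fit$deviance)) {
      return(list(par = 10^lpar0, ssr = Inf, ok = FALSE, info = -1))
    }
    list(par = 10^fit$par, ssr = fit$deviance,
         ok = fit$info %in% 1:4, info = fit$info)
  }

  results <- lapply(seq_len(n_starts), function(i) run_one(starts[i, ]))
  ssrs <- vapply(results, function(x) x$ssr, numeric(1))
  if (all(!is.finite(ssrs))) {
    stop("no start converged in multi-start least squares", call. = FALSE)
  }
  best <- results[[which.min(ssrs)]]
  # Polish from the incumbent.  A plain restart resets the trust region;
  # in addition, when a near-flat exchange ridge is declared (`ridge`:
  # indices of rates whose joint rescaling barely changes the curves,
  # e.g. the fast P<->C exchange pair f1, f2), restart from co-scaled
  # copies of the incumbent to escape ridge stalls at the bounds.
  scales <- c(1, if (!is.null(ridge)) c(0.8, 1.25, 0.5, 2, 0.25, 0.125))
  for (round in 1:4) {
    cand <- lapply(scales, function(s) {
      p0 <- best$par
      if (s != 1) p0[ridge] <- p0[ridge] * s
      p0 <- pmin(pmax(p0, 10^llo), 10^lhi)
      run_one(log10(p0))
    })
    cssr <- vapply(cand, function(x) x$ssr, numeric(1))
    if (!any(is.finite(cssr)) || min(cssr) >= best$ssr * (1 - 1e-8)) break
    best <- cand[[which.min(cssr)]]
  }
  per_start <- data.frame(start = seq_len(n_starts),
                          do.call(rbind, lapply(seq_len(n_starts), function(i) {
                            stats::setNames(10^starts[i, ], par_names)
                          })),
                          ssr = ssrs,
                          converged = vapply(results, function(x) x$ok,
                                             logical(1)))
  names(best$par) <- par_names
  list(par = best$par, ssr = best$ssr, converged = best$ok,
       per_start = per_start)
}

# Flat-direction flags from finite-difference profile curvature of the SSR.
identifiability_flags <- function(resid_fn, par, rel_step = 0.02,
                                  tol = 1e-6) {
  ssr0 <- sum(resid_fn(par)^2)
  vapply(seq_along(par), function(i) {
    d <- numeric(0)
    for (s in c(1 - rel_step, 1 + rel_step)) {
      p <- par
      p[i] <- par[i] * s + (par[i] == 0) * rel_step
      ss <- try(sum(resid_fn(p)^2), silent = TRUE)
      if (!inherits(ss, "try-error") && is.finite(ss)) d <- c(d, ss - ssr0)
    }
    length(d) > 0 && max(abs(d)) > tol * (1 + ssr0)
  }, logical(1))
}

#' Joint fit of the full model to multi-dose irradiation PD curves
#'
#' Estimates one shared parameter set (r, f1, f2, f3) from several PD
#' curves measured under different irradiation doses, exactly one stress
#' protocol per curve (the conditions differ only in exposure time; the
#' stress amplitude gamma is a fixed input, never fitted, because gamma
#' and f1 are confounded).  The pooled PD residual sum of squares is
#' minimized by multi-start Levenberg-Marquardt from a seeded
#' Latin-hypercube of starting points in log-parameter space, with all
#' rates bounded in [1e-3, 100] per day.
#'
#' @param curves list of [growth_curve()] objects.
#' @param protocols list of [stress_protocol] objects, same length.
#' @param params_template a [pcs_params()] supplying the response-shape
#'   constants (K, a, b, c), which are not fitted.
#' @param initial initial state shared by all conditions (default
#'   `cell_state(P = 100)`, the seeding scale of the irradiation designs).
#' @param n_starts number of multi-start points (default 16).
#' @param seed RNG seed for the start sequence (fits are deterministic
#'   given seed and inputs).
#' @param lower,upper bounds on the fitted rates (per day).
#' @return A `pcs_fit` with fitted `$params`, pooled `$residual_norm`,
#'   a `$per_start` log, and `$identifiable` flags from finite-difference
#'   profile curvature (flat directions are flagged, not silently
#'   returned).
#' @export
fit_joint_irradiation <- function(curves, protocols,
                                  params_template = pcs_params(r = 0.5),
                                  initial = cell_state(P = 100),
                                  n_starts = 16, seed = 1,
                                  lower = 1e-3, upper = 100) {
  if (length(curves) < 1) {
    stop("no curves supplied", call. = FALSE)
  }
  if (length(curves) < 2) {
    warning("only one condition supplied; the stress-response rates are ",
            "unlikely to be identifiable (see the identifiable flags)")
  }
  if (length(curves) != length(protocols)) {
    stop("curves and protocols must have equal length", call. = FALSE)
  }
  par_names <- c("r", "f1", "f2", "f3")
  resid_fn <- function(par) {
    p <- pcs_params(r = par[1], f1 = par[2], f2 = par[3], f3 = par[4],
                    K = params_template$K, a = params_template$a,
                    b = params_template$b, c = params_template$c)
    unlist(lapply(seq_along(curves), function(i) {
      sim <- simulate_pcs(p, protocols[[i]], initial = initial,
                          grid = curves[[i]]$times)
      sim$trajectory$pd - curves[[i]]$pd
    }))
  }
  n_resid <- sum(vapply(curves, function(cv) length(cv$times), integer(1)))
  ms <- multistart_lm(resid_fn, par_names, rep(lower, 4), rep(upper, 4),
                      n_starts, seed, n_resid = n_resid, ridge = c(2, 3))
  if (!ms$converged && !is.finite(ms$ssr)) {
    stop("joint irradiation fit failed to converge from any start",
         call. = FALSE)
  }
  params <- pcs_params(r = ms$par[["r"]], f1 = ms$par[["f1"]],
                       f2 = ms$par[["f2"]], f3 = ms$par[["f3"]],
                       K = params_template$K, a = params_template$a,
                       b = params_template$b, c = params_template$c)
  ident <- identifiability_flags(resid_fn, ms$par)
  names(ident) <- par_names
  new_fit_result(params, residual_norm = ms$ssr, n_starts = n_starts,
                 converged = ms$converged, per_start = ms$per_start,
                 identifiable = ident)
}

#' Fit the full model to a replicative-senescence PD curve
#'
#' A long-horizon culture accumulating stress gamma(t) = alpha + beta * t.
#' Because a single curve cannot identify all six parameters, the fit
#' works in one of two modes: `what = "rates"` fits the kinetic rates
#' (r, f1, f2, f3) with (alpha, beta) fixed at their supplied values;
#' `what = "stress"` fits (alpha, beta) with the kinetic rates fixed.
#'
#' @param curve a [growth_curve()] spanning the arrest plateau.
#' @param params a [pcs_params()]: the fixed kinetic rates
#'   (`what = "stress"`) or the response-shape template (`what = "rates"`).
#' @param alpha,beta accumulating-stress coefficients (fixed when fitting
#'   rates; starting bounds apply when fitted).
#' @param what which parameter subset to fit.
#' @param initial initial state (default `cell_state(P = 1e5)`).
#' @param n_starts,seed multi-start settings as in
#'   [fit_joint_irradiation()].
#' @return A `pcs_fit`; fitted stress coefficients are in `$extra`.
#' @export
fit_replicative <- function(curve, params, alpha, beta,
                            what = c("rates", "stress"),
                            initial = cell_state(P = 1e5),
                            n_starts = 16, seed = 1) {
  stopifnot(inherits(curve, "growth_curve"), inherits(params, "pcs_params"))
  what <- match.arg(what)
  sim_pd <- function(p, prot) {
    simulate_pcs(p, prot, initial = initial,
                 grid = curve$times)$trajectory$pd
  }
  if (what == "rates") {
    prot <- stress_linear(alpha, beta)
    resid_fn <- function(par) {
      p <- pcs_params(r = par[1], f1 = par[2], f2 = par[3], f3 = par[4],
                      K = params$K, a = params$a, b = params$b, c = params$c)
      sim_pd(p, prot) - curve$pd
    }
    ms <- multistart_lm(resid_fn, c("r", "f1", "f2", "f3"),
                        rep(1e-3, 4), rep(100, 4), n_starts, seed,
                        n_resid = length(curve$times), ridge = c(2, 3))
    fitted <- pcs_params(r = ms$par[["r"]], f1 = ms$par[["f1"]],
                         f2 = ms$par[["f2"]], f3 = ms$par[["f3"]],
                         K = params$K, a = params$a, b = params$b,
                         c = params$c)
    ident <- identifiability_flags(resid_fn, ms$par)
    names(ident) <- c("r", "f1", "f2", "f3")
    new_fit_result(fitted, extra = list(alpha = alpha, beta = beta),
                   residual_norm = ms$ssr, n_starts = n_starts,
                   converged = ms$converged, per_start = ms$per_start,
                   identifiable = ident)
  } else {
    resid_fn <- function(par) {
      sim_pd(params, stress_linear(par[1], par[2])) - curve$pd
    }
    ms <- multistart_lm(resid_fn, c("alpha", "beta"),
                        rep(1e-5, 2), rep(1, 2), n_starts, seed,
                        n_resid = length(curve$times))
    ident <- identifiability_flags(resid_fn, ms$par)
    names(ident) <- c("alpha", "beta")
    new_fit_result(params,
                   extra = list(alpha = ms$par[["alpha"]],
                                beta = ms$par[["beta"]]),
                   residual_norm = ms$ssr, n_starts = n_starts,
                   converged = ms$converged, per_start = ms$per_start,
                   identifiable = ident)
  }
}
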