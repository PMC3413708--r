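#' Simulate the P-C-S-F model
#'
#' Integrates the compartment model under a stress protocol and returns
#' the trajectory together with the population-doubling (PD) curve,
#' PD(t) = log2(total(t) / total(0)) with total = P + C + S (experimental
#' PDs count every cell in the dish, not only proliferating ones).
#'
#' Integration uses a stiff-capable solver (deSolve's `lsoda`, compiled
#' right-hand side) with the solver restarted exactly at pulse edges, so
#' short irradiation pulses are never stepped over.  While proliferation
#' is active the solver monitors the population-extinction event: when P
#' first crosses below `extinction_threshold` (one cell, in the
#' concentration units of the initial state), proliferation is switched
#' off permanently and integration continues, so C cells keep converting
#' to S while the PD curve stays on its plateau.
#'
#' @param params a [pcs_params()] object.
#' @param protocol a [stress_protocol] (default: no stress).
#' @param initial initial state; default `cell_state(P = 1e5)` with
#'   C = S = 0 and F at the healthy fixed point F = 0.
#' @param t_end end of the integration (days); ignored when `grid` is given.
#' @param grid sampling times (days, strictly increasing, first >= 0);
#'   default 201 equally spaced points on `[0, t_end]`.
#' @param f_hat optional fixed normalized response (reduced models:
#'   `f_hat = 1` is the saturated constant-stress limit, `f_hat = 0`
#'   disables arrest entirely); `NULL` for the dynamic switch.
#' @param extinction logical; monitor the extinction event (default TRUE).
#' @param extinction_threshold population level below which proliferation
#'   is irrecoverably lost (default 1).
#' @param rtol,atol solver tolerances (the response switch makes the
#'   system locally stiff; defaults 1e-8 / 1e-10).
#' @return An object of class `pcs_sim`: a list with elements
#'   `trajectory` (data.frame time, P, C, S, F, pd), `terminated`
#'   (logical), `t_event` (event time or NA), and the inputs.
#' @examples
#' p <- pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26)
#' sim <- simulate_pcs(p, t_end = 10, grid = 0:10)
#' sim$trajectory$pd   # a straight line of slope r / ln 2 under no stress
#' @export
simulate_pcs <- function(params, protocol = stress_none(),
                         initial = cell_state(P = 1e5),
                         t_end = NULL, grid = NULL, f_hat = NULL,
                         extinction = TRUE, extinction_threshold = 1,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pcs_params"), inherits(protocol, "stress_protocol"))
  initial <- as_cell_state(initial)
  if (is.null(grid)) {
    if (is.null(t_end) || t_end <= 0) {
      stop("provide t_end > 0 or an explicit sampling grid", call. = FALSE)
    }
    grid <- seq(0, t_end, length.out = 201)
  }
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0) || grid[1] < 0) {
    stop("grid must be strictly increasing with first time >= 0", call. = FALSE)
  }
  total0 <- sum(initial[c("P", "C", "S")])
  if (total0 <= 0) stop("initial total population must be positive", call. = FALSE)
  if (!is.null(f_hat) && (!is.finite(f_hat) || f_hat < 0)) {
    stop("f_hat must be non-negative", call. = FALSE)
  }

  t0 <- grid[1]; t1 <- grid[length(grid)]
  if (params$r * (t1 - t0) > 500) {
    # e^{r t} would overflow double precision; refuse early with a clear
    # error rather than letting the solver grind against Inf
    stop("population overflow: r * horizon exceeds floating-point range",
         call. = FALSE)
  }
  seg_bounds <- sort(unique(c(t0, protocol_breaks(protocol, t0, t1), t1)))

  prolif_on <- TRUE
  terminated <- FALSE
  t_event <- NA_real_
  if (extinction && initial[["P"]] <= extinction_threshold) {
    prolif_on <- FALSE
    terminated <- TRUE
    t_event <- t0
  }

  y <- unclass(initial)
  rows <- matrix(c(t0, y), nrow = 1)
  for (k in seq_len(length(seg_bounds) - 1)) {
    s0 <- seg_bounds[k]; s1 <- seg_bounds[k + 1]
    gpts <- grid[grid > s0 & grid <= s1]
    res <- integrate_segment(y, s0, s1, gpts, params, protocol,
                             prolif_on, f_hat,
                             extinction && !terminated, extinction_threshold,
                             rtol, atol)
    if (res$event_fired) {
      terminated <- TRUE
      prolif_on <- FALSE
      t_event <- res$t_event
    }
    if (nrow(res$rows) > 0) rows <- rbind(rows, res$rows)
    y <- res$y_end
  }

  traj <- as.data.frame(rows)
  names(traj) <- c("time", "P", "C", "S", "F")
  # keep requested grid times only (segment endpoints may duplicate them)
  idx <- vapply(grid, function(tt) {
    which.min(abs(traj$time - tt))
  }, integer(1))
  traj <- traj[idx, , drop = FALSE]
  traj$time <- grid
  rownames(traj) <- NULL
  total <- traj$P + traj$C + traj$S
  traj$pd <- log2(total / total0)
  traj$pd[1] <- 0  # exact anchor at the sampling origin

  structure(list(trajectory = traj, terminated = terminated,
                 t_event = t_event, params = params, protocol = protocol,
                 initial = initial, f_hat = f_hat,
                 extinction_threshold = extinction_threshold),
            class = "pcs_sim")
}

# Integrate one smooth segment [s0, s1]; returns output rows at the
# requested grid points, the state at s1, and event information.
integrate_segment <- function(y, s0, s1, gpts, params, protocol, prolif_on,
                              f_hat, watch_event, threshold, rtol, atol) {
  if (watch_event && y[[1]] <= threshold) {
    # already at/below the threshold when the segment opens (e.g. the root
    # coincided with a previous segment boundary): fire immediately
    res <- integrate_segment(y, s0, s1, gpts, params, protocol,
                             prolif_on = FALSE, f_hat = f_hat,
                             watch_event = FALSE, threshold = threshold,
                             rtol = rtol, atol = atol)
    res$event_fired <- TRUE
    res$t_event <- s0
    return(res)
  }
  coef <- protocol_segment_coef(protocol, (s0 + s1) / 2)
  parms <- c(r = if (prolif_on) params$r else 0,
             f1 = params$f1, f2 = params$f2, f3 = params$f3,
             K = params$K, a = params$a, b = params$b, c = params$c,
             g0 = coef[1], g1 = coef[2],
             fhat = if (is.null(f_hat)) -1 else f_hat,
             thresh = threshold)
  times <- sort(unique(c(s0, gpts, s1)))

  run <- function(y0, tt, parms, root) {
    out <- if (root) {
      deSolve::lsodar(y = y0, times = tt, func = "pcs_derivs", parms = parms,
                      dllname = "pcskinetics", initfunc = "pcs_initmod",
                      rootfunc = "pcs_root", nroot = 1,
                      rtol = rtol, atol = atol)
    } else {
      deSolve::lsoda(y = y0, times = tt, func = "pcs_derivs", parms = parms,
                     dllname = "pcskinetics", initfunc = "pcs_initmod",
                     rtol = rtol, atol = atol)
    }
    istate <- attr(out, "istate")[1]
    if (!is.null(istate) && istate < 0) {
      stop(sprintf(
        "ODE solver failed (istate = %d); last successful time %.6g days",
        istate, max(out[, 1])), call. = FALSE)
    }
    out
  }

  out <- run(y, times, parms, root = watch_event)
  troot <- attr(out, "troot")
  event_fired <- watch_event && length(troot) > 0 && !is.na(troot[1]) &&
    troot[1] < s1 - 1e-12

  if (!event_fired) {
    keep <- out[out[, 1] %in% gpts, , drop = FALSE]
    return(list(rows = unname(keep), y_end = out[nrow(out), -1],
                event_fired = FALSE, t_event = NA_real_))
  }

  # event inside the segment: keep pre-event grid rows, then continue from
  # the root with proliferation permanently off
  te <- troot[1]
  pre <- out[out[, 1] %in% gpts & out[, 1] <= te, , drop = FALSE]
  y_event <- out[nrow(out), -1]
  parms["r"] <- 0
  gpts2 <- gpts[gpts > te]
  times2 <- sort(unique(c(te, gpts2, s1)))
  out2 <- run(y_event, times2, parms, root = FALSE)
  post <- out2[out2[, 1] %in% gpts2, , drop = FALSE]
  list(rows = unname(rbind(pre, post)), y_end = out2[nrow(out2), -1],
       event_fired = TRUE, t_event = te)
}

#' @export
print.pcs_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("P-C-S simulation: %d time points on [%g, %g] days\n",
              nrow(tr), tr$time[1], tr$time[nrow(tr)]))
  cat(sprintf("  final PD = %.3f; final fractions P/C/S = %.3f/%.3f/%.3f\n",
              tr$pd[nrow(tr)],
              tr$P[nrow(tr)] / sum(tr[nrow(tr), c("P", "C", "S")]),
              tr$C[nrow(tr)] / sum(tr[nrow(tr), c("P", "C", "S")]),
              tr$S[nrow(tr)] / sum(tr[nrow(tr), c("P", "C", "S")])))
  if (x$terminated) {
    cat(sprintf("  extinction event: proliferation lost at t = %.4g days\n",
                x$t_event))
  }
  invisible(x)
}

#' Compartment fractions along a trajectory
#'
#' @param result a `pcs_sim` object from [simulate_pcs()].
#' @return A data.frame with columns time, frac_P, frac_C, frac_S and
#'   frac_arrested (= C + S over total, the model counterpart of
#'   arrest-marker-positive fractions); rows sum to 1 over P, C, S.
#' @examples
#' p <- pcs_params(r = 0.5)
#' state_fractions(simulate_pcs(p, t_end = 5, grid = 0:5))
#' @export
state_fractions <- function(result) {
  stopifnot(inherits(result, "pcs_sim"))
  tr <- result$trajectory
  total <- tr$P + tr$C + tr$S
  if (any(total <= 0)) {
    stop("total population is zero at some requested times", call. = FALSE)
  }
  data.frame(time = tr$time,
             frac_P = tr$P / total,
             frac_C = tr$C / total,
             frac_S = tr$S / total,
             frac_arrested = (tr$C + tr$S) / total)
}
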