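# Run code with a seeded, isolated RNG stream; the caller's RNG state is
# untouched, and identical seeds give bit-identical draws.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic PD growth curves
#'
#' Simulates the model under each protocol, samples PD on the grid, and
#' adds independent Gaussian noise on the PD scale (PD is the fitted
#' observable; its measurement scatter is approximately additive).  The
#' default noise of 0.25 PD emulates the small but significant
#' differences reported between biological replicates; set
#' `noise_sd_pd = 0` for noiseless round-trip curves.
#'
#' @param params generating [pcs_params()].
#' @param protocols named list of [stress_protocol] objects (one curve per
#'   protocol; names become condition labels).
#' @param times sampling grid (days).
#' @param noise_sd_pd Gaussian noise standard deviation in PD units.
#' @param seed RNG seed; regeneration with the same seed is bit-exact.
#' @param initial initial state for every condition.
#' @return List of [growth_curve()] objects with attribute `truth`
#'   (generating parameters, protocols, noise and seed).
#' @examples
#' fx <- fixture_catalog()$WI38_irradiation
#' curves <- generate_growth_curves(fx$params, fx$protocols, times = 0:12,
#'                                  noise_sd_pd = 0, seed = 1,
#'                                  initial = fx$initial)
#' @export
generate_growth_curves <- function(params, protocols, times,
                                   noise_sd_pd = 0.25, seed = 1,
                                   initial = cell_state(P = 1e5)) {
  stopifnot(inherits(params, "pcs_params"))
  if (noise_sd_pd < 0) stop("noise_sd_pd must be >= 0", call. = FALSE)
  if (is.null(names(protocols))) {
    names(protocols) <- paste0("condition_", seq_along(protocols))
  }
  curves <- with_seed(seed, {
    lapply(names(protocols), function(nm) {
      sim <- simulate_pcs(params, protocols[[nm]], initial = initial,
                          grid = times)
      pd <- sim$trajectory$pd
      if (noise_sd_pd > 0) {
        pd <- pd + stats::rnorm(length(pd), sd = noise_sd_pd)
      }
      growth_curve(nm, times, pd)
    })
  })
  names(curves) <- names(protocols)
  attr(curves, "truth") <- list(params = params, protocols = protocols,
                                noise_sd_pd = noise_sd_pd, seed = seed,
                                initial = initial)
  curves
}

#' Marker-positive fraction series
#'
#' Constructor for an observed or synthetic series of marker-positive
#' cell fractions (immunofluorescence-style counts: `n_counted` cells
#' scored per replicate at each time).
#'
#' @param marker marker name (e.g. `"p21"`, `"p16"`, `"SA-b-Gal"`,
#'   `"SAHF"`, `"gammaH2AX"`).
#' @param times observation times (days).
#' @param fraction_positive mean fraction of positive cells in `[0, 1]`.
#' @param n_counted cells counted per replicate (default 100).
#' @param replicate_sd optional across-replicate standard deviation.
#' @param n_replicates number of replicates behind each mean (default 3).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(marker, times, fraction_positive, n_counted = 100,
                          replicate_sd = NULL, n_replicates = 3) {
  if (any(fraction_positive < 0 | fraction_positive > 1)) {
    stop("fraction_positive must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_counted < 1)) stop("n_counted must be >= 1", call. = FALSE)
  structure(list(marker = marker, times = as.numeric(times),
                 fraction_positive = as.numeric(fraction_positive),
                 n_counted = n_counted, replicate_sd = replicate_sd,
                 n_replicates = n_replicates),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("Marker series '%s': %d times, fraction in [%.3f, %.3f] (n = %d x %d)\n",
              x$marker, length(x$times), min(x$fraction_positive),
              max(x$fraction_positive), x$n_replicates, max(x$n_counted)))
  invisible(x)
}

#' Generate synthetic marker-count series from a simulation
#'
#' For each marker, each observation time and each replicate, draws the
#' number of positive cells among `n_counted` as a binomial count with
#' success probability equal to the mapped model state fraction (plus an
#' optional additive bias, clipped to `[0, 1]`), then reports the mean
#' fraction and across-replicate sd.  The bias hook emulates markers that
#' respond to causes other than the mapped state (e.g. a non-senescence
#' SA-b-Gal component).
#'
#' @param result a `pcs_sim` from [simulate_pcs()].
#' @param times observation times (subset of the simulation horizon).
#' @param marker_map named character vector marker -> state
#'   (`"proliferating"`, `"arrested"`, `"senescent"`), default
#'   `c(p21 = "arrested", "SA-b-Gal" = "senescent")`.
#' @param n_counted cells scored per replicate (default 100).
#' @param n_replicates replicates per time (default 3).
#' @param bias optional named list marker -> function(time) giving an
#'   additive probability component; probabilities are clipped to [0, 1]
#'   (a warning records any clipping).
#' @param seed RNG seed (bit-exact regeneration).
#' @return List of `marker_series` objects, one per mapped marker.
#' @export
generate_marker_series <- function(result, times,
                                   marker_map = c(p21 = "arrested",
                                                  `SA-b-Gal` = "senescent"),
                                   n_counted = 100, n_replicates = 3,
                                   bias = NULL, seed = 1) {
  stopifnot(inherits(result, "pcs_sim"))
  fr <- state_fractions(result)
  if (min(times) < min(fr$time) || max(times) > max(fr$time)) {
    stop("requested marker times outside the simulation horizon",
         call. = FALSE)
  }
  model_col <- c(proliferating = "frac_P", arrested = "frac_arrested",
                 senescent = "frac_S")
  with_seed(seed, {
    out <- lapply(names(marker_map), function(mk) {
      p <- stats::approx(fr$time, fr[[model_col[[marker_map[[mk]]]]]],
                         xout = times)$y
      if (!is.null(bias) && !is.null(bias[[mk]])) {
        p <- p + vapply(times, bias[[mk]], numeric(1))
        if (any(p < 0 | p > 1)) {
          warning(sprintf(
            "bias pushed probabilities outside [0, 1] for '%s'; clipped", mk))
        }
        p <- pmin(1, pmax(0, p))
      }
      draws <- matrix(stats::rbinom(length(times) * n_replicates,
                                    size = n_counted,
                                    prob = rep(p, each = n_replicates)),
                      nrow = n_replicates) / n_counted
      marker_series(mk, times,
                    fraction_positive = colMeans(draws),
                    n_counted = n_counted,
                    replicate_sd = apply(draws, 2, stats::sd),
                    n_replicates = n_replicates)
    })
    names(out) <- names(marker_map)
    out
  })
}

#' Catalog of printed parameter fixtures
#'
#' Named, immutable truth sets used throughout the recovery studies:
#' the fitted irradiation-response parameter sets for WI-38 and MRC-5
#' fibroblasts (one shared set per line across three doses, with the
#' stress amplitude and exposure times of each dose), the replicative
#' (accumulating-stress) sets for WI-38, BJ and MRC-5 together with
#' their stress-accrual coefficients (alpha, beta), and the
#' constant-growth rates / two-state arrest rates fitted across cell
#' lines (see [table1_growth_rates()], [table2_arrest_rates()]).
#'
#' Irradiation fixtures carry the experiment design: seeding one day
#' before exposure at 100 concentration units (so that a high dose can
#' drive P below the extinction threshold of one), exposure times of the
#' three doses, and a 14-day observation window.  Replicative fixtures
#' carry the accumulating-stress protocol and a horizon spanning the
#' arrest plateau.
#'
#' @return Named list of fixtures.  Each irradiation fixture has elements
#'   `params`, `gamma`, `protocols` (3 doses), `initial`, `times`,
#'   `note`; each replicative fixture has `params`, `alpha`, `beta`,
#'   `protocol`, `initial`, `times`, `note`.
#' @examples
#' names(fixture_catalog())
#' fixture_catalog()$WI38_irradiation$params
#' @export
fixture_catalog <- function() {
  irr <- function(line, r, f1, f2, f3, gamma, durations, t_end, note) {
    list(params = pcs_params(r = r, f1 = f1, f2 = f2, f3 = f3),
         gamma = gamma,
         protocols = stats::setNames(
           lapply(seq_along(durations), function(i) {
             irradiation_protocol(names(durations)[i], gamma, durations[[i]])
           }), names(durations)),
         initial = cell_state(P = 100),
         times = seq(0, t_end, by = 0.5),
         note = note)
  }
  rep_fix <- function(line, r, f1, f2, f3, alpha, beta, t_end, by, note) {
    list(params = pcs_params(r = r, f1 = f1, f2 = f2, f3 = f3),
         alpha = alpha, beta = beta,
         protocol = stress_linear(alpha, beta),
         initial = cell_state(P = 1e5),
         times = seq(0, t_end, by = by),
         note = note)
  }
  list(
    WI38_irradiation = irr(
      "WI-38", r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26, gamma = 2800,
      durations = c(`0Gy` = 0, `2Gy` = 108 / 86400, `15Gy` = 13.5 / 1440),
      t_end = 14,
      note = "WI-38 fibroblasts, joint fit across 0/2/15 Gy; stress level 2800 during exposure"),
    MRC5_irradiation = irr(
      "MRC-5", r = 0.51, f1 = 4.0, f2 = 16, f3 = 0.42, gamma = 8000,
      durations = c(`0Gy` = 0, `0.5Gy` = 27 / 86400, `20Gy` = 18 / 1440),
      t_end = 14,
      note = "MRC-5 fibroblasts, joint fit across 0/0.5/20 Gy; stress level 8000 during exposure"),
    WI38_replicative = rep_fix(
      "WI-38", r = 0.47, f1 = 0.40, f2 = 0.43, f3 = 0.66,
      alpha = 0.002, beta = 0.028, t_end = 150, by = 2,
      note = "WI-38 long-term culture under accumulating stress"),
    BJ_replicative = rep_fix(
      "BJ", r = 0.30, f1 = 1.1, f2 = 2.45, f3 = 0.27,
      alpha = 0.001, beta = 0.016, t_end = 280, by = 4,
      note = "BJ long-term culture under accumulating stress"),
    MRC5_replicative = rep_fix(
      "MRC-5", r = 0.489, f1 = 6.64, f2 = 5.99, f3 = 0.26,
      alpha = 0.004, beta = 0.0042, t_end = 700, by = 10,
      note = "MRC-5 long-term culture under accumulating stress")
  )
}

#' Constant-growth rates fitted per cell line
#'
#' Proliferation rates r (per day) from single-rate exponential fits of
#' unhampered growth across rodent fibroblast lines and HeLa; the spread
#' between slowest and fastest is a factor of about 7.8.
#'
#' @return data.frame with columns species, r.
#' @export
table1_growth_rates <- function() {
  data.frame(
    species = c("House mouse", "Embryonic squirrel", "Squirrel",
                "Naked mole rat", "Gerbil", "Chinchilla", "Rat", "Chipmunk",
                "Guinea pig", "Muskrat", "Hamster", "HeLa"),
    r = c(0.28, 0.20, 0.09, 0.16, 0.25, 0.13, 0.32, 0.13, 0.26, 0.15, 0.28,
          0.70))
}

#' Arrest rates f1 under a shared maximal proliferation rate
#'
#' Two-state-model arrest rates f1 (per day) that reproduce each line's
#' apparent growth with the proliferation rate fixed at the maximal
#' observed 0.70 per day and the return rate f2 fixed at 1: slower lines
#' carry a larger standing arrested fraction instead of a smaller r.
#'
#' @return data.frame with columns species, f1.
#' @export
table2_arrest_rates <- function() {
  data.frame(
    species = c("House mouse", "Embryonic squirrel", "Squirrel",
                "Naked mole rat", "Gerbil", "Chinchilla", "Rat", "Chipmunk",
                "Guinea pig", "Muskrat", "Hamster"),
    f1 = c(2.00, 3.02, 8.31, 3.83, 2.28, 5.01, 1.61, 4.84, 2.11, 4.12, 1.88))
}
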