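test_that("fate threshold matches arithmetic and the eigenvalue sign", {
  fc <- classify_fate(pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26))
  expect_equal(fc$r_crit, 3.8 * 0.26 / 16.26, tolerance = 1e-12)
  expect_true(fc$grows)
  expect_gt(fc$dominant_eigenvalue, 0)

  fc0 <- classify_fate(pcs_params(r = 0.1, f1 = 0, f2 = 1, f3 = 1))
  expect_equal(fc0$r_crit, 0)
  expect_true(fc0$grows)

  fcd <- classify_fate(pcs_params(r = 0.1, f1 = 2, f2 = 0, f3 = 0))
  expect_true(fcd$degenerate)
  expect_equal(fcd$r_crit, 2)
})

test_that("fate classification agrees with a simulation oracle", {
  # random parameter sets away from the threshold; saturated response
  set.seed(99)
  n_ok <- 0
  while (n_ok < 100) {
    p <- pcs_params(r = runif(1, 0.05, 1), f1 = 10^runif(1, -1, 1),
                    f2 = 10^runif(1, -1, 1.3), f3 = 10^runif(1, -1.3, 0.5))
    fc <- classify_fate(p)
    if (abs(p$r - fc$r_crit) < 0.1 * max(p$r, fc$r_crit)) next
    n_ok <- n_ok + 1
    # the model has no death, so "no growth" shows as a PD plateau, not a
    # decline: compare late PD gain with early PD gain
    sim <- simulate_pcs(p, stress_none(), initial = cell_state(P = 1e3),
                        grid = c(0, 200, 400), f_hat = 1,
                        extinction = FALSE)
    pd <- sim$trajectory$pd
    grows_sim <- (pd[3] - pd[2]) > 0.1 * (pd[2] - pd[1])
    expect_identical(fc$grows, grows_sim)
  }
})

test_that("bifurcation scan finds the healthy state, two folds, hysteresis", {
  p <- pcs_params(r = 0.5)
  bd <- bifurcation_scan(p, gamma_grid = seq(0, 5, by = 0.05))

  at0 <- bd$fixed_points[bd$fixed_points$gamma == 0, ]
  expect_equal(nrow(at0), 1)
  expect_equal(at0$F, 0, tolerance = 1e-9)
  expect_true(at0$stable)

  expect_length(bd$fold_points, 2)

  # in the bistable band there are three fixed points, stability alternating
  mid <- mean(bd$fold_points)
  idx <- which.min(abs(bd$gamma_grid - mid))
  band <- bd$fixed_points[bd$fixed_points$gamma == bd$gamma_grid[idx], ]
  expect_equal(nrow(band), 3)
  expect_identical(band$stable[order(band$F)], c(TRUE, FALSE, TRUE))

  # quasi-static hysteresis: the up-switch happens at a larger gamma than
  # the down-switch, and the loop enclosed is non-trivial
  gam_up <- seq(0, 4, by = 0.1)
  up <- sweep_F(gam_up, p)
  dn <- rev(sweep_F(rev(gam_up), p, relax_time = 40))
  switch_up <- gam_up[min(which(up > 10))]
  switch_dn <- gam_up[min(which(dn > 10))]
  expect_gt(switch_up, switch_dn)
  expect_gt(sum((dn - up) * 0.1), 1)  # loop area in F * gamma units
  expect_gt(switch_up, bd$fold_points[1])
  expect_lt(switch_dn, bd$fold_points[2])
})

test_that("fixed-point stability flags agree with perturbed relaxation", {
  p <- pcs_params(r = 0.5)
  bd <- bifurcation_scan(p, gamma_grid = seq(0, 5, by = 0.05))
  mid <- mean(bd$fold_points)
  gam <- bd$gamma_grid[which.min(abs(bd$gamma_grid - mid))]
  band <- bd$fixed_points[bd$fixed_points$gamma == gam, ]
  band <- band[order(band$F), ]
  eps <- 0.05
  for (i in seq_len(3)) {
    Fstar <- band$F[i]
    up <- relax_F(Fstar + eps, gam, p, t_end = 30)
    dn <- relax_F(max(Fstar - eps, 0), gam, p, t_end = 30)
    if (band$stable[i]) {
      expect_lt(abs(up - Fstar), 2 * eps)
      expect_lt(abs(dn - Fstar), 2 * eps)
    } else {
      expect_gt(abs(up - Fstar) + abs(dn - Fstar), 2 * eps)
    }
  }
})

test_that("sensitivity ranks r first and orders cell-line fragility", {
  cat_fx <- fixture_catalog()
  rel <- list()
  for (nm in c("WI38_replicative", "BJ_replicative", "MRC5_replicative")) {
    fx <- cat_fx[[nm]]
    sr <- sensitivity_analysis(fx$params, fx$protocol, initial = fx$initial,
                               grid = fx$times)
    expect_identical(sr$deltas$parameter[1], "r")
    rel[[nm]] <- stats::setNames(sr$deltas$delta_pd / sr$baseline_pd_norm,
                                 sr$deltas$parameter)
  }
  # WI-38 is less sensitive than BJ to the arrest-return and senescence
  # rates (relative PD-curve deltas)
  expect_lt(rel$WI38_replicative[["f2"]], rel$BJ_replicative[["f2"]])
  expect_lt(rel$WI38_replicative[["f3"]], rel$BJ_replicative[["f3"]])
})

test_that("sensitivity is exactly zero at zero perturbation and rank-stable", {
  fx <- fixture_catalog()$WI38_replicative
  sr0 <- sensitivity_analysis(fx$params, fx$protocol, initial = fx$initial,
                              grid = fx$times, perturbation = 0)
  expect_true(all(sr0$deltas$delta_pd == 0))
  expect_true(all(sr0$deltas$delta_frac == 0))

  coarse <- sensitivity_analysis(fx$params, fx$protocol,
                                 initial = fx$initial,
                                 grid = seq(0, 150, by = 4))
  fine <- sensitivity_analysis(fx$params, fx$protocol, initial = fx$initial,
                               grid = seq(0, 150, by = 2))
  # halving the sampling step must not change the ranking
  expect_identical(coarse$deltas$parameter, fine$deltas$parameter)
})

test_that("marker comparison scores quantitative vs confounded markers", {
  fx <- fixture_catalog()$WI38_replicative
  sim <- simulate_pcs(fx$params, fx$protocol, initial = fx$initial,
                      grid = fx$times)
  fr <- state_fractions(sim)
  mtimes <- seq(10, 140, by = 10)

  exact <- marker_series("SA-b-Gal", mtimes,
                         stats::approx(fr$time, fr$frac_S, mtimes)$y)
  cmp <- marker_comparison(sim, list(exact))
  expect_equal(cmp$rmse, 0, tolerance = 1e-12)

  expect_error(marker_comparison(sim, list(marker_series("Ki67", 10, 0.5))),
               "no state mapping")

  # binomially sampled counts sit near the sampling noise floor ...
  mk <- generate_marker_series(sim, mtimes, n_counted = 100,
                               n_replicates = 3, seed = 4)
  cmp2 <- marker_comparison(sim, mk)
  p_true <- stats::approx(fr$time, fr$frac_S, mtimes)$y
  floor_sabgal <- binomial_floor(p_true)
  expect_lt(cmp2$rmse[cmp2$marker == "SA-b-Gal"], 3 * floor_sabgal + 0.01)

  # ... while an additive non-senescence component (a confounded marker)
  # lifts the misfit far above the floor
  biased <- suppressWarnings(generate_marker_series(
    sim, mtimes, marker_map = c(`SA-b-Gal` = "senescent"),
    bias = list(`SA-b-Gal` = function(t) 0.3 * min(1, t / 60)),
    n_counted = 100, n_replicates = 3, seed = 4))
  cmp3 <- marker_comparison(sim, biased)
  expect_gt(cmp3$rmse, 3 * floor_sabgal + 0.01)
  # and the biased series leads the senescent fraction in time
  lead <- biased[["SA-b-Gal"]]$fraction_positive - p_true
  expect_gt(mean(lead[mtimes <= 60]), 0.05)
})
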