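wi38_irr <- pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26)

test_that("parameter and state constructors validate their contracts", {
  expect_error(pcs_params(r = -0.1), "non-negative")
  expect_error(pcs_params(r = NA), "finite")
  expect_error(pcs_params(r = 0.5, K = 0), "K must be positive")
  expect_error(cell_state(P = -1), "non-negative")
  expect_s3_class(pcs_params(r = 0.7), "pcs_params")
})

test_that("constant-growth equation gives the analytic exponential line", {
  p <- pcs_params(r = 0.70)
  expect_equal(constant_growth_rhs(cell_state(P = 1), p), 0.70)

  sim <- simulate_pcs(p, initial = cell_state(P = 1), grid = 0:10,
                      extinction = FALSE)
  expect_equal(sim$trajectory$pd[11], 0.70 * 10 / log(2), tolerance = 1e-6)

  sim0 <- simulate_pcs(pcs_params(r = 0), initial = cell_state(P = 5),
                       grid = 0:10, extinction = FALSE)
  expect_equal(sim0$trajectory$P, rep(5, 11), tolerance = 1e-10)
  expect_equal(sim0$trajectory$pd, rep(0, 11), tolerance = 1e-10)

  # time to the first doubling at r = 0.28 is ln 2 / r
  t1 <- log(2) / 0.28
  sim28 <- simulate_pcs(pcs_params(r = 0.28), initial = cell_state(P = 1),
                        grid = c(0, t1), extinction = FALSE)
  expect_equal(sim28$trajectory$pd[2], 1, tolerance = 1e-6)
})

test_that("pcs_rhs matches direct substitution and conserves mass", {
  d0 <- pcs_rhs(cell_state(P = 100), wi38_irr, gamma_now = 0)
  expect_equal(unname(d0["P"]), 0.46 * 100)
  expect_equal(unname(d0[c("C", "S", "F")]), c(0, 0, 0))

  # P = 0, C = 10 with f2 = 16, f3 = 0.26: dC = -162.6, dS = 2.6, dP = 160
  d1 <- pcs_rhs(cell_state(P = 0, C = 10), wi38_irr, gamma_now = 0)
  expect_equal(unname(d1["C"]), -(16 + 0.26) * 10)
  expect_equal(unname(d1["S"]), 2.6)
  expect_equal(unname(d1["P"]), 160)

  # conservative exchange: dP + dC + dS = r P for random states and stress
  set.seed(42)
  for (i in 1:25) {
    st <- cell_state(P = runif(1, 0, 1e4), C = runif(1, 0, 1e4),
                     S = runif(1, 0, 1e4), F = runif(1, 0, 50))
    pp <- pcs_params(r = runif(1, 0, 1), f1 = runif(1, 0, 10),
                     f2 = runif(1, 0, 20), f3 = runif(1, 0, 2))
    d <- pcs_rhs(st, pp, gamma_now = runif(1, 0, 100))
    expect_equal(unname(d["P"] + d["C"] + d["S"]), pp$r * st[["P"]],
                 tolerance = 1e-12)
  }

  expect_error(pcs_rhs(cell_state(P = 1), wi38_irr, gamma_now = -1),
               "non-negative")
})

test_that("saturated-response subsystem has a positive dominant eigenvalue", {
  # with the response held at its saturated level the WI-38 population can
  # still grow, so irreversible arrest must come from the extinction event
  J <- matrix(c(0.46 - 3.8, 16, 3.8, -(16 + 0.26)), 2, 2, byrow = TRUE)
  expect_gt(max(Re(eigen(J)$values)), 0)
})

test_that("stress response has a healthy fixed point and slow relaxation", {
  p <- pcs_params(r = 0.5)
  expect_equal(stress_response_rhs(0, 0, p), 0)

  # default shape: a single fixed point (F = 0) at gamma = 0 ...
  Fs <- seq(0, 2 * p$K, length.out = 500)
  g <- stress_response_rhs(Fs, 0, p)
  expect_true(all(g[-1] < 0))
  # ... and three fixed points at gamma = 0 for a stronger feedback shape
  p3 <- pcs_params(r = 0.5, a = 2.5 * p$b * p$c)
  g3 <- function(F) stress_response_rhs(F, 0, p3)
  Fs3 <- seq(0, 3 * p3$a / p3$c, length.out = 4000)
  flips <- sum(diff(sign(g3(Fs3[-1]))) != 0) + 1
  expect_equal(flips, 3)

  # step stress on, then off: 10-90% rise is much faster than the decay
  pr <- pcs_params(r = 0, K = 1)
  grid_on <- seq(0, 2, by = 0.005)
  on <- simulate_pcs(pr, stress_constant(100), initial = cell_state(P = 1),
                     grid = grid_on, extinction = FALSE)$trajectory$F
  F_hi <- on[length(on)]
  rise <- grid_on[min(which(on >= 0.9 * F_hi))] -
    grid_on[max(which(on <= 0.1 * F_hi))]
  grid_off <- seq(0, 60, by = 0.05)
  off <- simulate_pcs(pr, stress_none(),
                      initial = cell_state(P = 1, F = F_hi),
                      grid = grid_off, extinction = FALSE)$trajectory$F
  fall <- grid_off[min(which(off <= 0.1 * F_hi))] -
    grid_off[max(which(off >= 0.9 * F_hi))]
  expect_gt(fall / rise, 5)
})

test_that("unstressed simulation reduces to the exponential limit", {
  sim <- simulate_pcs(wi38_irr, stress_none(), initial = cell_state(P = 1e5),
                      grid = seq(0, 12, by = 0.5))
  expect_false(sim$terminated)
  expect_equal(sim$trajectory$pd[1], 0)
  expect_rel_equal(sim$trajectory$pd[-1],
                   0.46 * seq(0.5, 12, by = 0.5) / log(2), 1e-6)
  expect_equal(sim$trajectory$C, rep(0, 25), tolerance = 1e-9)
})

test_that("high-dose pulse triggers permanent extinction, low dose a delay", {
  fx <- fixture_catalog()$WI38_irradiation
  grid <- seq(0, 40, by = 0.5)

  hi <- simulate_pcs(fx$params, fx$protocols[["15Gy"]], initial = fx$initial,
                     grid = grid)
  expect_true(hi$terminated)
  expect_lt(min(hi$trajectory$P), 1 + 1e-6)
  # permanent plateau: no appreciable PD gain after the event
  after <- hi$trajectory$pd[grid >= hi$t_event]
  expect_lt(max(after) - min(after), 0.05)

  lo <- simulate_pcs(fx$params, fx$protocols[["2Gy"]], initial = fx$initial,
                     grid = grid)
  un <- simulate_pcs(fx$params, fx$protocols[["0Gy"]], initial = fx$initial,
                     grid = grid)
  expect_false(lo$terminated)
  n <- length(grid)
  slope_un <- (un$trajectory$pd[n] - un$trajectory$pd[n - 8]) / 4
  slope_lo <- (lo$trajectory$pd[n] - lo$trajectory$pd[n - 8]) / 4
  expect_lt(abs(1 - slope_lo / slope_un), 0.1)   # full recovery of the slope
  delay <- (un$trajectory$pd[n] - lo$trajectory$pd[n]) / slope_un
  expect_gt(delay, 0.3)                          # but with a visible delay
  expect_lt(delay, 3)
})

test_that("production solver agrees with a fixed-step RK4 oracle", {
  p <- pcs_params(r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26)
  prot <- stress_constant(2)
  init <- cell_state(P = 1000, C = 10, S = 5, F = 0.5)
  times <- c(0, 0.5, 1)
  sim <- simulate_pcs(p, prot, initial = init, grid = times,
                      extinction = FALSE)
  ora <- rk4_trajectory(p, prot, init, times, dt = 5e-5)
  for (col in c("P", "C", "S", "F")) {
    expect_rel_equal(sim$trajectory[[col]][-1], ora[-1, col], 1e-6)
  }
})

test_that("states stay non-negative and S never decreases on fixtures", {
  cat_fx <- fixture_catalog()
  runs <- list(
    list(cat_fx$WI38_irradiation$params,
         cat_fx$WI38_irradiation$protocols[["15Gy"]],
         cat_fx$WI38_irradiation$initial, seq(0, 30, 0.25)),
    list(cat_fx$MRC5_irradiation$params,
         cat_fx$MRC5_irradiation$protocols[["20Gy"]],
         cat_fx$MRC5_irradiation$initial, seq(0, 30, 0.25)),
    list(cat_fx$WI38_replicative$params, cat_fx$WI38_replicative$protocol,
         cat_fx$WI38_replicative$initial, cat_fx$WI38_replicative$times))
  for (rn in runs) {
    tr <- simulate_pcs(rn[[1]], rn[[2]], initial = rn[[3]],
                       grid = rn[[4]])$trajectory
    expect_true(all(tr$P >= -1e-9 & tr$C >= -1e-9 & tr$S >= -1e-9 &
                      tr$F >= -1e-9))
    expect_true(all(diff(tr$S) >= -1e-8))
    total <- tr$P + tr$C + tr$S
    expect_true(all(diff(total) >= -1e-6 * total[-length(total)]))
  }
})

test_that("state fractions sum to one and senescence saturates late", {
  p <- pcs_params(r = 0.5)
  pure <- simulate_pcs(p, t_end = 5, grid = 0:5)
  fr <- state_fractions(pure)
  expect_equal(fr$frac_P, rep(1, 6), tolerance = 1e-9)
  expect_equal(fr$frac_arrested, rep(0, 6), tolerance = 1e-9)

  # with r = 0 the total is constant, so the S fraction is non-decreasing
  pr <- pcs_params(r = 0, f1 = 2, f2 = 1, f3 = 0.5)
  sim <- simulate_pcs(pr, stress_constant(5),
                      initial = cell_state(P = 100, C = 10),
                      grid = seq(0, 20, 0.5), extinction = FALSE)
  frs <- state_fractions(sim)
  expect_equal(frs$frac_P + frs$frac_C + frs$frac_S, rep(1, nrow(frs)),
               tolerance = 1e-9)
  expect_true(all(diff(frs$frac_S) >= -1e-9))

  fx <- fixture_catalog()$WI38_replicative
  rep_sim <- simulate_pcs(fx$params, fx$protocol, initial = fx$initial,
                          grid = fx$times)
  fr_rep <- state_fractions(rep_sim)
  expect_gt(fr_rep$frac_S[nrow(fr_rep)], 0.99)
})
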