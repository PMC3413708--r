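# pcskinetics

Quantitative kinetics of cell-cycle arrest and cellular senescence in
primary human fibroblast cultures.

Cultured fibroblasts stop dividing after a finite number of population
doublings (PD), and acute stress such as gamma-irradiation can arrest them
long before that.  `pcskinetics` implements a deterministic compartment
model of this progression for people who want to *fit* growth curves and
senescence-marker counts, not just describe them: proliferating cells `P`
enter a reversible cell-cycle arrest `C` and commit irreversibly to
senescence `S`,

    dP/dt = r P − f1 (F/K) P + f2 C
    dC/dt = f1 (F/K) P − f2 C − f3 C
    dS/dt = f3 C
    dF/dt = γ(t) + a F²/(b² + F²) − c F

with rates per day.  The stress input γ(t) (an irradiation pulse, constant
stress, or accumulating replicative stress γ = α + βt) is separated from
the cellular response F(t), a bistable switch that turns on rapidly when
stress exceeds a threshold and relaxes back slowly — so the model can
distinguish a one-day growth delay after a mild dose from permanent arrest
after a harsh one.  Growth stops irreversibly when `P` falls below one
cell (the extinction event).  The observable is PD(t) = log2 of total
cells relative to seeding.

The package provides:

* `simulate_pcs()` — stiff-capable ODE simulation (compiled right-hand
  side, exact restarts at pulse edges, event detection), with
  `state_fractions()` for the model counterparts of marker-positive
  fractions;
* `fit_constant_growth()`, `fit_two_state_f1()`,
  `fit_joint_irradiation()`, `fit_replicative()` — least-squares
  estimation on the PD scale, multi-start Levenberg–Marquardt with
  seeded starts, ridge-aware polishing and identifiability flags;
* `classify_fate()` (analytic growth threshold r > f1·f3/(f2+f3) under
  saturated stress), `bifurcation_scan()` (fixed points, stability,
  saddle-node folds of F), `sensitivity_analysis()`,
  `marker_comparison()`;
* `generate_growth_curves()` / `generate_marker_series()` /
  `fixture_catalog()` — seeded synthetic datasets emulating the study
  designs (multi-dose irradiation, long-term replicative cultures,
  3 × 100-cell marker counts), so the whole pipeline is testable without
  any external data;
* `pcs_cli()` plus `inst/scripts/pcskinetics` — a thin command-line
  surface (`simulate`, `fit`, `analyze`, `synth`) over the same functions.

## Worked example

Simulate the three-dose WI-38 irradiation experiment from its published
parameter set and refit the model jointly to the three curves:

```r
library(pcskinetics)

fx <- fixture_catalog()$WI38_irradiation
fx$params
#> P-C-S model parameters (per day):
#>   r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26
#>   stress response: K = 1, a = 39.6, b = 20, c = 1

# a 15 Gy analogue: gamma = 2800 for 13.5 min, applied 1 day after seeding
sim <- simulate_pcs(fx$params, fx$protocols[["15Gy"]],
                    initial = fx$initial, grid = seq(0, 30, 0.5))
sim
#> P-C-S simulation: 61 time points on [0, 30] days
#>   final PD = 1.235; final fractions P/C/S = 0.002/0.007/0.991
#>   extinction event: proliferation lost at t = 25.71 days

curves <- generate_growth_curves(fx$params, fx$protocols,
                                 times = fx$times, noise_sd_pd = 0,
                                 seed = 1, initial = fx$initial)
fit_joint_irradiation(curves, fx$protocols, initial = fx$initial,
                      n_starts = 16, seed = 1)
#> P-C-S least-squares fit
#>   estimates: r = 0.46, f1 = 3.8, f2 = 16, f3 = 0.26
#>   residual norm (SSR on PD): 1.307e-21; 16 start(s); converged: TRUE

classify_fate(fx$params)
#> Fate under constant saturated stress: r_crit = 0.06076 -> population grows
```

Reading the output: under 15 Gy the population gains barely one doubling,
the proliferating pool drops below a single cell (the event at ~26 days)
and essentially all cells end up senescent — while the same parameter set
under the 2 Gy pulse only delays growth by about a day.  The joint refit
recovers the generating rates exactly (residual at machine zero), which is
the package's round-trip check against the published fitted values.  The
fate classification says WI-38 cells would still grow even at a
permanently saturated stress response (r = 0.46 far above
r_crit = 0.061), which is why permanent arrest needs the extinction
event rather than an eigenvalue sign change.

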