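---
title: "A compartmental model of cell-cycle arrest and cellular senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of cell-cycle arrest and cellular senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcskinetics)
```

## The model

Primary human fibroblasts in culture divide a limited number of times.  As
the culture ages (or after acute genotoxic stress such as gamma-irradiation)
an increasing share of cells first enters a *reversible* cell-cycle arrest
and then commits *irreversibly* to cellular senescence.  `pcskinetics`
implements a deterministic population model of this progression with three
cell compartments — proliferating `P`, reversibly arrested `C`, senescent
`S` — and a cellular stress-response variable `F`:

$$
\begin{aligned}
dP/dt &= r\,P - f_1\,\hat F\,P + f_2\,C \\
dC/dt &= f_1\,\hat F\,P - f_2\,C - f_3\,C \\
dS/dt &= f_3\,C \\
dF/dt &= \gamma(t) + a\,\frac{F^2}{b^2 + F^2} - c\,F,
\qquad \hat F = F/K .
\end{aligned}
$$

All transitions are linear (first-order) in the compartment sizes; `S` has
no back reaction.  The exchange is conservative —
$d(P+C+S)/dt = rP$ — so the model has no cell death, and "no growth"
manifests as a population-doubling (PD) plateau.  The primary observable is
$\mathrm{PD}(t) = \log_2\big((P+C+S)(t)\,/\,(P+C+S)(0)\big)$, matching how
growth curves are recorded experimentally (all cells in the dish are
counted, arrested or not).  Time is in days; fitted proliferation rates of
0.26–0.70 per day correspond to doubling times of 1–2.7 days.

The stress input $\gamma(t)$ is separated from the cellular response $F$:
the same cell line (fixed response parameters) can be exposed to an
irradiation pulse, constant stress, or slowly accumulating replicative
stress $\gamma = \alpha + \beta t$ (telomere shortening, ambient 20%
oxygen), and conversely different lines can respond differently to the
same stress.  Protocols are built with `stress_none()`, `stress_pulse()`,
`stress_constant()` and `stress_linear()`; `irradiation_protocol()` wraps
the pulse form with the convention that cells are seeded one day before
exposure.

## The bistable stress response

$F$ is a switch, not a proxy of instantaneous stress: damage markers decay
within hours while downstream arrest markers peak much later, so the
response must *remember* stress.  The form used here combines an additive
drive $\gamma$, a saturating positive feedback $a F^2/(b^2+F^2)$, and
linear decay $cF$ — a minimal one-variable bistable switch in the spirit
of classical outbreak models.  Its properties under the default shape
constants ($a = 39.6$, $b = 20$, $c = 1$ per day, $K = 1$):

* at $\gamma = 0$ the only fixed point is the healthy state $F = 0$;
* over an intermediate band of constant $\gamma$ (about 0.2–2.7) there are
  three fixed points — low and high stable branches separated by an
  unstable one — producing saddle-node folds, switch-like activation and
  hysteresis (`bifurcation_scan()` locates the folds; the quasi-static
  up-sweep and down-sweep switch at different $\gamma$);
* the up-switch under strong stress is fast (during an irradiation pulse
  $F$ rises at rate $\approx \gamma$), while relaxation back to the
  healthy state is slow: the decay passes the saddle-node *ghost* near
  $F \approx a/2c$, where the net rate is small.

The defaults were chosen once so that the model reproduces the qualitative
program reported for human fibroblasts: a low dose (pulse
$\gamma\,\Delta t \approx 3$) delays growth by about one day and the PD
slope then returns to within a few percent of the unstressed slope; a high
dose ($\gamma\,\Delta t \gtrsim 25$) keeps $\hat F$ elevated long enough
that `P` falls below one cell and proliferation is irrecoverably lost;
a linear ramp tracks the low branch, bends the PD curve and ends in a
plateau with the senescent fraction approaching one.

Two points where this package deliberately interprets an under-specified
formulation, with the reasoning:

* **$\hat F$ is not capped at 1.**  With the printed kinetic rates the
  $(P, C)$ subsystem still grows when $\hat F = 1$ (its dominant
  eigenvalue is positive because $r > f_1 f_3/(f_2+f_3)$), so a response
  capped at saturation could never stop proliferation — high-dose
  extinction and replicative plateaus would be impossible.  The arrest
  flux therefore scales with the uncapped $F/K$, and `K` acts as the
  normalization scale of the response rather than a hard ceiling: under an
  additive drive a strong pulse necessarily pushes $F$ to
  $\approx \gamma\,\Delta t$ regardless of the feedback constants.
* **Monostable at $\gamma = 0$.**  If the high state persisted at zero
  stress, mildly irradiated cells would stay slowed by
  $f_1 f_3/(f_2+f_3)/r$ (13% for the WI-38 irradiation set) forever,
  contradicting the observed full recovery after low doses.  The default
  shape therefore satisfies $a < 2bc$ (tangent to bistability at
  $a = 2bc$), and bistability lives in the $\gamma > 0$ band.

## Extinction event and initial conditions

Growth termination uses the criterion that a culture recovers whenever at
least one functional proliferating cell survives: when `P` first crosses
below `extinction_threshold` (1 by default, in the same concentration
units as the initial state), proliferation is switched off permanently and
integration continues, so `C` keeps converting to `S` while PD stays on
its plateau.  The solver (`deSolve`'s `lsoda`/`lsodar` with a compiled
right-hand side, `rtol = 1e-8`, `atol = 1e-10`) is restarted exactly at
pulse edges — step-size control would otherwise step over a 27-second
exposure — and the event is located by root-finding on `P - threshold`.

Because the event compares an absolute count with the dimensionless
threshold "one cell", the seeding scale matters.  Plain simulations
default to $P(0) = 10^5$, which keeps unstressed PD curves far from the
event.  The irradiation experiment fixtures seed at 100 concentration
units: the commitment rate $f_3$ caps how fast the proliferating pool can
drain (the dominant eigenvalue tends to $-f_3$ as $\hat F \to \infty$), so
with the printed WI-38 rates a high dose can push `P` below one only from
a moderate seeding scale within a realistic arrest window.  This is a
normalization choice of the synthetic experiment design, not a biological
claim about dish cell numbers.

## Fitting

All fits minimize the sum of squared PD residuals — PD (a log2 scale) is
the plotted and reported observable and keeps magnitudes comparable across
the curve.  Four drivers mirror the study designs:

* `fit_constant_growth()`: single exponential rate, 1-D minimization;
  the closed form $\hat r = \ln 2\,\Sigma t\,\mathrm{pd}/\Sigma t^2$
  serves as an independent oracle in the tests.
* `fit_two_state_f1()`: the reduced `P`↔`C` model (no senescence,
  response saturated) with `r` fixed at the reference maximal rate 0.70
  per day and `f2` at 1; explains slower apparent growth by a standing
  arrested fraction via a single fitted `f1`.
* `fit_joint_irradiation()`: one shared `(r, f1, f2, f3)` across all dose
  conditions, which differ only in exposure time; the pulse amplitude
  $\gamma$ is a fixed input because it is fully confounded with `f1`.
* `fit_replicative()`: long-horizon accumulating-stress curves; fits
  either the kinetic rates with $(\alpha, \beta)$ fixed or vice versa,
  because a single curve cannot identify all six parameters.

The multi-parameter drivers use multi-start Levenberg–Marquardt
(`minpack.lm`) in log10 parameter space with rates bounded in
$[10^{-3}, 100]$ per day, 16 starts from a seeded Latin hypercube by
default.  Two numerical details matter in practice.  First, the pooled SSR
surface has a shallow ridge along joint rescaling of the fast exchange
pair $(f_1, f_2)$; after the best start converges, the driver restarts the
solver from co-scaled copies of the incumbent, which reliably walks ridge
stalls down to the global minimum on noiseless data.  Second,
identifiability is reported rather than assumed: finite-difference profile
curvature flags flat directions (for example, fitting a single unstressed
curve leaves `f1`, `f2`, `f3` flagged unidentifiable while `r` is sharp).
Fits are bit-reproducible given the same seed and inputs.

With the generator's replicate-level noise (0.25 PD), the growth rate `r`
is still recovered with a median error of about 1% over seeded replicates,
but the exchange pair genuinely drifts along its ridge — at that noise the
global minimum itself sits away from the truth in $(f_1, f_2)$, an
identifiability limit of three 14-day growth curves, not an optimizer
failure.

## Synthetic data

`generate_growth_curves()` adds independent Gaussian noise on the PD scale
(default sd 0.25 PD, chosen once to emulate the "small but significant"
scatter between biological replicates; the true experimental noise level
is not published).  `generate_marker_series()` emulates
immunofluorescence scoring: at each time, each of 3 replicates draws a
binomial count of positive cells among 100 scored, with success
probability equal to the mapped model fraction — p21 maps to the arrested
fraction `C+S`, SA-b-Gal to the senescent fraction `S`; p16 and SAHF are
treated as qualitative and not mapped.  An optional additive bias hook
emulates a marker that responds to causes other than its mapped state
(used to reproduce the diagnosis that SA-b-Gal is a good quantitative
senescence marker in some lines but leads the senescent fraction in
others).  All generators are seeded and bit-reproducible.

What passing tests on these synthetic data do and do not show: they
verify that the pipeline recovers the parameters of its own generating
process (round-trip identifiability under the stated designs and noise),
and that analytic properties hold.  They cannot validate the model against
real cultures — the generator shares the model's assumptions (no death,
no quiescence or differentiation, deterministic dynamics, Gaussian PD
noise) — and the absolute plateau levels of the replicative fixtures
depend on the stand-in response shape, whose exact published form is not
recoverable from the source text.

## Fixtures and problem sizes

`fixture_catalog()` carries the five published fitted parameter sets
(WI-38 and MRC-5 irradiation; WI-38, BJ and MRC-5 replicative) with their
stress protocols, plus `table1_growth_rates()` (twelve constant-growth
rates; max/min = 7.8) and `table2_arrest_rates()` (eleven two-state `f1`
values).  The recovery studies sample irradiation designs on a 14-day
grid every half day (29 points per dose, three doses) and replicative
designs on 150/280/700-day horizons with 76/71/71 points — sizes chosen so
each joint refit completes in seconds to minutes while the curves span
their informative features (delay, extinction plateau, senescence
plateau).

## Known limitations

* No apoptosis, quiescence or terminal differentiation compartments, and
  no cell death at all; senescent cells accumulate indefinitely.
* The response equation is a documented stand-in satisfying a qualitative
  contract (bistable band, fast up-switch, slow relaxation); quantities
  that depend on its absolute scale — the usable $\gamma$ ranges per cell
  line, absolute replicative plateau PDs — are reproduced qualitatively,
  not numerically.
* Marker comparison treats replicate means as the observable; per-cell
  fluorescence intensities are out of scope.
* The paracrine influence of senescent cells on their neighbours is not
  modelled.
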