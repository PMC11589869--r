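---
title: "Models and methods: secretion kinetics from capacitance recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: secretion kinetics from capacitance recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretolyze)
```

## The measurement and the model

Whole-cell membrane capacitance (CM, femtofarads) is an electrical proxy
for cell surface area: every vesicle that fuses adds its membrane, so CM
steps up with exocytosis. In chromaffin cells the standard experiment
first loads the cell for about two minutes with a submicromolar
(~500 nM) free-calcium solution, during which *premature (tonic)
secretion* can be measured, and then triggers synchronized fusion either
with a step rise of intracellular calcium (flash photolysis of a caged
calcium compound) or with a slow, quasi-linear calcium *ramp*.

`secretolyze` implements both analyses plus a forward simulator of the
recordings. The generative model — which is also the model family the
flash analysis fits — is:

* two depleting primed vesicle pools, sizes $B_1$ (fast; the readily
  releasable pool, RRP) and $B_2$ (slow; the slowly releasable pool,
  SRP), each obeying
  $\mathrm{d}F_i/\mathrm{d}t = k_i([\mathrm{Ca}]) \,(B_i - F_i)$;
* Hill-type calcium dependence of each fusion rate constant,
  $k_i(c) = r_{\max,i}\, c^{n_i} / (c^{n_i} + K_{D,i}^{n_i})$;
* a non-depleting *sustained* component whose membrane-addition rate
  (fF/s) follows a saturating Hill shape of calcium;
* a pure onset delay $t_0$: the fusion machinery sees the calcium signal
  shifted by $t_0$;
* additive white Gaussian recording noise on capacitance only (measured
  calcium is treated as given).

For a calcium step at time $t_f$ this model has the exact closed form

$$ CM(t) = A_0 + A_1\!\left(1-e^{-(t')/\tau_1}\right)
         + A_2\!\left(1-e^{-(t')/\tau_2}\right) + k\,t', \qquad
   t' = t - t_f - t_0 ,$$

with $A_i = B_i$ and $\tau_i = 1/k_i(c_\text{post})$ — which is exactly
the function fitted by `fit_flash_response()`. That closure is the
backbone of the test suite: simulated step responses are *in-family*, so
the fitter must recover the generating parameters to numerical
precision, and every downstream readout (RRP, SRP, EB = RRP + SRP,
sustained rate SR, secretory delay) has known ground truth.

### Integration scheme

Within one sample the calcium command is constant, so each pool is
updated with the exact exponential step
$F_i(t+\Delta t) = B_i - (B_i - F_i(t))\,e^{-k_i \Delta t}$
(implemented as a cumulative sum of $k_i\,\Delta t$). No generic ODE
solver is involved; the integration is exact for piecewise-constant
calcium and bit-reproducible for a fixed seed. All randomness flows from
explicit integer seeds: per-group seeds derive per-cell seeds
deterministically, so populations rerun identically.

## Flash decomposition

`fit_flash_response()` fits the seven parameters
$(A_0, A_1, \tau_1, A_2, \tau_2, k, t_0)$ by nonlinear least squares.
Numerical choices that matter:

* **Multi-start.** Double-exponential fits are multimodal. A grid of
  log-spaced time-constant seeds (10 ms … 1 s, pairs $\tau_1<\tau_2$)
  and a few onset-delay seeds is scanned; at each seed the amplitudes
  $(A_0, A_1, A_2, k)$ are solved *linearly*, which makes the scan cheap
  and the subsequent Levenberg–Marquardt refinement well-started. The
  best-RSS solution wins; ties go to the smaller $\tau_1$.
* **Delay.** Published work reports a "secretory delay" without defining
  its estimator. Here $t_0$ is a fitted onset parameter that time-shifts
  all stimulus-evoked terms (bounded to [0, 50 ms] by default). This
  keeps the standard fit family intact while making the delay
  identifiable; on noise-free input the fitted $t_0$ lands within one
  sample of the generating value.
* **Baseline.** $A_0$ is fitted jointly on a 0.2 s pre-flash segment by
  default (configurable down to 0), since fitting the baseline from the
  post-flash segment alone trades off against the slow component.
* **Identifiability guards.** A component with fitted amplitude below
  `amp_floor` (1 fF) has its time constant reported as `NA` rather than
  an arbitrary number; a flat trace returns an empty burst rather than a
  pseudo-fit.
* **Single-component option.** `components = 1` fits one burst
  exponential. For recordings known to contain a single kinetic
  component (e.g. the near-saturating anchor experiments below), a free
  second exponential would occasionally latch onto noise at the onset
  and produce an absurd `1/tau`; fixing the model dimension is the
  correct remedy.

Premature secretion is quantified exactly as the conventional readouts:
total capacitance gain over the loading window, and the tonic rate as
the OLS slope over the final sub-window (default 30 s — the slope window
is not standardized in the literature, so it is a configurable choice
here), together with the mean calcium over the window.

## Ramp analysis

The ramp pipeline (`analyze_ramp()`) mirrors the conventional procedure:
smooth the sigmoid capacitance rise with a polynomial; at fixed 40 ms
intervals (the cadence of ratiometric calcium measurements) compute the
slope, the remaining pool, and the fusion rate
`rate = slope / remaining`; interpolate each cell's rates onto a 50 nM
calcium grid below a per-group reliability cutoff; average across cells;
fit a Hill equation to the mean rates; and compute the calcium of
half-maximal pool depletion (P50) from the mean remaining-fraction
curve, with a seeded bootstrap over cells for its standard error.

The numerically delicate parts, and what this package does about them:

* **Polynomial order.** The conventional choice is a low-order
  polynomial; `smooth_cm()` defaults to order 8. For the full pipeline,
  however, order 8 leaves a systematic slope bias of several percent on
  realistic sigmoids (verifiable with `smooth_order_diagnostic()` and
  with noise-free simulations, where the recovered Hill coefficient
  shifts by ~0.15). `analyze_ramp()` therefore uses order 12 by default;
  with ~6000 samples per trace the added variance is negligible while
  the bias essentially disappears.
* **Burst-size (EB) estimate.** The depletion amplitude is plateau minus
  baseline. A plain "median of the last 10%" plateau underestimates EB
  by 1–2% whenever the ramp ends short of complete depletion, and
  because the late-ramp rates divide by the *remaining* pool (small
  there), a 1% EB error becomes a 5–15% rate error exactly where the
  Hill fit is most sensitive. The default estimator (`method = "tail"`)
  therefore extrapolates the terminal quarter of the raw trace with an
  exponential-asymptote model with quadratic exponent,
  $y = A - R\,e^{-(a s + b s^2/2)}$ (the form the depletion tail takes
  along a rising ramp), profiled linearly in $(A, R)$, with a fallback
  to the terminal median when the tail is already flat or the
  extrapolation is untrustworthy. The plain `"plateau"` and `"final"`
  estimators remain available. The saturation guard that refuses
  still-rising traces is stricter for the plateau estimators (terminal
  slope < 5% of peak) than for the tail estimator (< 20%), which only
  needs the decay to be well into its tail.
* **Baseline window.** The baseline is the median over the first 1% of
  the ramp window. Longer windows (e.g. 10%) overlap seconds of tonic
  depletion at the foot of the ramp and bias EB low by ~0.7%.
* **Midpoint convention.** Slope, remaining pool and calcium are all
  referenced to the interval midpoint. For pure exponential depletion at
  constant rate $r$ the discrete estimate is then
  $2\sinh(r\Delta/2)/\Delta$ — second-order accurate, comfortably inside
  the first-order bias bound $(e^{r\Delta}-1)/\Delta$.
* **Masks and monotonicity.** Rates are masked where the remaining pool
  falls below 5% of EB; interpolation never extrapolates beyond a cell's
  observed calcium range; non-monotone measured calcium is handled by
  restricting to the longest strictly increasing run; grid points
  supported by fewer than 3 cells are dropped.
* **Reliability cutoff.** Published analyses cap the usable calcium
  range per group ("rates reliable below X µM") because excessive
  depletion corrupts the ratio. The cutoff is a per-group setting; the
  automatic default is the calcium at which the remaining pool falls
  below 25% of EB.

### Identifiability of the Hill fit, and the flash anchor

With rates measured only far below saturation (cutoffs of a few µM
against $K_D$ of tens of µM), the rate relation is effectively a power
law $r_{\max}(c/K_D)^n$: the product $r_{\max}K_D^{-n}$ and $n$ are well
determined but $r_{\max}$ and $K_D$ individually sit on a flat ridge.
Unconstrained three-parameter fits on such data return essentially
arbitrary $K_D$ (errors of 50–600% in simulation). The conventional
resolution — visible in published rate–calcium plots, where the
flash-derived RRP rate constant is plotted as the extrapolation target
of the ramp rates — is to anchor the saturating branch with an
independent high-calcium measurement. `fit_hill()` accepts such an
`anchor` point, and `flash_rate_anchor()` computes it from a companion
flash experiment as the mean `1/tauRRP` plotted at the post-flash
calcium. In the simulated studies the companion step goes to 40 µM, a
near-saturating stimulus in the usual dose–response-design sense (at or
above the largest $K_D$ of interest); with the anchor in place the
pipeline recovers generating $(n, K_D)$ to within a few percent. When
the ramp itself covers the half-maximal region (small $K_D$), the
unanchored fit recovers the parameters directly, and the
`kd_extrapolated` flag marks fits whose $K_D$ lies beyond the gridded
range.

`fit_hill()` multi-starts over Hill-coefficient seeds 1–4 and several
$K_D$ scales (amplitude solved linearly at each seed), optionally
weights by $1/\mathrm{SEM}^2$ (unweighted by default: cross-cell SEMs at
low calcium are small in proportion to the rate, and weighting would
concentrate the fit on the power-law region that carries no $K_D$
information), reports standard errors from the local quadratic
approximation, and degrades gracefully on degenerate (constant-rate)
input.

The Hill fit is performed on the cross-cell mean profile, not per cell
(matching how such fits are usually presented); per-cell gridded rates
are returned so per-cell fits remain possible.

## Group statistics

`compare_groups()` reproduces the conventional workflow: per-group
normality check, then one-way ANOVA with Tukey–Kramer post hoc
comparisons if every group passes, otherwise Kruskal–Wallis with Dunn's
post hoc test; pairwise significance is tiered at p < 0.05 / 0.01 /
0.001. Two under-specified corners were resolved as follows: the
normality check is a one-sample Kolmogorov–Smirnov test of the
standardized sample against the standard normal (the Lilliefors caveat —
estimated parameters make the test conservative — is accepted for a
branch gate and documented); Dunn's pairwise p-values use Bonferroni
adjustment by default (configurable via `p.adjust` methods). Dunn's
statistic uses tie-corrected rank-sum variances; fully tied data yield
p = 1 rather than NaN. Zero-variance groups force the nonparametric
branch with a warning.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
biphasic burst kinetics in the flash-fit family, calcium-saturating
sustained/tonic secretion from a single mechanism (which yields both the
~500 nM loading-phase tonic rate and the post-flash linear component),
sigmoid pool depletion along ramps, mean-preserving log-normal
inter-cell parameter variability (so positivity survives without
truncation artifacts), and seeded additive Gaussian capacitance noise.

It deliberately does not model: endocytosis or pool refilling during the
burst, vesicle-size variability, calcium-measurement noise (optional in
principle, but the analysis treats calcium as given), lock-in admittance
demodulation (simulation starts at the capacitance level), or any
mechanistic multi-site calcium-sensor scheme — the analysis stops at the
empirical Hill description, and so does the generator. Passing tests
therefore certify the estimators against the assumed data-generating
process, not against violations of it (correlated noise, drifting
baselines, rundown), which real recordings do exhibit.

Two magnitudes are genuinely free choices rather than published values:
the post-flash calcium level (set to tens of µM; 20 µM in examples,
40 µM for anchor experiments) and the baseline cell size (5 pF). Both
are stated where used and configurable.

## Problem sizes used by the shipped studies

The simulation studies run by the test suite and by
`scripts/acceptance.R` use: 15 cells per group, a single 400 fF pool
with 20% coefficient of variation, 2 fF noise, a 0.3→8 µM ramp over 60 s
sampled at 10 ms, maximal fusion rate 15 1/s, per-group reliability
cutoffs of 3/4/6 µM for generating $K_D$ of 17.4/38.2/58.13 µM, and a
companion 40 µM flash per group for the anchor. The P50-ordering study
uses 6 cells per group and 100 replicates; flash-recovery studies use a
100-point random parameter grid (noise-free) and 50 noisy replicates;
the type-I-error study uses 1000 two-group comparisons of 15 + 15
standard-normal observations.

## Known limitations

* The anchored Hill fit treats the anchor as one more observation; its
  uncertainty is not propagated separately.
* P50 requires the mean depletion curve to cross one half within the
  observed calcium range; shallower depletion raises an error rather
  than extrapolating.
* The KS normality gate is conservative (Lilliefors), so the parametric
  branch is chosen slightly more often than a calibrated test would.
* Polynomial smoothing, however high the order, is global: strongly
  asymmetric sigmoids retain some edge bias, which is why the burst-size
  estimator works on the raw trace rather than the smoothed one.
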