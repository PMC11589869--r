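# secretolyze

Kinetic analysis of Ca²⁺-triggered exocytosis from whole-cell membrane
capacitance recordings, for electrophysiologists working with
neuroendocrine (e.g. chromaffin) cells — plus a seeded forward simulator
of such recordings, so every estimator in the package can be validated
against known ground truth.

Membrane capacitance (CM, in fF) tracks cell surface area and therefore
steps up with vesicle fusion. The package covers the three standard
readout families of flash-photolysis / calcium-ramp experiments:

1. **Flash (calcium-step) responses.** The capacitance rise is
   decomposed with the standard burst model

   f(t′) = A₀ + A₁(1 − e^(−(t′−t₀)/τ₁)) + A₂(1 − e^(−(t′−t₀)/τ₂)) + k·(t′−t₀)

   where the fast exponential is the readily releasable pool
   (RRP = A₁, τ_RRP = τ₁), the slow one the slowly releasable pool
   (SRP), k the sustained rate and t₀ the secretory delay; their sum
   A₁ + A₂ is the exocytotic burst (EB). Premature (tonic) secretion
   during the ~500 nM loading phase is quantified as ΔCM over the
   loading window and the OLS slope over its final stretch.

2. **Calcium ramps.** The sigmoid capacitance rise during a slow ramp is
   smoothed with a polynomial; slope, remaining pool, and fusion rate
   (rate = slope [fF/s] / remaining pool [fF]) are computed on fixed
   40 ms intervals, interpolated per cell onto a 50 nM calcium grid
   below a per-group reliability cutoff, averaged across cells, and the
   mean rate–[Ca]ᵢ relation is fitted with a Hill equation

   rate(Ca) = r_max · Caⁿ / (Caⁿ + K_Dⁿ),

   optionally anchored by the flash-derived RRP rate constant at the
   post-flash calcium (the conventional extrapolation target; without
   such an anchor, K_D is unidentifiable from sub-saturating ramp data).
   The calcium of half-maximal pool depletion (P50) is read off the mean
   remaining-fraction curve with a bootstrap SE over cells.

3. **Group statistics.** Kolmogorov–Smirnov normality gate, then one-way
   ANOVA + Tukey–Kramer or Kruskal–Wallis + Dunn (Bonferroni), with the
   usual `*`/`**`/`***` tiers at p < 0.05/0.01/0.001.

The simulator (`simulate_cell()`, `simulate_group()`) integrates a
two-pool + sustained-component kinetic model exactly (exponential
stepping per sample), so a step protocol reproduces the flash-fit
function *exactly* and ramp protocols produce the sigmoid depletion the
ramp analysis assumes. See the methods vignette
(`vignettes/secretion-kinetics.Rmd`) for the model, the numerical
choices and their rationale.

## Worked example

Simulate a small wild-type-like group, decompose one flash response, and
compare the RRP readout between two simulated genotypes:

```r
library(secretolyze)

proto <- make_flash_protocol(ca_pre = 0.5, ca_post = 20, t_flash = 0.5,
                             duration = 1.7, dt = 0.002)
cells <- simulate_group(group_spec("wt", 3, cv = 0.15, seed = 42), proto)

fit <- fit_flash_response(cells[[1]]$cm, t_flash = 0.5)
fit
#> Flash-evoked capacitance decomposition
#>   A0 = 6099.3 fF, A1 = 188.4 fF (tau1 = 0.0276 s), A2 = 163.5 fF (tau2 = 0.389 s)
#>   sustained k = 44.58 fF/s, delay t0 = 0.3 ms
#>   RSS = 4.3e+03 fF^2 over 601 points; converged: TRUE

unlist(classify_components(fit))[c("RRP", "SRP", "EB", "SR")]
#>      RRP      SRP       EB       SR
#> 188.3780 163.4712 351.8493  44.5780
```

This cell's generating parameters (drawn around B₁ = 200 fF,
B₂ = 150 fF at 15% CV) are recovered to within the 2 fF recording
noise: a 188 fF RRP with 28 ms time constant, a 163 fF SRP at 389 ms,
and a ~45 fF/s sustained rate.

```r
rrp_of <- function(cl) classify_components(fit_flash_response(cl$cm, 0.5))$RRP
samples <- list(
  ko = vapply(simulate_group(group_spec("ko", 12,
          means = cell_params(B1 = 90, B2 = 80), cv = 0.2, seed = 1), proto),
        rrp_of, 0),
  wt = vapply(simulate_group(group_spec("wt", 12, cv = 0.2, seed = 2), proto),
        rrp_of, 0))
compare_groups(samples)
#> Group comparison (parametric branch)
#>  group  n   mean    sem
#>     ko 12  86.12  5.045
#>     wt 12 196.59 16.979
#> one-way ANOVA: statistic = 38.9, p = 2.81e-06
#>  group1 group2 estimate    p_adj tier
#>      ko     wt      110 2.81e-06  ***
```

The knockout-like group's smaller readily releasable pool is detected at
the `***` tier.

For a ramp experiment, `analyze_ramp()` chains the whole pipeline; the
end-to-end demo configuration in `inst/extdata/demo_config.yaml` runs
simulation → flash analysis → group comparison via
`run_pipeline(system.file("extdata", "demo_config.yaml",
package = "secretolyze"), out_dir = "demo_out")`, writing CSV traces,
JSON manifests and JSON results that are byte-identical across reruns.

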