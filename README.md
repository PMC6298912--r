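# ceusquant

Quantification of organ perfusion from contrast-enhanced ultrasound (CEUS)
bolus wash-in studies.

After an intravenous microbubble bolus, the (linearised) CEUS signal inside a
region of interest is proportional to the local contrast concentration. The
mean ROI intensity over the frames of a cine loop — the time–intensity curve
(TIC) — therefore carries the wash-in kinetics of the organ's blood pool.
`ceusquant` covers the whole analysis chain for such studies, calibrated to
small-animal ovarian imaging (ovaries of 1–2.5 mm, 55 s loops at
36 frames/s):

* **ROI extraction** — mean-intensity TICs from multi-page TIFF cine loops
  with a fixed ROI mask (`extract_tic()`);
* **Bolus model fitting** — a lognormal wash-in model
  `f(t) = O + A·exp(−(ln(t−t₀)−μ)²/(2σ²)) / ((t−t₀)σ√(2π))` for `t > t₀`,
  fitted by bounded multi-start Levenberg–Marquardt (`fit_bolus_model()`);
* **Perfusion parameters** — the nine standard wash-in quantities: peak
  enhancement PE = `A·e^{σ²/2−μ}/(σ√2π)`, wash-in rate WiR (maximum slope),
  time to peak TTP = `t₀ + e^{μ−σ²}`, rise time RT, AUC = `A` (to infinite
  time), mean transit time MTT = `e^{μ+σ²/2}`, perfusion index PI = AUC/MTT,
  wash-in AUC, and wash-in perfusion index WiPI = WiAUC/RT
  (`extract_parameters()`);
* **Group statistics** — two-tailed unequal-variance (Welch) t-tests, both
  from raw samples and directly from published group summaries
  (`welch_from_samples()`, `welch_from_summary()`), and per-timepoint
  two-arm study comparisons (`compare_study()`);
* **Synthetic data** — seeded generators for TICs, speckled cine loops and
  full two-arm longitudinal study tables with known ground truth
  (`simulate_tic()`, `simulate_cine()`, `simulate_study()`), so the entire
  chain is testable end to end;
* **Pipeline** — directory-level orchestration with per-item error handling
  and a reproducibility log (`run_pipeline()`), plus a thin CLI at
  `inst/cli/ceusquant.R`.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fits, `autoplot()` for TICs, fits and comparisons.

## Worked example

Simulate a noisy 55 s acquisition from known kinetics, fit it, and extract
the perfusion parameters:

```r
library(ceusquant)

p <- bolus_params(O = 5, A = 100, mu = 1, sigma = 0.5, t0 = 2)
curve <- simulate_tic(p, duration = 55, frame_rate = 36, noise_sd = 0.7, seed = 42)
fit <- fit_bolus_model(curve, fit_config(seed = 1))
fit
#> <bolus_fit> (converged)
#> <bolus_params>  lognormal wash-in model
#>   O = 4.995 a.u.   A = 99.72 a.u.s   mu = 1.006 ln(s)   sigma = 0.4961   t0 = 1.985 s
#>   rss = 959.956 on 1981 samples, 8 start(s), time origin 0 s

extract_parameters(fit)
#>      pe   wir   ttp    rt   auc   mtt    pi wipi wiauc
#> 1 33.15 33.27 4.124 1.445 99.72 3.094 32.23 21.2 30.62
```

All five model parameters are recovered within 1% of truth, and the derived
quantities sit on their closed forms: the true PE is
`100·e^{0.125−1}/(0.5√2π) = 33.26` a.u., TTP is `2 + e^{0.75} = 4.117` s,
AUC is exactly `A = 100`, MTT is `e^{1.125} = 3.080` s.

Reproduce a published group comparison straight from summary statistics —
day-10 dominant-follicle diameters, treated 0.659 ± 0.07 mm vs control
0.170 ± 0.05 mm, n = 10 per arm:

```r
welch_from_summary(0.659, 0.07, 10, 0.170, 0.05, 10)
#>   t_stat    df  p_value significant
#> 1   18.0  16.3 3.62e-12 TRUE
```

The p-value is far below 0.001: the follicle-diameter increase under
GnRH-analogue treatment is unambiguous at these summaries.

Simulate a full two-arm study at the reference effect sizes and compare the
arms per timepoint:

```r
st <- simulate_study(study_config(seed = 1))
cmp <- compare_study(st)
subset(cmp, parameter %in% c("follicle_diameter_mm", "pe"))
#>   timepoint            parameter mean_treated mean_control  p_value significant
#> 1      day0 follicle_diameter_mm        0.259        0.162 7.80e-03        TRUE
#> 2      day0                   pe       80.033       38.563 1.93e-11        TRUE
#> 3     day10 follicle_diameter_mm        0.659        0.175 5.04e-14        TRUE
#> 4     day10                   pe       87.160      102.237 5.42e-01       FALSE
#> 5     day20 follicle_diameter_mm        0.427        0.241 1.17e-03        TRUE
#> 6     day20                   pe      118.970      144.714 2.93e-03        TRUE
```

Each row is one Welch test of treated vs control at one timepoint;
`autoplot(cmp)` draws the mean ± sd panel per parameter.

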