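---
title: "Bolus-kinetic quantification of CEUS perfusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bolus-kinetic quantification of CEUS perfusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceusquant)
```

## The measurement problem

Contrast-enhanced ultrasound (CEUS) measures tissue perfusion by imaging an
intravenous bolus of microbubble contrast agent as it washes into an organ.
After linearisation, the image intensity is proportional to the local
microbubble concentration, so the mean intensity inside a region of interest
(ROI), sampled over the frames of a cine loop, traces the blood-pool kinetics
of the region: a time–intensity curve (TIC). `ceusquant` implements the full
wash-in analysis chain for small-organ studies of this kind — here calibrated
to murine ovaries of 1–2.5 mm diameter imaged for 55 s at 36 frames/s
starting at contrast administration — together with a synthetic-data
generator that makes every stage testable without any acquisition hardware.

## The bolus model

The wash-in phase of a bolus TIC is modelled as a baseline offset plus a
scaled lognormal density in time since bolus arrival:

$$f(t) = O + A\,
  \frac{\exp\!\left\{-\frac{(\ln(t-t_0)-\mu)^2}{2\sigma^2}\right\}}
       {(t-t_0)\,\sigma\sqrt{2\pi}} \quad (t > t_0),
  \qquad f(t) = O \quad (t \le t_0).$$

The lognormal is the standard parametric family for bolus transit through a
vascular bed: it is supported on positive time-since-arrival, right-skewed
like observed wash-in curves, and analytically tractable. Commercial contrast
quantification packages fit curves from this family (or close relatives such
as the gamma-variate); the exact functional form used by any particular
vendor tool is proprietary, so the lognormal here is this package's own
model choice, kept behind a small interface (`evaluate_model()`,
`bolus_params()`) so a gamma-variate alternative could be added without
touching the rest of the chain.

Closed forms used throughout:

* peak at $t_0 + e^{\mu-\sigma^2}$; peak enhancement
  $\mathrm{PE} = A\,e^{\sigma^2/2-\mu}/(\sigma\sqrt{2\pi})$;
* area under the baseline-subtracted curve to infinite time
  $\mathrm{AUC} = A$;
* mean transit time $\mathrm{MTT} = e^{\mu+\sigma^2/2}$ (first moment of the
  normalised bolus, measured from arrival).

## The nine perfusion parameters

`extract_parameters()` computes, from a fitted model: peak enhancement (PE,
a.u.), wash-in rate (WiR, a.u./s — the maximum slope during wash-in), time to
peak (TTP, s, from the acquisition origin), rise time (RT, s), AUC (a.u.·s),
MTT (s), perfusion index (PI = AUC/MTT), wash-in AUC (WiAUC — the area from
starting enhancement to the peak), and wash-in perfusion index
(WiPI = WiAUC/RT).

Three conventions in those definitions are genuinely open, and the package
fixes them as follows:

* **The rise-time tangent.** RT runs from the intersection of the
  maximum-slope tangent with "the axis" to the peak. The package intersects
  the tangent of the *baseline-subtracted* curve with zero — equivalently,
  the tangent of the raw curve with the baseline level $O$. This makes RT
  independent of both the baseline level and the time origin, which is the
  property that definition is meant to have; intersecting with absolute zero
  intensity would make RT grow with the baseline.
* **The start of the wash-in window.** WiAUC integrates "from starting
  enhancement to peak enhancement". The default start is the tangent
  intercept $t_i$, consistent with the rise-time construction (so
  WiPI·RT = WiAUC relates quantities over the same window); integrating from
  bolus arrival $t_0$ is available via `wiauc_from = "arrival"`.
* **The MTT origin.** MTT is "the average time for the contrast agent to
  pass through the region": a transit property. It is therefore measured
  from bolus arrival $t_0$, not from the acquisition origin — the arrival
  delay reflects injection-to-organ travel, not transit through the ROI.
  Published per-study MTT tables generally cannot disambiguate this
  convention; it is stated prominently here because comparisons across tools
  must match conventions before comparing numbers.

PI and WiPI are ratios of an area (a.u.·s) to a time (s) and are therefore
reported in a.u.; study tables sometimes print them in a.u./s, which is
dimensionally an intensity either way — the package keeps the dimensionally
consistent unit.

AUC deliberately uses the infinite-time closed form rather than integrating
the 55 s record; the `"diagnostics"` attribute of `extract_parameters()`
reports the AUC truncated at the record end and the extrapolated tail
fraction, so users can see how much extrapolation contributed (for typical
murine kinetics it is well under 1%).

PE, TTP, AUC, MTT, PI follow from the closed forms. WiR has no convenient
closed form: it is located by a 2048-point bracket over $(t_0, t_\mathrm{peak}]$
refined by golden-section search to machine precision, and WiAUC by adaptive
quadrature at `rel.tol = 1e-10`. The identities PI·MTT = AUC and
WiPI·RT = WiAUC hold by construction and are asserted in the tests, along
with agreement of all nine parameters against an independent brute-force
oracle (1 ms grid extrema plus quadrature in log-time) to within 0.1%.

## Fitting

`fit_bolus_model()` minimises the residual sum of squares with bounded
Levenberg–Marquardt (via minpack.lm), with bounds wide enough to be
physiological rather than informative: $O \in [0, \max y]$,
$A \in [0, 10\,\mathrm{range}(y)\,T]$, $\mu \in [\ln 0.1, \ln 60]$,
$\sigma \in [0.05, 3]$, $t_0 \in [0, T/2]$ for a record of duration $T$.
The initial point comes from the baseline/arrival estimate and the observed
peak (solving the PE closed form for $A$ at a template $\sigma = 0.5$);
8 seeded multi-starts perturb that point (multiplicative on $A$ and
$\sigma$, additive on $\mu$ and $t_0$) and the lowest-RSS converged solution
wins. Fits are deterministic given the configuration seed. A constant curve
short-circuits to $A = 0$ with a "non-perfused" flag, and extraction then
returns zero amplitudes with undefined (NA) time parameters rather than
inventing kinetics.

The baseline estimator is a median over a pre-arrival window with a
`k = 5` MAD detection threshold (defaults: initial window = first 10% of
samples). Because the true pre-arrival extent is unknown, the window is
refined iteratively — shrunk to the samples before each successive arrival
detection, or halved when the contaminated MAD is so inflated that nothing
exceeds the threshold — which removes the bias a fixed window suffers when
the bolus arrives early in the record. One honest limitation: for a smooth
lognormal onset the curve leaves the baseline *gradually*, so any
threshold-based detector flags arrival a few frames after $t_0$ (for the
canonical test curve, about 0.14 s at 36 frames/s); the fit, not the
detector, is responsible for the final $t_0$ estimate, and recovers it to
well under 1%.

Intensities are assumed linear (proportional to concentration). For
log-compressed display data, `linearise_tic()` inverts the compression given
the dynamic range (default 40 dB, the contrast-mode setting the acquisition
protocol specifies); the pipeline exposes this as `log_compressed = TRUE`.

## The synthetic study generator

`simulate_study()` emulates a two-arm (GnRH-analogue-treated vs saline
control), three-timepoint (day 0/10/20) murine ovarian study with 10 animals
per arm. Its generative defaults (`reference_effects()`) are the group
means and standard deviations of the study it emulates: two B-mode
measurements (ovary and dominant-follicle diameter, mm) and all nine CEUS
parameters, per arm and timepoint. Each animal's measurements are drawn from
the configured normal distributions truncated at zero (redraw with bounded
retries); for the CEUS curve, model parameters are back-solved so the
curve's true PE equals the drawn value — $\sigma$ fixed at 0.5, $\mu$ the
log of a 4–8 s transit draw, $A$ from the PE closed form, arrival 1–4 s,
baseline 2–8 a.u. — which keeps curves realistic while making ground truth
exactly known. With `match_auc = TRUE`, $\mu$ is instead solved so the AUC
matches its draw too. TIC noise defaults to additive Gaussian at 2% of the
curve's peak; cine loops plant an elliptical "ovary" (diameter within the
1–2.5 mm range the organ presents on B-mode) over a static multiplicative
speckle background (sd 10%).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: no acoustic physics (attenuation, shadowing,
nonlinear propagation), no microbubble destruction or replenishment, no
probe or animal motion, no wash-out phase beyond the model's own tail, and
measurement noise that is Gaussian rather than speckle-distributed inside
the ROI. The generator validates the *analysis chain* (fitting, extraction,
statistics) under known truth; it cannot validate the acquisition.

Per-timepoint group sizes are exposed as configuration rather than fixed at
10: published summary tables of this design sometimes show per-cell spreads
incompatible with the nominal n, so the effective CEUS n per cell is left to
the user.

## Statistics

`welch_from_summary()` implements the two-tailed unequal-variance t-test
from group means, SDs and sizes — the form required to reproduce published
comparisons when only summary tables survive — with Welch–Satterthwaite
degrees of freedom. `welch_from_samples()` summarises and delegates, so the
two routes agree exactly; the tests additionally verify equality with
`stats::t.test` to 1e-12 and agreement with a permutation test within
Monte-Carlo error. `compare_study()` tests every parameter at every
timepoint independently at $\alpha = 0.05$ with no multiple-testing
correction, mirroring the per-cell convention of the study design it
reproduces; a Benjamini–Hochberg switch (`adjust = "BH"`, off by default) is
provided for reuse where that convention is not wanted. The experimental
unit is the animal (one CEUS ovary per animal).

Two statistical facts worth knowing when interpreting simulation results:
the Welch test's true size at $n = 10$ per arm is slightly below the nominal
0.05 (about 0.048 under normality — a known property of the
Welch–Satterthwaite approximation, not an implementation artefact), and
truncation-at-zero makes some heavily-spread cells mildly non-normal. Both
effects are visible in the package's own null-calibration simulation, which
still lands within three binomial standard errors of 0.05.

## Problem sizes and numerical tolerances

The validation suite uses: 55 s × 36 fps grids (1981 samples) for fitting;
100 seeded replicates for noisy-recovery checks (median relative errors of
PE, AUC and TTP are all below 0.5% at 2% peak noise, against a 5% bound);
20 random parameter draws against the brute-force oracle at 0.1% relative
tolerance; 1000 simulated null studies (33 cells each) for type-I
calibration; and 500 replicates at $n = 6$ per arm for the power check on
the day-20 PE contrast, where empirical power is about 70%. Quadrature
tolerances are 1e-10 (relative); fit convergence follows minpack.lm's
information codes; identities are asserted at 1e-6.

## Limitations

The package analyses bolus wash-in only — no destruction–replenishment, no
wash-out parameters. It does not segment the ovary or propose ROIs; the mask
is user-supplied and fixed over the loop (the acquisition design this
targets fixes the probe mechanically). The lognormal form is a modelling
choice, not a claim about any vendor implementation; parameter values are
comparable across tools only where conventions (MTT origin, RT tangent,
WiAUC window) match. Group summaries feeding `welch_from_summary()` are
taken at face value; no correction for truncated or non-normal underlying
data is attempted.
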