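---
title: "Models and methods behind bioradr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bioradr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

Dynamic FDG bioradiography images living tissue — here a reconstructed
human epidermal model (RHEM), a stratified keratinocyte culture about
100 µm thick — incubated in medium containing the PET tracer
[¹⁸F]FDG. FDG enters cells through glucose transporters, is
phosphorylated by hexokinase and trapped, so trapped ¹⁸F activity reports
glycolytic activity and, through it, cell number and viability. The
tissue sits on a storage-phosphor radioluminography plate; exchanging
the plate repeatedly (by default seven 45-min exposures starting every
60 min over 405 min) gives a dynamic series of 2-D activity images
without destroying the tissue.

`bioradr` implements the full quantification chain for this experiment
and a synthetic phantom simulator that stands in for the unavailable raw
plate images.

## Plate response

The plate's photostimulated luminescence (PSL) is logarithmic in
absorbed dose — convenient for X-ray contrast, but it saturates with
radioactivity. The manufacturer calibration

$$\mathrm{nGy} = 8770 \times 10^{\,(\mathrm{PSL} - 1535)/1024 -
\log_{10} 1.25}$$

linearizes it into 80 kV X-ray-equivalent dose. `psl_to_dose()` and
`dose_to_psl()` are exact inverses; we read "log 1.25" as base-10
because the formula is written in decades (the /1024 term). One design
point deviates from the obvious placement: integer images can contain
PSL 0, which the formula would map to a spurious ~222 nGy-scale dose,
so a configurable clamp (`floor_psl`, default 1) is applied where
*images* are ingested (`extract_uptake_series()`), not inside the scalar
conversion — the scalar inverse pair must round-trip exactly for the
simulator and the calibration checks.

## Decay correction of finite exposure windows

For a window $[t_0, t_0 + \Delta]$ and decay constant
$\lambda = \ln 2 / T_{1/2}$ ($T_{1/2}$ = 109.77 min for ¹⁸F by default),
the measured window-integrated dose is rescaled by

$$f = \frac{\lambda \Delta}{e^{-\lambda (t_0 - t_{\mathrm{ref}})}
\left(1 - e^{-\lambda \Delta}\right)}$$

to the value that a constant reference-time activity would have
produced. The reference time defaults to the start of incubation so that
corrected values plot directly against incubation time. A useful exact
property falls out of the algebra: for a linearly growing trapped amount
the corrected frame value equals the true rate times the decay-weighted
mean time of the window, which is the window midpoint shifted by a
*constant*. Regressing corrected values on frame midpoints therefore
recovers the trapping rate exactly (the shift moves only the intercept),
which is why the midpoint is the regression abscissa; `time_col =
"start_min"` is available for sensitivity checks.

## The uptake-rate estimator

Trapping is modeled as irreversible with constant medium concentration
(tracer consumed ≪ supplied), i.e. a Patlak-type regime in which the
decay-corrected uptake grows linearly over the 405-min experiment.
`fit_uptake_rate()` is ordinary least squares of the decay-corrected
per-ROI series (nGy/pixel/min) on frame midpoint time; the slope, in
Δ nGy/pixel/min per minute, is the uptake rate used as the
viability/metabolism readout. It returns a small model object
(`uptake_fit`) with `print`, `summary`, `coef`, `predict`, `plot`,
`fitted` and `residuals` methods; the slope standard error comes from
the residual variance (7 frames, 5 degrees of freedom). The ROI
statistic is the plain mean over mask pixels — per-pixel normalization
makes values independent of ROI size for homogeneous tissue — and no
background subtraction is applied by default.

## The phantom simulator

`simulate_stack()` renders, per pixel and frame,

* tissue signal: rate × ∫ τ e^{−λτ} dτ over the window, the physical
  image of a linearly accumulating trapped amount;
* ambient background: the surrounding radioactive medium,
  `background_dose_rate` (nGy/pixel/min at t = 0) decaying with the
  nuclide, attenuated by `exp(-mu_per_um × thickness)` under the tissue;
* Poisson noise on a latent photon count (`noise_scale` photons/nGy,
  default 0.5), applied to the dose before plate rendering;
* the plate's logarithmic response, quantized to 16-bit PSL integers.

The background is deliberately *radioactive*: a non-decaying floor
would be inflated ~11-fold by the decay-correction factor of the last
frame and would bias every fitted slope upward by tens of percent; with
a decaying background the corrected series is exactly linear (offset by
a constant), which matches how an FDG-containing medium actually
behaves. Plate fog without a radioactive source is negligible by
comparison and is not modeled, nor is fading between exposure and
readout.

The per-well trapping rate is

$$r = b \cdot A \cdot \rho \cdot m \cdot \frac{1}{1 + g/K_m}$$

with medium activity $A$ (MBq/0.5 mL), viable cell density $\rho$,
metabolic modifier $m$ and glucose $g$ (mM). $K_m$ is the apparent
competitive constant of medium glucose; `fit_km_glucose()` fits it by
grid least squares to the reference percent-of-control series
(89/73/44/39/23% at 1/2/5/10/20 mM), giving 5.352 mM with a maximum
model-vs-reference deviation of 7.7 points. The base rate $b$ = 37.5
(nGy/pixel/min)/min/MBq places the standard control condition
(0.04625 MBq, 5 mM glucose) at ≈ 0.9 nGy/pixel/min per min, which keeps
all frames of all scenarios inside the plate's representable PSL range
(roughly 50–1800 PSL for the defaults) — the absolute dose scale is
otherwise unconstrained, since no raw images are available to anchor it.

### Replicate variability and the CV band

Reported control-tissue precision for bioradiography is a CV(SEM) of
5–13%. Photon statistics cannot produce that: averaged over a 12-mm ROI
(~900 pixels at 350 µm/px) the Poisson noise on a fitted slope is well
under 1%. The spread between replicate tissues is biological, so
`scenario()` draws each well's viable cell density lognormally around
its nominal value with CV 14% (mean-preserving). The realized density —
and therefore the realized trapping rate — is recorded in the design
table and ground truth, so parameter-recovery checks measure only
measurement error while group-level statistics see realistic replicate
scatter; with n = 4 the expected sample CV(SEM) is ≈ 6.5%, inside the
reported band. Destructive comparator readouts (MTT viability, DNA
content) are represented by the ground-truth viability/density fields
plus lognormal assay noise (`assay_readout()`, CV 4%, matching the 3–5%
plate-reader precision); their chemistry is not modeled.

### Scenario presets

`scenario()` reproduces the study designs: the activity titration
(0.0115625–0.37 MBq, six levels), the glucose series (control plus
1/2/5/10/20 mM at 0.04625 MBq), proliferation days (relative densities
0.45/1/1.25 for days 3/6/14, n = 5), chemical insults (survival
fractions 0.21/0.24/0.12/0.14 for the four corrosives, mirroring the
reported percent-of-control rates), and hypothermia/hypoxia (metabolic
modifiers 0.34 and 2.35 with ground-truth viability 1 — the dissociation
between metabolism and viability that motivates the method). The
schedule default follows the 60-min exchange convention (7 frames);
alternative frame counts are configurable since the acquisition is
described both as 45-min and 60-min spaced in different places.

## Thickness from attenuation

Tissue between the medium and the plate attenuates the ambient signal,
so a no-tissue exposure and a no-uptake (time-zero) tissue exposure give
a per-pixel transmission measurement:
$t = \ln(D_{\mathrm{bg}} / D_{\mathrm{tissue}}) / \mu$, analogous to
PET transmission-based attenuation correction. No measured µ is
available for this geometry; the simulator's µ (0.002 /µm, ~18%
attenuation through 100 µm) defines the oracle, and the median over the
ROI is the recommended summary (robust to the zero-clamp applied where
noise makes the tissue pixel brighter than the background).

## Group comparison: Steel test by permutation

Treatments are compared many-to-one against a shared control with the
Steel procedure: pairwise Wilcoxon rank-sum statistics (midranks for
ties), standardized, with family-wise adjustment from the joint
permutation distribution of the maximum statistic. We deliberately
replace the classical equicorrelated-normal critical tables with the
permutation null — exact enumeration when the number of label
arrangements is ≤ `max_exact` (the n = 4–5 designs with one treatment
are exact), seeded Monte Carlo with ≥ 10⁴ draws otherwise, using the
add-one convention so Monte-Carlo p-values remain valid. Two-sided is
the default since the original analyses do not state a direction.

A known limitation follows from discreteness, not implementation: with
k = 5 treatments and n = 4 per group the most extreme achievable
configuration (one treatment entirely outside the control range) still
has joint tail probability ≈ 0.11 two-sided, so no valid permutation
(or rank-table) test can reject at α = 0.05 — the family-wise error is
controlled but very conservative at these sizes. Power at n = 4
requires either one-sided alternatives with larger k-adjusted atoms or
more replicates.

`spearman_correlation()` (midrank ρ and ρ²) and
`coefficient_of_variation()` (100 × SEM/mean or SD/mean) complete the
statistical layer.

## Dosimetry

The decay arithmetic is exact closed forms: atoms from activity
$N = A T_{1/2} / \ln 2$ (4.39 × 10⁸ at 0.04625 MBq — the published
pairing of "0.0425 MBq" with 4.40 × 10⁸ atoms is internally
inconsistent at the 9% level; the atom count corresponds to
0.04625 MBq), expected last-nuclide time $T_{1/2} \log_2 N$ (52.5 h,
an expected-value definition chosen over a stochastic first-passage
time because it is deterministic and matches the printed figure), and
fraction remaining $2^{-t/T_{1/2}}$ (~10⁻⁴ after 24 h). Dosimetry is
reduced MIRD: cumulated activity $\tilde A = A_0/\lambda_{\mathrm{eff}}$,
absorbed dose $\tilde A E / m$ with a *config-supplied* absorbed energy
per decay (no particle transport), and effective dose
$D \, w_R \, w_T$. The pipeline's default energy/mass pair
(1.54 × 10⁻¹⁶ J, 1.13 × 10⁻⁵ kg — a 12-mm disc of 100-µm tissue)
reproduces the published tentative 6 mGy absorbed dose, whose own
inputs are not printed; 6 mGy × 1 × 0.01 = 0.06 mSv, well below the
1 mSv/year public limit.

## Numerical choices and problem sizes

* PSL quantization is to integer 16-bit; with Poisson dithering its
  effect on fitted slopes is ≪ 0.1%.
* Degenerate inputs: all-tied Steel data give p = 1 with a warning;
  constant vectors make Spearman ρ undefined (NA, flagged), not 0; a
  constant uptake series fits slope 0 with r² reported as 0.
* Validation problem sizes (chosen to make Monte-Carlo error small
  relative to the asserted tolerances): parameter recovery uses 100
  random wells on one plate; the activity-titration linearity check
  averages 4 independently seeded plates and the glucose-series check 8
  (each 6 conditions × n = 4), because a single n = 4 plate leaves
  ~10% group-mean sampling error against bands of a few points; the CV
  check averages 12 plates; Steel null calibration uses 2000 simulated
  datasets at 10⁴ permutations each.

## What passing tests do and do not show

The simulator emulates trapping linearity, competitive inhibition,
decay, plate response, photon noise and replicate scatter. It does not
emulate spatial heterogeneity within a tissue, glucose or oxygen
gradients across the 100-µm thickness, plate fading, frame-to-frame
misregistration from plate exchange, or optical scatter. Recovery of
simulated ground truth therefore validates the estimator chain and its
decay/response arithmetic — not the biological model itself, whose
wet-lab measurements (DNA correlation r² = 0.797, insult and
hypoxia/hypothermia percentages, etc.) come from data that are not
deposited and are covered here only qualitatively by the scenario
presets.
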