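# bioradr

Quantification of dynamic [¹⁸F]FDG bioradiography — repeated-exposure
autoradiography of living tissue with a PET tracer — for
viability and metabolism readouts in cultured tissues such as
reconstructed human epidermal models.

Non-invasive quality control of tissues grown for transplantation needs a
quantitative readout that does not destroy the sample (unlike the MTT
viability assay). Trapped [¹⁸F]FDG reports glycolytic activity; imaging
it dynamically on storage-phosphor plates yields an uptake *rate* per
tissue. This package implements the quantification chain for that
experiment:

* **Plate response** — storage-phosphor plates record photostimulated
  luminescence (PSL) that is logarithmic in dose; the manufacturer
  calibration
  `nGy = 8770 × 10^((PSL − 1535)/1024 − log10 1.25)`
  linearizes readouts into 80 kV X-ray-equivalent dose
  (`psl_to_dose()` / `dose_to_psl()`).
* **Decay correction** — finite exposure windows `[t₀, t₀ + Δ]` are
  rescaled to the start of incubation by
  `f = λΔ / (e^{−λ(t₀−t_ref)} (1 − e^{−λΔ}))`, λ = ln2/109.77 min for
  ¹⁸F (`decay_correction_factor()`).
* **Uptake-rate estimation** — decay-corrected per-ROI dose rates
  (nGy/pixel/min) grow linearly under irreversible (Patlak-type)
  trapping; `fit_uptake_rate()` fits the slope (Δ nGy/pixel/min per min)
  by ordinary least squares and returns a model object with the usual
  `coef`/`summary`/`predict`/`plot`/`residuals` methods.
* **Statistics** — `steel_test()` compares treatments many-to-one
  against a shared control (midrank Wilcoxon statistics, family-wise
  control via the permutation distribution of the maximum statistic;
  exact enumeration for small designs, seeded Monte Carlo otherwise),
  plus `spearman_correlation()` and `coefficient_of_variation()`.
* **Dosimetry** — ¹⁸F decay arithmetic (atoms from activity, expected
  last-nuclide time, fraction remaining) and simplified MIRD absorbed /
  effective dose (`dose_estimate()`).
* **Synthetic phantoms** — `phantom_spec()` / `simulate_stack()` /
  `scenario()` simulate the full multiwell experiment (trapping
  kinetics, competitive glucose inhibition with fitted Km ≈ 5.35 mM,
  physical decay, tissue-attenuated ambient background, Poisson noise,
  logarithmic plate rendering) with complete ground truth, and
  `attenuation_thickness_map()` recovers tissue thickness from the
  background transmission ratio.

## Worked example

Simulate the glucose-competition experiment (six conditions × four
replicate tissues at 0.04625 MBq), quantify it, and compare groups:

```r
library(bioradr)

sc     <- scenario("fig3_glucose", seed = 7)
sim    <- simulate_stack(sc$phantom)
series <- extract_uptake_series(sim$stack, sim$mask)
rates  <- fit_uptake_rates(series)
rates$condition <- sc$design$condition

relative_to_control(rates)
#>   condition n  mean    sem percent percent_sem
#> 1   control 4 1.750 0.2075   100.0       16.77
#> 2      1 mM 4 1.391 0.0809    79.5       10.50
#> 3      2 mM 4 1.529 0.1373    87.4       13.00
#> 4      5 mM 4 1.063 0.0724    60.7        8.31
#> 5     10 mM 4 0.596 0.0332    34.1        4.46
#> 6     20 mM 4 0.385 0.0296    22.0        3.11
```

Uptake rates fall monotonically with medium glucose — competitive
inhibition of FDG transport/phosphorylation — with group scatter typical
of n = 4 replicate tissues. A single tissue's fit:

```r
fit_uptake_rate(series[series$roi == 1, ])
#> Uptake rate fit ( 7 frames )
#>   rate: 2.36326 delta-nGy/pixel/min (SE 0.00101)
#>   intercept: 95.5659 nGy/pixel/min, r^2 = 1.0000
```

(The intercept is the ambient-background offset; the rate is this
well's realized trapping rate.) Group comparison:

```r
grp <- split(rates$slope, rates$condition)
steel_test(grp$control, grp[names(grp) != "control"], seed = 7)
#> Steel many-to-one rank test (two.sided, monte_carlo, 10000 arrangements; control n = 4)
#>  treatment n  statistic     p_adj signif
#>       1 mM 4 -1.7320508 0.3654635
#>      10 mM 4 -2.3094011 0.1099890
#>       2 mM 4 -0.5773503 0.9905009
#>      20 mM 4 -2.3094011 0.1099890
#>       5 mM 4 -2.3094011 0.1099890
#> signif: ** p < 0.01, * p < 0.05
```

Note the floor at p ≈ 0.11: with n = 4 per group and five treatments the
permutation null of the maximum statistic is discrete, and even a
treatment entirely outside the control range cannot reach p < 0.05 —
the family-wise test is valid but very conservative at these sizes (see
the methods vignette).

Dosimetry one-liners:

```r
effective_dose(6, w_R = 1, w_T = 0.01)  # 0.06 mSv, << 1 mSv/year limit
time_to_last_atom(4.4e8)                # 52.5303 h
```

An end-to-end run (`run_pipeline()`, or the thin CLI in
`inst/cli/bioradr.R`) writes the simulated TIFF stack, ROI mask, ground
truth, per-frame series, fitted rates, percent-of-control table, Steel
test and a JSON dose estimate, each stamped with the config hash and
seed; identical config + seed reproduce byte-identical outputs.

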