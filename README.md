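# dynpatlak

Simulation and kinetic analysis of **dynamic whole-body [18F]FDG PET**
studies in R.

Static FDG PET quantifies uptake with the standardized uptake value
(SUV = tissue activity / (injected activity / body weight)), which mixes
trapped tracer with free tracer circulating in blood and interstitium.
Dynamic whole-body acquisitions — an early continuous scan over the heart
followed by repeated whole-body passes — allow Patlak graphical analysis,
which separates the two. For an irreversibly trapped tracer, once the
reversible compartments have equilibrated (t ≥ t\*):

```
C_T(t) = Ki · ∫₀ᵗ Cp(s) ds + Vd · Cp(t)
```

where `C_T` is the tissue activity, `Cp` the plasma input function, **Ki**
(mL/min/mL) the net influx rate — `K1·k3/(k2+k3)` in the irreversible
two-tissue-compartment model — and **Vd** (mL/mL) the apparent distribution
volume of free tracer. Fitting this linear model per voxel yields parametric
Ki and Vd images; Ki suppresses blood pool and highlights metabolically
trapping tissue, which is the rationale for comparing cancer against
inflammatory lesions on Ki rather than SUV alone.

The package provides the full chain for desk-scale, fully synthetic studies:

- **Simulation** — acquisition schedules (cardiac frame ladder + evenly
  spaced whole-body passes), BMI-adapted dosing, triangular-bolus /
  double-exponential plasma input, irreversible 2TC and exact Patlak-linear
  tissue curves, frame sampling, duration-scaled Gaussian noise, 4D NIfTI
  phantoms with ground truth, and a two-group lesion cohort (60 cancer vs
  17 inflammatory/infectious) with log-normal Ki/Vd distributions.
- **Image-derived input function (IDIF)** — automatic aortic
  tube-of-interest segmentation, whole-blood extraction, time-varying
  blood-to-plasma conversion, double-exponential tail fit, and
  integral-preserving linear interpolation of the early bolus.
- **Patlak core** — `fit_patlak()` returns a classed model object with
  `print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods; weighted
  multilinear regression in closed form, voxelwise parametric maps, SUV
  images.
- **Measurements** — spherical VOIs of nominal volume, max/mean extraction,
  liver-normalized lesion-to-background ratios (LBR).
- **Statistics** — Shapiro–Wilk-gated t / Wilcoxon rank-sum comparisons,
  ROC with the Youden cutoff, Spearman correlation, and a six-variable
  cohort summary table.
- **Workflow** — `run_pipeline()` ties simulate → idif → fit → measure →
  compare into one reproducible, manifested run; a thin `exec/dynpet` CLI
  wraps the same functions.

## Worked example

```r
library(dynpatlak)

ph   <- build_phantom(shape = c(48, 48, 48), noise_scale = 0, seed = 1)
idif <- estimate_input_function(ph, t_max = 45)
maps <- fit_patlak_map(ph, idif$Cp, t_star = 20)

design <- patlak_design(idif$Cp, ph$schedule, t_star = 20, average = "frame")
lesion_tac <- label_tac(ph, 3)          # cancer-like lesion, true Ki = 0.03
fit <- fit_patlak(lesion_tac[design$frame], design)
print(fit)
#> Patlak graphical fit
#>   Ki = 0.03 mL/min/mL (3 x 10^-2)
#>   Vd = 0.9 mL/mL
#>   7 frames from t = 22.0 min, weighted R^2 = 1.0000
```

The lesion's Ki is recovered at `3.0 × 10⁻²` mL/min/mL and Vd at
`0.90` mL/mL — the phantom's ground truth — through the estimated input
function, not the true one. A full synthetic study:

```r
res <- run_pipeline(run_config(seed = 7, shape = c(24, 24, 24)), "out")
print(res$summary)
#> Lesion cohort summary: 60 cancer vs 17 inflammatory/infectious
#>
#>   SUV_max          7.7 (IQR 4.8) vs 5.9 (IQR 1.2)  p = 0.0153 * [wilcoxon]
#>   LBR_suv          2.0 (IQR 1.3) vs 1.5 (IQR 0.3)  p = 0.0153 * [wilcoxon]
#>   Ki_max [x10^-2]  3.0 (IQR 2.3) vs 2.3 (IQR 0.7)  p = 0.12 [wilcoxon]
#>   LBR_ki           2.8 (IQR 2.2) vs 2.2 (IQR 0.7)  p = 0.12 [wilcoxon]
#>   Vd_max           0.9 (IQR 0.6) vs 0.7 (IQR 0.3)  p = 0.00302 * [wilcoxon]
#>   LBR_vd           0.8 (IQR 0.5) vs 0.7 (IQR 0.3)  p = 0.00302 * [wilcoxon]
#>
#>   pooled LBR(Ki) 2.7 vs LBR(SUV) 1.9, signed-rank p = 2.51e-14
#>   Spearman rho[LBR(Ki), LBR(SUV)] = 0.96 (p = 1.56e-43)
```

Each line compares cancer vs inflammatory medians (IQR in parentheses) with
the normality-gated test; Ki is printed on the conventional ×10⁻² scale.
Individual cohorts fluctuate — here the Ki contrast misses significance at
this seed, while across repeated cohorts it is significant in ~88% of runs.

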