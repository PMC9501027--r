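---
title: "Dynamic whole-body FDG PET: simulation and Patlak analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic whole-body FDG PET: simulation and Patlak analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpatlak)
```

## The model

[18F]FDG is transported into cells (rate `K1`, mL/min/mL), transported back
(`k2`, 1/min) and phosphorylated (`k3`, 1/min); phosphorylated FDG is
effectively trapped over a one-hour scan, so the two-tissue compartment
(2TC) model is irreversible here. The measured tissue activity adds a
vascular contribution with fractional blood volume `vb`:

$$\frac{dC_1}{dt} = K_1 C_p - (k_2+k_3) C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1, \qquad
  C_T = C_1 + C_2 + v_b C_p .$$

After the reversible pool equilibrates (transient $\propto e^{-(k_2+k_3)t}$),
Patlak's graphical linearization holds:

$$C_T(t) \;=\; K_i \int_0^t C_p(s)\,ds \;+\; V_d\, C_p(t),
  \qquad K_i = \frac{K_1 k_3}{k_2+k_3},$$

with the net influx rate $K_i$ as slope and the apparent distribution volume
$V_d$ (free tracer in reversible compartments plus blood) as intercept.
`fit_patlak()` estimates $(K_i, V_d)$ by weighted multilinear regression in
the *undivided* form — response $C_T$, regressors $\int C_p$ and $C_p$ —
solved from the closed-form 2×2 weighted normal equations. The divided
Patlak-plot coordinates $C_T/C_p$ vs $\int C_p / C_p$ are equivalent
algebraically but amplify noise through the division; they are used only for
display (`plot()` method). Estimates are deliberately *not* clipped at zero:
negative $V_d$ or $K_i$ estimates preserve the estimator's sampling
properties, and clipping is a display concern.

Key assumptions: no tracer metabolites in plasma; all activities
decay-corrected to injection time (so no physical-decay term appears
anywhere — the standard quantification convention); irreversibility
($k_4 = 0$); the plasma curve doubles as the whole-blood proxy for the
$v_b$ term.

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `t_star` | 20 | min | start of the Patlak-linear window; the transient $e^{-(k_2+k_3)t}$ is below 2% of its initial size by 20 min for typical FDG rates ($k_2+k_3 \approx 0.2$/min). Exposed everywhere. |
| regression weights | ∝ frame duration | — | the variance of a reconstructed frame mean scales inversely with duration; weights are normalised to sum to 1 |
| `average` (design) | midpoint / frame | — | regressors evaluated at frame mid-times (instantaneous samples) or averaged over the frame (frame-mode data); voxelwise and cohort fits use `"frame"`, matching what a PET frame measures |
| partition model | 1.0 → 1.16, τ = 5 | — , min | plasma-to-whole-blood ratio $p(t)=p_\infty-(p_\infty-p_0)e^{-t/\tau}$; defaults near literature FDG plasma/whole-blood ratios |
| `switch_time` | 10 | min | IDIF junction between the interpolated early segment and the fitted tail; the end of the cardiac acquisition |
| `early_window` | 1 | min | window for aortic TOI segmentation (see below) |
| `noise_scale` | 0.05 | — | frame-noise magnitude; σ = scale·√(value/duration) |
| dose, weight | 210 MBq, 75 kg | — | SUV normalisation; the cohort's mean injected activity and a typical body weight |

## What the simulator emulates — and what it does not

The synthetic-data generator reproduces the study conditions: an early
single-bed cardiac segment (12×5 s, 4×10 s, 8×25 s, five 60 s frames,
ending at 10 min) followed by 11 whole-body passes at 35 s/bed over 5 beds,
so one tracked bed position is sampled every 175 s — the even spacing the
unidirectional protocol exists to guarantee. Both pass count and the number
of 60 s frames varied per patient in the protocol (11 ± 3 and 5 ± 4), so
both are parameters rather than constants. The plasma input is a triangular
bolus peaking at 30 s with a double-exponential washout — the same
functional form the IDIF tail fit assumes, so the input-function module can
be exact on clean data, which is what makes end-to-end recovery testable.
The phantom contains an aortic tube carrying whole blood
($C_p/p(t)$), a liver with micro-kinetics whose implied macro-parameters
sit at normal-liver values (Ki ≈ 1.0×10⁻², intercept ≈ 1.1), and spherical
lesions with exact Patlak-linear kinetics (cancer-like Ki = 3.0×10⁻²,
inflammation-like 2.0×10⁻², in mL/min/mL).

The lesion cohort draws true Ki and Vd log-normally around the group
medians, with the log-scale spread chosen so the interquartile range matches
the configured value ($\sigma = \operatorname{asinh}(\mathrm{IQR}/2m)/z_{0.75}$);
defaults are 60 cancer vs 17 inflammatory lesions at medians 3.0/2.0 ×10⁻²
(IQR 2.2/1.1) for Ki and 0.9/0.7 (IQR 0.5/0.4) for Vd — the shape of the
clinical comparison table this package emulates.

Not emulated: sinogram-level physics (noise is duration-scaled Gaussian on
reconstructed frames, a desk-scale surrogate for count statistics — real
penalized-likelihood reconstructions have spatially correlated,
non-Gaussian noise); scatter, randoms, attenuation; patient or respiratory
motion (the TOI re-centring hook exists but is disabled); partial-volume
effects beyond the one-voxel TOI erosion. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model, not
clinical performance.

## Numerical choices

- **2TC integration** uses `deSolve::lsoda` at tolerance 1e-10; the test
  suite cross-checks it against an independent fine-grid convolution of the
  closed-form impulse response.
- **Frame sampling** is a ≥32-subsample trapezoid per frame. The voxelwise
  and cohort Patlak designs average the regressors with the same quadrature,
  so exact Patlak-linear phantoms are recovered to machine precision.
- **Integral-preserving interpolation** places knots at frame boundaries;
  with the endpoint condition $v(0)=0$ the conservation equations reduce to
  the recursion $v_{k+1} = 2c_k - v_k$, which conserves every frame mean
  exactly (to 1e-10 in tests). The recursion is undamped, so curvature of
  the bolus over the 25–60 s frames leaves a persistent few-percent zig-zag
  in the pointwise curve. This is a known property of the scheme, not a
  bug: the Patlak regressors consume the *conserved running integral* and
  the fitted tail, both of which are accurate, and end-to-end lesion Ki/Vd
  recovery on noiseless phantoms is ≈10⁻⁵ relative. The assembled input
  function should not be read as a pointwise-faithful early bolus.
- **Aortic TOI segmentation** thresholds the duration-weighted early-mean
  image at 50% of its robust maximum (top 0.1 percentile excluded), keeps
  the largest 6-connected component and erodes one voxel. The default
  1-minute window is centred on the bolus peak deliberately: hepatic
  K1 is high (≈0.8 mL/min/mL), and by 2 min liver uptake already rivals
  blood-pool activity, whereas within the first minute blood exceeds every
  tissue severalfold. The threshold is relative, so the mask is invariant
  under global rescaling.
- **Double-exponential tail fit**: decay rates are profiled out by variable
  projection (amplitudes solve a weighted linear problem exactly), started
  from a log-spaced rate grid (10⁻³–1 /min), the five best starts polished
  by Nelder–Mead and a final Levenberg–Marquardt pass. Rates are returned
  with $\lambda_1 > \lambda_2$. At realistic noise the two rates are only
  jointly identifiable — the fitted *curve* is stable at the noise level
  while individual rate estimates can collapse ($\lambda_2 \to 0$); the
  package therefore treats the tail as a function, not as rate estimates.
- **Youden cutoff** ties are broken toward the smaller threshold (favouring
  sensitivity), with a 1e-12 slack so floating-point differences between
  equal J values cannot flip the tie-break.
- **Degenerate inputs**: an all-zero early image, an empty post-erosion
  mask, a collinear Patlak design, a zero-variance group in the normality
  gate, an empty group in a comparison and a non-positive liver reference
  all raise informative errors rather than propagating NaN. Per-voxel fit
  failures in maps are recorded as (0, 0) with QC 0, never raised.

## Design decisions

- "Wilcoxon test" for the unpaired 60-vs-17 comparison is the rank-sum
  (Mann–Whitney) test — exact for small tie-free samples, tie-corrected
  normal approximation otherwise; the signed-rank test is reserved for the
  pooled paired LBR(Ki) vs LBR(SUV) contrast. No multiplicity correction is
  applied: the summary reports raw p-values, matching the reporting
  convention of the analysis it mirrors.
- The normality gate requires Shapiro–Wilk p ≥ α in *both* groups; its
  combined pass rate under normality is $(1-\alpha)^2 \approx 0.90$, which
  the tests verify empirically.
- VOIs are spheres of nominal volume (liver 3 cm³, lesions 2 cm³) because
  the measurement protocol specifies volumes, not shapes; the liver
  reference VOI is auto-placed in the eroded, lesion-free liver core.
- The cohort's measured apparent distribution volume includes blood, so the
  drawn Vd is used directly as the Patlak intercept; the drawn blood-volume
  fraction is retained as metadata.
- Group-level LBR summaries are reported per group *and* pooled: the two
  views differ (pooled medians are not derivable from group medians), so
  both are computed.
- Seeds are mandatory function arguments; no function touches global RNG
  state without saving and restoring it.

## Problem sizes

The test suite and the acceptance script run phantoms at 16³–48³ voxels with
the full 40-frame schedule, 500-lesion recovery ensembles, 2000-seed null
calibrations and 200–500-seed cohort replications — sizes chosen so the
whole chain, including the voxelwise fits (closed-form and vectorised over
voxels), completes in minutes on a single CPU while keeping Monte-Carlo
error well below the asserted margins.

## Known limitations

Real dynamic whole-body data would additionally need inter-frame motion
correction (the hook exists, unimplemented), metabolite and dispersion
corrections for the IDIF, partial-volume correction for small lesions, and
a noise model matched to the reconstruction. The synthetic cohort's
LBR(Ki)/LBR(SUV) correlation is tighter than clinical data shows, because
all synthetic lesions share one liver reference and one input function.
Clinical headline numbers (group medians around 3.0 vs 2.0 ×10⁻², a Ki
cutoff near 2.6×10⁻²) emerge at similar magnitudes here by construction of
the generator, but sensitivity/specificity at the cutoff depend on
distribution tails the generator does not calibrate.
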