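# cmrflow

Absolute quantification of myocardial blood flow (MBF) from first-pass
cardiovascular magnetic resonance (CMR) perfusion curves, for imaging
scientists and cardiac physiologists working with saturation-recovery FLASH
dynamic series.

The package implements the full quantification chain:

* **Signal → concentration.** The SR-FLASH signal equation
  `SI = Ψ[(1−e^(−PD·R1))·a^(n−1) + b·(1−a^(n−1))/(1−a)]` with
  `a = cos α · e^(−TR·R1)`, `b = 1−e^(−TR·R1)` is calibrated from
  pre-contrast baseline frames (`calibrate_psi()`), inverted by bracketed
  root finding (`invert_signal()`), and concentrations follow from
  `c(t) = ΔR1/r1` (`concentration_from_signal()`). Samples at the signal
  plateau are clipped and flagged — that clipping is how residual
  arterial-input saturation survives into the analysis.
* **Tracer-kinetic deconvolution.** `mbf_fit()` fits the convolution of a
  tissue impulse response with the arterial input function (AIF) to the
  tissue curve by constrained multi-start nonlinear least squares, for two
  models: the empirical Fermi response `R(t) = 1/(exp[(t−τ0)k]+1)` over the
  AIF first pass, and the two-region one-barrier distributed-parameter (DP)
  model defined in the Laplace domain,
  `R(s) = (1 − exp[−s(T + s·Tc·Te)/(1 + s·Te)])/s`, over the full curve.
  Returned objects support `coef`, `summary`, `predict`, `plot`,
  `residuals`, `simulate`.
* **Microvascular parameters** from DP fits: vascular, interstitial and
  distribution volumes, permeability–surface-area product, extraction
  fraction and plasma flow (`microvascular_profile()`, haematocrit 0.45 by
  default).
* **Dual-bolus analysis.** `scale_prebolus_aif()` scales a dilute 1:5
  pre-bolus AIF and aligns its arrival to the main bolus at sub-frame
  precision, giving a saturation-free input function.
* **Cohort analysis.** Territory aggregation on the 16-segment model,
  perfusion reserve, reduced-flow classification at the strict
  2.5 mL/min/mL hyperaemic threshold, detection counts against
  angiography/FFR group labels, and the comparison statistics (paired t,
  Welch t, F, one-sample t, Bland–Altman).
* **Synthetic cohorts.** `generate_cohort()`, `generate_dual_bolus()` and
  friends produce gamma-variate AIFs with recirculation, DP-kinetic tissue
  curves and SR-FLASH signal rendering with a T2\*-attenuation term that
  emulates dose-dependent AIF saturation — so every stage is testable
  without patient data.

## Worked example

Simulate one hyperaemic acquisition, convert, fit both models and derive
the microvascular profile:

```r
library(cmrflow)

cfg   <- sim_config(seed = 7)
aif   <- generate_aif(cfg)                      # true [Gd] in blood, mM
truth <- dp_params(mbf = 3.0, t_overall = 9.0, t_cap = 2.5, t_int = 12.5)
tissue <- generate_tissue(aif, truth)

fit <- mbf_fit(aif, tissue, model = "dp")
fit
#> <mbf_fit> DP model, converged
#>   coefficients:
#>       mbf t_overall     t_cap     t_int
#>       3.0       9.0       2.5      12.5
#>   MBF = 3.000 mL/min/mL | SSE = 1.074e-15 over frames 1-50

summary(fit)$microvascular
#> <microvascular_profile>
#>   vb = 0.125 mL/mL   ve = 0.1787 mL/mL   vd = 0.2475 mL/mL
#>   PS = 0.858 mL/min/mL   MPF = 1.65 mL/min/mL   E = 0.405
#>   (hct = 0.45, flow convention 'mpf' for ve/vd/PS)
```

The fitted MBF of 3.0 mL/min/mL is the planted hyperaemic flow; the profile
says an eighth of the tissue volume is capillary blood, about 40% of the
tracer extracts into the interstitium per pass, and plasma flow is
MBF·(1−hct). Classification of the five-patient vessel-territory table:

```r
counts <- detection_counts(load_table4())
counts$dp$stenotic    # 12 of 12 stenotic vessels flagged below 2.5 mL/min/mL
counts$fermi$stenotic # 9
```

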