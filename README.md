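# vertperf

Quantification of lumbar vertebral bone-marrow perfusion from axial
dynamic contrast-enhanced MRI (DCE-MRI), for researchers studying how the
choice of arterial input function (AIF) shapes tracer-kinetic parameter
estimates in the spine.

A vertebra is supplied by a pair of segmental arteries branching off the
aorta. On an axial lumbar slice both vessels are visible at once, so the
same tissue curve can be deconvolved against three AIF variants: the
patient aortic ROI mean (AIF_A), a single segmental-artery pixel chosen
automatically on baseline-subtracted images (AIF_SA), and a
population-normalized aortic curve with a 6 mmol blood peak (AIF_PA,
Parker-style). The package implements the full chain:

* **Variable-flip-angle T1 mapping** for spoiled gradient-echo (SPGR)
  data: `S = M0_eff sin(a) (1 - E)/(1 - cos(a) E)`, `E = exp(-TR/T1)`,
  with DESPOT1-initialized bounded nonlinear fitting (`fit_t1_vfa`).
* **Signal-to-concentration conversion** by closed-form inversion of the
  SPGR signal-ratio relation and the relaxivity equation
  `C(t) = (1/r1)(1/T1(t) - 1/T10)`, `r1 = 3.6 s^-1 mmol^-1`
  (`concentration_from_signal`).
* **AIF construction**: first-pass windowing (baseline, upslope, peak,
  3–4 post-peak points, stopping before recirculation) and a 7-parameter
  first-pass bolus fit — Gaussian plus sigmoid-gated exponential washout —
  plus plasma conversion `Cp = Cb/(1 - Hct)`, `Hct = 0.42`, temporal SNR,
  and peak normalization (`estimate_aif`, `normalize_population`).
* **Extended Tofts model**
  `Ct(t) = vp Cp(t) + Cp(t) (*) Ktrans exp(-Ktrans t / ve)` with an exact
  exponential-kernel convolution, fitted pixel-wise (PWM) or ROI-based
  (RBM) (`tofts_forward`, `fit_tofts_curve`, `fit_map_pixelwise`,
  `fit_roi_based`).
* **AIF sensitivity study**: rescale the AIF peak by {1, 1/2, 1/4, 1/6}
  and delay it by 0–3 frames, refit 1000 noisy tissue curves (SNR 20) per
  condition, and summarize the fitted parameter distributions
  (`run_aif_sensitivity_study`).
* **A digital phantom** with known ground truth standing in for patient
  scans (`generate_phantom`), and **nonparametric comparisons** —
  Wilcoxon signed-rank, Mann–Whitney U, Kruskal–Wallis with
  Dunn–Bonferroni post hoc, exact by enumeration at small n
  (`compare_paired`, `compare_unpaired`, `compare_groups`).

See the vignette (`vignettes/vertebral-perfusion.Rmd`) for the models,
default parameters, and the design decisions behind them.

## Worked example

Generate the default noisy phantom and run the whole pipeline with
ROI-based fitting against all three AIFs:

```r
library(vertperf)
ph  <- generate_phantom(phantom_spec(seed = 7))
res <- run_pipeline(ph$vfa, ph$dynamic, ph$masks, ph$spec$protocol,
                    methods = "RBM")
print(res)
#> Vertebral perfusion analysis
#> AIF (population): peak 6.000 mmol, arrival frame 10 (19.0 s), SNR 5233.9
#> AIF (aortic): peak 5.056 mmol, arrival frame 10 (19.0 s), SNR 5233.9
#> AIF (segmental): peak 1.760 mmol, arrival frame 10 (19.0 s), SNR 58.9
#> -- population RBM --
#>   parameter    mean sd
#> 1    ktrans 0.01923  0
#> 2       kep 0.15029  0
#> 3        ve 0.12797  0
#> 4        vp 0.02120  0
#> -- aortic RBM --
#>   parameter    mean sd
#> 1    ktrans 0.02282  0
#> 2       kep 0.15029  0
#> 3        ve 0.15186  0
#> 4        vp 0.02515  0
#> -- segmental RBM --
#>   parameter    mean sd
#> 1    ktrans 0.06494  0
#> 2       kep 0.14941  0
#> 3        ve 0.43467  0
#> 4        vp 0.07276  0
```

Reading the numbers: the phantom's vertebra was generated with
Ktrans = 0.0225 min^-1, ve = 0.15, vp = 0.025 driven by the aortic curve,
and the aortic-AIF fit recovers them (0.0228, 0.152, 0.0252). The
segmental AIF peaks at roughly a third of the aortic peak (1.76 vs
5.06 mmol), and by the scaling law of the Tofts model the parameters fitted
against it inflate accordingly (Ktrans 0.065, ve 0.435) while the reflux
rate kep = Ktrans/ve is left untouched (0.149–0.150 min^-1 for every AIF) — the
same ordering reported for in-vivo lumbar data. The aortic AIF is also far
cleaner than the single-pixel segmental one (temporal SNR 5234 vs 59;
the phantom's iid pixel noise makes ROI-averaged curves much cleaner than
in vivo, so only the ordering is meaningful).

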