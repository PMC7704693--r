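# kwia — K-Space Weighted Image Average reconstruction for low-dose CT perfusion

CT perfusion (CTP) tracks a contrast bolus with repeated CT scans over about
a minute, at roughly three times the dose of a standard head CT. Lowering the
tube current by a fraction *b* lowers dose proportionally, but Poisson
counting statistics then cut the reconstructed-image SNR by √*b*. **kwia**
implements a reconstruction-side fix: each time frame's parallel-beam
sinogram is mapped to radial k-space (central slice theorem), divided into
concentric rings, and the outer rings — where radial sampling is sparse and
SNR-starved — are averaged across neighbouring time frames, while the
contrast-defining k-space center keeps single-frame temporal resolution.

The package is a full simulation-and-evaluation toolkit for this method,
aimed at CT reconstruction researchers:

* dynamic digital phantoms: a FORBILD-style head with three gamma-variate
  enhancing vessels (10/5/2.5 mm), and a rod-based perfusion phantom with a
  known arterial input and ground-truth CBF;
* Joseph forward projection, fan→parallel rebinning, Poisson low-dose
  simulation (both direct and variance-matched injection into already-noisy
  counts);
* the KWIA chain: ring design, view-shared averaging, Voronoi density
  compensation, Kaiser-Bessel regridding (β = 16.25, width 7, 2×
  oversampling), deapodization;
* baselines (Ram-Lak/Hann/Shepp-Logan FBP, plain regridding), image-quality
  metrics (ROI SNR/CNR, Bland-Altman), and perfusion quantification
  (time-density curves, truncated-SVD deconvolution to CBF).

## The core design rule

With `N_proj` distinct parallel angles per half rotation, radial k-space is
fully sampled out to radius `R = N_proj/π` (sample units). To restore
full-dose SNR at relative SNR `rSNR = √(dose fraction)`, the single-frame
central ring shrinks to

```
R1 = (N_proj/π) · rSNR
```

and the remaining annulus is split evenly to the edge,
`Rn = R1 + (N_det/2 − R1)(n−1)/(N_rings−1)`, each outer ring averaged over
1, 2, 4, 8, … neighbouring frames. For a 1152-view/728-detector scan this
gives `R1 = 130` at 50% dose and `92` at 25%, with the 4-ring layout
`[92, 182, 273, 364]` — see `ring1_radius()`, `ring_radii()`,
`ring_preset()`.

## Worked example

The shipped seven-condition study (full/50%/25% dose, plain and KWIA
reconstructions of a 27-frame dynamic head phantom at N_e = 4.8×10⁶ photons)
runs in a few minutes:

```r
library(kwia)
study <- run_study(digital_phantom_config(seed = 1), verbose = TRUE)
study$snr_table[, c("condition", "snr", "snr_pct_of_full", "sd_ratio_to_full")]
#>          condition    snr snr_pct_of_full sd_ratio_to_full
#>               full  96.66          100.00           1.0000
#>           50% dose  68.85           71.23           1.4039
#>   KWIA 50% 2 rings  94.27           97.53           1.0253
#>   KWIA 50% 3 rings 116.98          121.03           0.8263
#>           25% dose  51.03           52.79           1.8942
#>   KWIA 25% 3 rings  92.23           95.41           1.0481
#>   KWIA 25% 4 rings 106.07          109.74           0.9113
```

Reading this: halving/quartering the dose drops uniform-ROI SNR to ~71%/53%
of full dose (theory: 70.7%/50%) and raises noise SD by ~1.40×/1.89×
(theory: 1.41×/2×); KWIA brings SNR back to ≥95% of full dose, and more
rings recover more. Temporal fidelity of the smallest (2.5 mm) vessel:

```r
subset(study$temporal_table, vessel == "2.5mm")[, c("condition", "auc_err_pct", "fwhm_err_pct", "rmse")]
#>          condition auc_err_pct fwhm_err_pct     rmse
#>               full        0.00         0.00 0.000000
#>   KWIA 50% 2 rings        0.96         0.48 0.004986
#>   KWIA 50% 3 rings        0.94         0.66 0.004999
#>   KWIA 25% 3 rings        0.23         1.93 0.013366
#>   KWIA 25% 4 rings        0.13         2.28 0.013319
```

AUC of the bolus curve agrees with full dose to within ~1% and FWHM to
within a few percent; the RMSE (in unit-bolus-amplitude units) grows for the
smallest vessel at the lowest dose — the expected temporal-blurring cost of
averaging high spatial frequencies across frames.

Closed-loop perfusion check:

```r
spec <- rod_phantom_spec()
aif <- gamma_variate((0:26) * 2, 14, 11, 0.02)
ser <- render_perfusion_rod_phantom(aif, cbf_true = 60, "exponential", mtt = 4, spec)
tis <- extract_tdc(ser, roi_circle(mm_to_pixel(c(0, 30), 256, 0.75), 6), baseline_frames = 1)
art <- extract_tdc(ser, roi_circle(mm_to_pixel(c(-30, 0), 256, 0.75), 4), baseline_frames = 1)
svd_deconvolve(tis, art)$cbf   # ~60 ml/100g/min
```

A thin command-line front end (`inst/cli/kwia.R`) wraps the same functions
as `simulate` / `noise` / `recon` / `perfusion` / `metrics` / `study`
subcommands; sinograms travel in a versioned container
(`write_sinogram()`), image series as 4D NIfTI.

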