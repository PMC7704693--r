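---
title: "View-shared k-space averaging for low-dose CT perfusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{View-shared k-space averaging for low-dose CT perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kwia)
```

## The problem

CT perfusion (CTP) keeps the X-ray tube on for about a minute while a
contrast bolus transits the brain, which makes it one of the highest-dose
routine CT protocols. Cutting the tube current by a factor `b` cuts dose by
`b` but also cuts the photon flux by `b`, and because detection is
Poisson-limited the reconstructed-image SNR falls by `sqrt(b)`. This package
implements and evaluates a reconstruction-side remedy: *k-space weighted
image average* (KWIA), which recovers the lost SNR by sharing projection data
between neighbouring time frames — but only in the outer, detail-carrying
part of k-space, so that image contrast and temporal dynamics (which live in
the k-space center) remain those of a single frame.

## From sinogram to k-space

By the central slice theorem, the 1D Fourier transform of a parallel-beam
projection at angle theta equals the radial line at angle theta through the
object's 2D Fourier transform. A parallel sinogram (rebinned from fan-beam
data on a scanner; simulated directly here) therefore maps to a *radial*
k-space: `n_views` spokes over 180 degrees, each with `n_detectors` samples.
Radial sampling is densest at the center: with `N_proj` distinct parallel
angles the local azimuthal sampling matches the radial spacing out to radius
`R = N_proj / pi` (in radial sample units), and gets progressively sparser
beyond. The sampling-density surplus at low radius is exactly what KWIA
spends to buy back SNR.

## The KWIA filter

Each frame's k-space is divided into `N_rings` concentric rings. Ring 1 (the
disk of radius `R1`) always keeps the current frame's data. Ring `n > 1`
replaces each sample by the uniform average of the same sample over a window
of `M_n` neighbouring frames (defaults 1, 2, 4, 8, doubling outward). Since
Poisson noise is independent across frames, averaging `M` frames cuts the
noise variance in that ring by `M`, while the temporal dynamics of structures
small enough to have substantial energy in that ring are low-pass filtered
across frames — the method's one systematic cost, quantified below.

The ring radii follow the sampling-density argument: to restore full-dose
SNR at relative SNR `rSNR = sqrt(dose fraction)`, the single-frame region
shrinks to

    R1 = (N_proj / pi) * rSNR

and the remaining annulus is split evenly out to the k-space edge,

    Rn = R1 + (N_det/2 - R1) * (n - 1) / (N_rings - 1).

`ring1_radius()` rounds half-up after the multiplication; `ring_radii()`
keeps `R1` unrounded in the interpolation and rounds each final radius. With
1152 views per rotation (576 parallel angles) and 728 detectors this gives
R1 = 130 (50% dose), 92 (25%), and the 25%-dose 4-ring layout
[92, 182, 273, 364]. The shipped three-ring presets use the reference
middle radii (234/256/190), which were chosen empirically rather than by the
interpolation formula; `ring_spec()` accepts any explicit radii.

Two boundary conventions matter and are fixed as: ring membership is
`R_{n-1} < |k| <= R_n` with DC in Ring 1 (hard boundaries, no feathering),
and averaging windows are centered with offsets `ceil(-(M-1)/2)` to
`ceil((M-1)/2)` (for `M = 2`: the current and next frame). At the start and
end of the series the whole window *slides* to stay in range, keeping its
size `M` — so edge frames average the same number of frames, at the cost of
a slightly asymmetric temporal footprint there.

## Reconstruction chain

`reconstruct_kwia_series()` runs, per frame: 1D FFT of each projection;
ring-wise view-shared averaging; density compensation; convolution gridding
onto a 2x-oversampled Cartesian grid with a Kaiser-Bessel kernel
(`beta = 16.25`, width 7 cells); inverse 2D FFT; deapodization by the
kernel's analytic transform; central crop. A single ring reduces the chain
to plain regridding reconstruction (`regrid_reconstruct_series()`), the
package's non-view-shared baseline alongside Ram-Lak FBP
(`fbp_reconstruct()`).

Numerical choices worth knowing:

* **Density compensation.** For the regular radial trajectory the Voronoi
  cell of a sample at radius `r` is the annular sector of angular width
  `dtheta` and radial extent 1, with area exactly `dtheta * r` — the ramp
  profile classic to radial sampling. `voronoi_weights()` computes these
  closed-form cell areas (shared DC disk; outermost cell clipped to the
  sampled k-disk); the weights partition the disk to within a fraction of a
  percent.
* **Radial refinement.** The low-frequency spectrum of a head-sized object
  varies quickly on the scale of one radial sample, and a cell-wise constant
  quadrature of it biases flat regions by several percent. Because the
  object is contained within the detector span, zero-padding each projection
  before the spoke FFT evaluates the *exact* continuous spectrum at twice
  the radial density; the regridder does this internally (`radial_refine =
  2`, the default) and the bias drops to ~1%. FBP gets the same effect from
  its zero-padded ramp filter.
* **Coordinate convention.** The isocenter sits at 0-based pixel index
  `N/2` and detector offset 0 at channel index `M/2`, matching DFT index
  conventions exactly (no half-pixel phase ramps). All angles are
  counter-clockwise from +x; parallel views span `[0, pi)`.
* **Deapodization guard.** Grid points where the kernel transform falls
  below 1e-8 of its peak are masked to zero rather than divided.
* **FBP.** Frequency-domain Ram-Lak filtering with zero-padding to the next
  power of two >= 2x the detector count (avoids circular wrap), then linear
  detector interpolation during back projection. Hann and Shepp-Logan
  windows are available and trade noise for smoothing.

## Noise model

Detected counts are `N_d = Poisson(b * N_e * exp(-l))` for dose fraction
`b`, emitted photons `N_e` and line integral `l` — pure Poisson, no
electronic noise, constant `N_e` across rays. The package's default
`N_e = 4.8e6` is a clinical-equivalent full-dose flux. Two entry points
exist: `counts_from_line_integrals()` simulates any dose directly from
noiseless line integrals, and `inject_dose_reduction()` turns *already
noisy* full-dose counts into reduced-dose counts by adding a zero-mean
Poisson-derived term with variance `(b - b^2) * N_e * exp(-l)`, estimating
the unknown `l` from the observed counts; the output then has both mean and
variance of a genuine `b`-dose acquisition. Counts are floored at one
photon before the log transform; photon-starvation streaks are out of scope.

## The digital phantom study and its analysis

`run_study()` reproduces a seven-condition experiment on a FORBILD-style
dynamic head phantom: full, 50% and 25% dose with plain reconstruction, and
KWIA with 2/3 rings (50%) and 3/4 rings (25%). The phantom (512 px, 0.75 mm
pixels, 27 frames at 2 s) has an elliptical skull, uniform brain, two
ventricle-like ellipses, and three vessels of 10/5/2.5 mm diameter whose
enhancement follows a gamma-variate bolus `C(t) = c0 * tau^11 *
exp(11 * (1 - tau))`, `tau = t / 20 s`, peaking at the 10th frame.
Attenuation uses `mu_water = 0.02 mm^-1`; the bolus amplitude is
`c0 = 0.02 mm^-1`, i.e. a unit bolus on the same scale as brain tissue, the
convention of FORBILD-style phantoms (tissue ~1, bolus peak 1). Projections
use 1152 views per rotation (576 parallel angles) and 728 detectors at
0.75 mm pitch; detector spacing is not stated independently of the pixel
grid, so it defaults to the pixel spacing.

Measurement choices, fixed in the shipped configuration:

* SNR = mean/SD in a uniform brain circle (r = 22 mm at (0, 62) mm); CNR
  pairs it with a ventricle circle. Both use the same-region SD, so SNR is
  scale- but not shift-invariant.
* Vessel TDCs are ROI means over the vessel disk dilated by half a pixel —
  enough to capture the reconstruction point-spread footprint. The measured
  peaks are therefore partial-volume diluted (about 0.86/0.80/0.55 of `c0`
  for the three vessels), as in any real measurement; curves are reported
  in units of `c0` without per-curve renormalization.
* TDC baselines come from the noiseless reference reconstruction, which a
  simulation has exactly. Estimating the baseline from noisy pre-contrast
  frames instead would inject a coherent offset whose 54-s integral
  dominates the AUC comparison (~1.3% per condition at these noise levels)
  and would measure baseline estimation, not temporal fidelity. For
  measured data `extract_tdc()` averages pre-contrast frames.
* Temporal fidelity is summarized by AUC (trapezoid), FWHM (linear
  interpolation at half maximum) and RMSE against the full-dose curve.

What the phantom does and does not emulate: it reproduces the noise physics
(Poisson counts through realistic head attenuation), the sampling geometry,
and bolus dynamics at three vessel scales; it does not model anatomy, bone
beam-hardening, scatter, motion, or detector electronics. Passing the study
therefore validates the reconstruction and its noise/temporal trade-offs,
not clinical image quality.

## Perfusion quantification

The rod phantom (`render_perfusion_rod_phantom()`) encodes the
indicator-dilution model `tissue = (CBF / cbf_scale) * dt * (AIF (*) R)`
with an exponential or box residue `R`, an artery rod carrying the AIF and a
vein rod a delayed copy. `svd_deconvolve()` inverts the lower-triangular AIF
convolution matrix by truncated SVD, zeroing singular values below a
fraction of the largest, and reports `CBF = cbf_scale * max(residue)`. The
truncation threshold is *noise-matched regularization*: the default 0.2 is
the standard choice for clinical noise levels, and like any truncation it
deterministically clips the sharp onset of the residue — for
gamma-variate-shaped inputs and physiological transit times the noiseless
peak is biased down by roughly 7-25%. Noise-free validation therefore uses
a near-zero threshold (where recovery is exact up to rasterization), while
noisy-data behavior is characterized at the default threshold, including
the classic upward CBF bias as image noise grows. (At very small noise
levels the bias is not yet monotone — noise on the AIF slightly deepens the
effective regularization before tissue-curve noise amplification takes
over — so the monotonicity checks compare well-separated noise levels.) The default `cbf_scale = 6000 / 1.04`
(tissue density 1.04 g/ml, unit hematocrit correction) makes the closed loop
self-consistent; absolute clinical CBF constants are not claimed. The
delay-sensitive (non-circulant) formulation follows the classic SVD method;
under image noise SVD deconvolution overestimates flow, and the package's
tests check exactly that monotone bias direction.

## Problem sizes

The shipped defaults run the full-scale study (512-px images, 576x728
sinograms, 27 frames, 7 conditions) in a few minutes on one core, with the
compiled projector/gridder doing the heavy loops. Unit tests exercise the
same code paths on 64-256 px instances, where the brute-force oracles
(0.1-pixel ray marching, direct nonuniform DFT) are affordable.

## Known limitations

* 2D parallel-beam only; fan-beam data must be rebinned
  (`rebin_fan_to_parallel()`); no cone-beam support.
* Uniform averaging windows; non-uniform temporal weights are a
  configuration hook, off by default.
* No motion model: view sharing averages neighbouring frames, so subject
  motion would blur outer k-space across frames.
* The three-ring middle radii of the shipped presets are the reference
  values, not derivable from the interpolation formula.
* SART-TV and other iterative baselines are intentionally absent; FBP and
  plain regridding are the comparators.
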