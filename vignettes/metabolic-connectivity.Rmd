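---
title: "Metabolic connectivity from constant-infusion fPET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity from constant-infusion fPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpetconn)
```

## The measurement model

Under a constant [18F]-FDG infusion, plasma radioactivity rises
throughout the scan (peaking near 90 minutes) and tissue traps tracer in
proportion to local glucose uptake. Short (16-s) list-mode frames
therefore record a *cumulative*, monotonically rising time-activity
curve per voxel. Writing `r_i(t)` for the instantaneous uptake rate of
region `i`, the voxel signal is essentially `∫ r_i dt` plus
reconstruction noise and a point-spread blur. Metabolic connectivity is
defined on `r_i(t)`, not on the integral: two regions are "connected"
when their short-term uptake fluctuations co-vary over the scan.

The pipeline recovers `r_i(t)` with a spatio-temporal gradient filter:
the separable product of an isotropic 3-D Gaussian (σs, in voxels) and a
signed 1-D temporal Gaussian (σt, in frames) with weights
`sgn(t)·G(t; σt)` — negative on past frames, exactly zero on the current
frame, positive on future frames. Antisymmetry makes the operator odd:
its response to any temporally constant image is zero, so the
accumulated baseline drops out, and its response to a temporal ramp
recovers the slope. The kernel is truncated to a 7×7×7×7 window to
prevent the spatial lobe from averaging across neighbouring regions and
creating artificial correlations between adjacent ROIs.

Downstream, each product mirrors one arm of the study workflow:

* **fPET**: analysis window → gradient filter → parcellation (mean over
  voxels per region) → Pearson correlation across frames, per subject.
* **fMRI**: parcellation → high-pass (> 0.01 Hz) → Pearson correlation.
* **static PET**: frame sum → regional means → per-subject global
  demeaning → across-subject correlation ("metabolic covariance").
* Subject matrices are group-averaged entrywise on the Fisher-z scale.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `scan_duration_s` | 5700 | s | yields 356 complete 16-s frames |
| `frame_duration_s` | 16 | s | list-mode binning width |
| `analysis_onset_s` | 1800 | s | signal too weak before 30 min |
| `n_blocks`, `block_duration_s` | 6, 600 | –, s | 225 analysis frames |
| `sigma_spatial_vox` | 1 | voxels | spatial denoising width |
| `sigma_temporal_frames` | 2 | frames | gradient time scale |
| `window_extent` | 7 | voxels/frames | truncation of the kernel |
| `edge_policy` | `"valid"` | – | see numerical choices |
| `cutoff_hz`, `tr_s` | 0.01, 2.45 | Hz, s | BOLD drift removal |
| `half_life_s` | 6586.2 | s | fluorine-18 (109.77 min) |
| `psf_fwhm_mm` | 5 | mm | reconstruction post-filter emulation |
| `noise_sd` | 10 | activity | white imaging noise of the generator |
| `rho_within`, `rho_between` | 0.5, 0.1 | – | planted network structure |
| `signal_sd` | 1 | activity/s | planted rate fluctuation |

Raising σt estimates the gradient at a longer time scale (in the limit,
the start-to-end uptake difference, i.e. nearly static contrast);
raising σs trades noise suppression against cross-ROI mixing. The
defaults are the least-smoothing pair that preserves the planted
structure cleanly, matching how they are used in practice.

## What the synthetic generator emulates — and what it does not

`simulate_roi_uptake()` draws, per frame, correlated Gaussian deviations
(population correlation given by the community structure of
`network_spec()`, realised through a symmetric eigendecomposition square
root) around a baseline `10 + 1.0 · p(t)/p(peak)` activity/s, where
`p(t)` is the concave quadratic plasma input peaking at 90 min; rates
are floored at zero (uptake cannot be negative; with the default
baseline the floor is never active in practice). The *affine* rather
than strictly proportional plasma coupling is deliberate: the offset
keeps rates strictly positive while the small plasma-tracking term
(trend variance well under 1% of the fluctuation variance) keeps the
shared rising trend from swamping Pearson correlations, so planted
correlations are recoverable without detrending. `integrate_cumulative()`
then produces the monotone TACs, and `render_volumes()` paints them into
the parcellation, blurs with the 5-mm PSF and adds white noise. BOLD
data are simulated analogously (baseline 100, correlated fluctuations,
per-region linear drift to give the high-pass something to remove) for
one 10-minute run of 245 volumes. Per-subject motion severity varies
log-normally around a 0.25-mm framewise step, giving group summaries at
the sub-millimetre scale typical of resting human PET.

The generator runs on a 40×40×40 grid with 82 contiguous rectangular
regions tiling it. It emulates the *statistical* structure the analysis
assumes — monotone cumulative uptake on a rising plasma input, planted
stationary inter-regional correlation, PSF blur, white noise, rigid
motion, the directory layout — and deliberately not: anatomy (no brain
shapes, no grey/white contrast), scanner physics (attenuation, scatter,
randoms, Poisson counting), kinetic compartment models, motion-induced
image artefacts (traces are generated, not applied to the volumes), or
haemodynamic response shapes. Passing tests therefore demonstrate that
the *estimators* behave correctly under the assumed signal model, not
that real tissue obeys that model.

## Numerical choices

* **Frame indexing** is 0-based with half-open intervals
  `[i·Δ, (i+1)·Δ)`. A partial trailing frame is discarded.
* **Analysis window**: the window starts at the frame *containing* the
  onset (`floor(1800/16) = 112`) and spans `floor(3600/16) = 225`
  frames. Stability **blocks are anchored at the start time of the first
  retained frame** and frames are assigned to the block containing their
  midpoint; for the study window this gives the deterministic partition
  37, 38, 37, 38, 37, 38.
* **Kernel normalisation**: the truncated spatial lobe is renormalised
  to unit sum per axis; the temporal profile is scaled so the ramp
  response `Σ w(t)·t = 1`. Output is then uptake change per frame, and
  constants map exactly to zero. The filter is applied as a
  *correlation* (kernel not flipped), so positive temporal offsets
  address later frames.
* **Edge policy**: `"valid"` (default) trims `(w−1)/2 = 3` voxels per
  spatial face and 3 frames per temporal end (225 → 219 frames); the
  trimmed offsets travel with the image so the parcellation is cropped
  consistently. `"renormalized"` keeps the input geometry: at edges the
  truncated spatial weights are rescaled to unit sum, and the truncated
  temporal weights are recentred to zero sum and rescaled to unit ramp
  response, preserving both defining identities; it equals the valid
  output away from edges.
* **Correlation estimator**: Pearson on untransformed series; regional
  extraction uses the mean over voxels. Group averaging uses Fisher z by
  default (`fisher = FALSE` gives the plain mean); the choice is
  recorded in the provenance sidecars so both variants are comparable.
* **Plasma fitting** is ordinary least squares on the quadratic basis
  via QR; fits are made to *decay-corrected* concentrations (recorded in
  provenance). Decay correction references infusion onset, which
  coincides with the PET start.
* **High-pass** removes the discrete-cosine components below the cutoff
  (`k ≤ 2·n·TR·cutoff`) by orthogonal projection; rows come back
  zero-mean.
* **Degenerate inputs**: zero-variance time series are rejected naming
  the region; regions left empty after cropping are dropped with a
  warning and the matrix annotated; coefficient-of-variation maps flag
  zero-mean voxels as missing rather than infinite.
* **Storage**: volumes are written as 32-bit float NIfTI (like scanner
  output); `datatype = "double"` is available for lossless round-trips.
  Outputs contain no timestamps, so identical configurations and seeds
  reproduce byte-identical files.
* The blood schedule defaults to draws every `scan/9.5` seconds
  (10-minute spacing for the full-length scan); whether the reported
  sample count includes the pre-infusion baseline draw is ambiguous, so
  the schedule is configurable and never asserted.

## Problem sizes used by the tests

The suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which every statistical
claim is still comfortably testable: the full-pipeline recovery uses 82
regions on the 40³ grid, 225 frames and 10 subjects; Monte-Carlo checks
of the planted correlation use 200 seeds at 225 frames; oracle
equivalence uses 12×12×12×20 random images against a brute-force
seven-deep-loop correlation; the written-dataset and pipeline tests use
reduced grids (10³–14³) and 3–4 subjects; the motion cohort uses 27
subjects, matching the study's sample size.

## Known limitations

* The gradient filter is a linear, stationary estimator; deconvolution-
  or GLM-based baseline removal and adaptive kernels are out of scope.
* σs is specified in voxels and the kernel ignores voxel anisotropy
  (2.09 vs 2.03 mm is a 3% effect at the default width).
* The synthetic BOLD arm shares the PET grid and parcellation; real
  fMRI preprocessing (realignment, distortion correction, slice timing)
  is consumed upstream, not implemented.
* Motion parameters are summarised, not used to resample images; the
  displacement statistic covers translations only, with a per-axis
  variant exposed because the choice is not standardised.
* Across-subject metabolic covariance with realistic cohort sizes
  (tens of subjects) is statistically noisy; the tests use large
  synthetic cohorts where null bounds are sharp.
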