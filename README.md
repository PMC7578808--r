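# fpetconn

Metabolic connectivity analysis for constant-infusion FDG functional PET
(fPET), with the simultaneously acquired BOLD-fMRI and static-PET
comparison paths, and a synthetic-data generator that makes the whole
pipeline testable on a laptop.

## The problem

Functional PET administers [18F]-fluorodeoxyglucose as a slow constant
infusion across a ~95-minute scan, so the scanner can bin list-mode data
into short (16-s) frames and resolve *within-scan* changes in glucose
uptake. What each voxel measures, however, is *cumulative* trapped
activity: a monotonically rising time-activity curve riding on the rising
plasma input. To correlate regional uptake dynamics — "metabolic
connectivity" — the cumulative signal must first be converted into an
instantaneous uptake-change signal.

`fpetconn` implements that conversion and everything around it:

- **Frame-grid arithmetic** for the acquisition (5700 s binned into 356
  16-s frames; 225 frames retained from the 30-minute time point,
  spanning six 10-minute blocks).
- **The spatio-temporal gradient filter.** A separable 4-D kernel
  `w(x,y,z,t) = G3(x,y,z; σs) · sgn(t) · G1(t; σt)` — a 3-D spatial
  Gaussian (σs = 1 voxel) times a signed temporal Gaussian (σt = 2
  frames) with negative weights on past frames, zero on the current
  frame, and positive weights on future frames — truncated to a
  7×7×7×7 window and scaled so the response to a unit-slope temporal
  ramp is exactly 1. Correlating it with the 4-D image estimates the
  short-term change in glucose uptake, in activity per frame.
- **Connectivity products**: per-subject Pearson correlation of
  filtered, parcellated fPET time series; BOLD connectivity after
  high-pass (> 0.01 Hz) drift removal; across-subject static metabolic
  covariance of demeaned regional uptake; Fisher-z group averaging;
  block-wise connectome stability; filter-width sweeps.
- **Plasma and QC utilities**: fluorine-18 decay correction
  (`2^(Δt/T½)`, T½ = 109.77 min), second-order polynomial plasma-curve
  fits, group-average curves, and motion QC (mean relative framewise
  translational displacement) from 6-column `.par` realignment files.
- **A synthetic generator** (`simulate_subject()`, `simulate_dataset()`)
  that plants a known inter-regional correlation structure on the uptake
  signal, integrates it into cumulative TACs, renders 4-D NIfTI volumes
  with point-spread blur and imaging noise, and writes the BIDS-like
  layout (`sub-*/pet`, `sub-*/func`, `derivatives/mcflirt/.../*.par`,
  `participants.tsv`) the pipeline consumes.

## Worked example

```r
library(fpetconn)

grid <- build_frame_grid(5700, 16, 1800)
#> <frame_grid> 356 frames of 16 s over 5700 s (analysis onset 1800 s)
length(analysis_window(grid))
#> [1] 225

kern <- build_gradient_kernel(sigma_spatial_vox = 1, sigma_temporal_frames = 2)
#> <gradient_kernel> 7x7x7x7, sigma_s = 1 vox, sigma_t = 2 frames

## plant a 4-community network on 82 regions and push one synthetic
## subject through the full fPET path
net  <- network_spec(n_roi = 82, n_communities = 4,
                     rho_within = 0.5, rho_between = 0.1)
acq  <- acquisition_spec()           # 40^3 grid, 5-mm PSF, noise SD 10
parc <- synthetic_parcellation(acq$grid_shape, net$n_roi)

rates <- simulate_roi_uptake(net, acq, seed = 11)   # uptake change / s
cum   <- integrate_cumulative(rates)                # what the scanner sees
pet   <- render_volumes(cum, parc, acq, seed = 12)
#> <dynamic_image> 40x40x40 voxels, 225 frames (grid indices 112..336)

grad <- apply_gradient_filter(pet, kern)            # cumulative -> change
conn <- subject_connectivity(extract_roi_timeseries(grad, parc))
#> <connectivity_matrix> 82x82, fpet/subject

same <- outer(net$block_assignment, net$block_assignment, "==")
ut   <- upper.tri(conn$values)
round(c(within  = mean(conn$values[same & ut]),
        between = mean(conn$values[!same & ut])), 3)
#>  within between
#>   0.615   0.239
```

The recovered within-community correlations clearly exceed the
between-community ones, and their difference (0.38) reproduces the
planted gap (0.5 − 0.1 = 0.4). Block-wise stability of the same subject:

```r
bs <- block_stability(rates)
bs$block_sizes
#> [1] 37 38 37 38 37 38
round(bs$similarity, 3)
#> [1] 0.794 0.791 0.777 0.720 0.754 0.878
```

A whole dataset can be simulated, written to disk and analysed end to
end:

```r
simulate_dataset(3, "my_dataset", net, acq, seed = 1)
res <- run_pipeline(pipeline_config(), discover_dataset("my_dataset"))
dim(res$group_fpet$values)   # 82 x 82
```

A thin command-line interface wrapping these functions ships in
`inst/cli/fpetconn.R` (verbs `simulate`, `plasma`, `filter`,
`connectome`, `qc`, `sweep`, `run`).

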