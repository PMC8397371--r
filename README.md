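# corralspt

Single-molecule binding kinetics on micropatterned ligand corrals.

## The problem

Receptor clustering is widely believed to change signaling output, but
comparing clustered and non-clustered receptors across different cells
confounds the clustering effect with cell-to-cell variability. Hybrid
micropatterned substrates solve this by displaying the same ligand
(ephrinA1, binding the EphA2 receptor tyrosine kinase) in micron-scale
**mobile** corrals (fluid supported lipid membrane, clustered by the cell)
and **immobile** corrals (polymer-grafted, cannot cluster), side by side
under a single cell. Spatially resolved single-molecule imaging then reads
out binding kinetics of downstream adaptors (Grb2, SOS, NCK, N-WASP) in
the two region types of the *same* cell.

`corralspt` reimplements that analysis as a tested, reusable R pipeline,
together with a ground-truthed synthetic-data generator, so that every
kinetic and intensity-ratio comparison can be validated on data with known
truth:

* **synthetic data** — corral layouts, Poisson binding events with
  two-exponential dwell mixtures and photobleach competition, confined
  Brownian motion, TIRF movie rendering (Gaussian PSF, Poisson/read
  noise), ligand-channel images with rim-trapped clusters, corral
  intensity tables and recruitment time series with configured
  fold-changes;
* **detection** — matched-filter spot detection with subpixel Gaussian
  refinement (including two-emitter refits for unresolved pairs), plus
  single-molecule diagnostics (intensity unimodality, photobleach step
  counting);
* **tracking** — greedy nearest-neighbor linking, frame-quantized dwell
  times with censoring, first-appearance localization images, MSD and
  confinement diagnostics;
* **regions** — corral segmentation from the ligand channel, mobility
  classification by a clustering index, region assignment of trajectories;
* **kinetics** — survival curves, the two-order exponential decay fit
  `y = y0 + A1·exp(-t/τ1) + A2·exp(-t/τ2)` with 0.5% tail truncation
  (τ2, the slow constant, is the comparison statistic; K_off = 1/τ2),
  photobleach controls, appearance-based K_on, paired per-cell t-tests;
* **quantify** — background-subtracted corral intensities, per-cell
  channel ratios, normalized time-lapse heatmaps, max/cumulative
  recruitment per ligand, nuclear signal ratios;
* **pipeline** — `run_simulated_experiment()` / `run_measurement()` with
  YAML/JSON configuration, seeded reproducibility and JSON reports, plus a
  thin CLI at `inst/scripts/corralspt-cli.R`.

## Worked example

Recover the slow dwell constant from synthetic dwell times drawn at the
mobile-region Grb2 condition (slow component 508 ms, fast component 80 ms,
fraction 0.55), frame-quantized at 50 ms:

```r
library(corralspt)
set.seed(7)
tt  <- simulate_dwell_times(10000, f1 = 0.55, tau1 = 0.08, tau2 = 0.508)
s   <- dwell_sample(quantize_dwells(tt, dt = 0.05), dt = 0.05)
fit <- fit_two_exponential(survival_curve(s))
fit
#> Two-order exponential decay fit
#>   y0 = 0, A1 = 0.904, tau1 = 0.08069 s, A2 = 0.5683, tau2 = 0.5008 s
#>   RSS = 6.576e-05 on 47 points (truncated at 2.4 s)
```

The fitted `tau2` of 0.5008 s recovers the configured 0.508 s within 1.5%;
`tau1` recovers the 80 ms fast component. Amplitudes are reweighted by
frame quantization and are not compared.

A full simulated experiment (4×4 alternating corral grid, 1000 frames at
20 frames/s, default photobleach rate 0.2/s):

```r
rep <- run_simulated_experiment(list(
  layout = list(n_rows = 4, n_cols = 4, radius = 1, spacing = 3),
  sim = list(n_frames = 1000), seed = 1), render = FALSE)
#> tau2 mobile   447 ms (truth 508)
#> tau2 immobile 418 ms (truth 451)
#> n mobile 2071  n immobile 2023  corrals 16
```

The estimates are *apparent* dwell constants — photobleaching at 0.2/s
shortens the configured 508/451 ms to expected apparent values of
462/414 ms, and the fits land within a few percent of those. The
mobile/immobile ratio, the quantity actually compared across regions, is
insensitive to the bleach contribution; the bleach rate itself is
measured from a membrane-anchored control with
`fit_photobleach_control()` and reported, not subtracted. With
`render = TRUE` the same chain runs through movie rendering, spot
detection and mask segmentation instead of using ground-truth positions.

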