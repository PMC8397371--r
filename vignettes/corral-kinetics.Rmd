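---
title: "Single-molecule binding kinetics on micropatterned ligand corrals"
author: "corralspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule binding kinetics on micropatterned ligand corrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corralspt)
```

## The measurement

Micropatterned hybrid substrates display a receptor ligand (ephrinA1, the
EphA2 ligand) in two configurations within the reach of a single cell:
micron-scale *mobile* corrals, where the ligand sits on a fluid supported
lipid membrane and is gathered into clusters by the cell, and *immobile*
corrals, where the ligand is grafted to a polymer and cannot move. Because
both configurations face the same cytoplasm, any difference in downstream
signaling between neighboring corrals isolates the effect of
ligand:receptor clustering itself.

The single-molecule readout is sptPALM: a sparse subset of
fluorescent-protein-tagged adaptors (Grb2, SOS, NCK, N-WASP) is
photoswitched and imaged by TIRF at 20 frames/s for 1000 frames, at an
active density of about 0.5 molecules/µm². Each binding event contributes a
trajectory; the frame-quantized trajectory duration is its dwell time. The
distribution of dwell times t in a region is summarized through its
empirical survival function and fitted with a two-order exponential decay

$$ y(t) = y_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}, $$

whose slower constant $\tau_2$ is the comparison statistic: the fast
component absorbs short-lived events (fluorophore blinking, cytoplasmic
molecules crossing the evanescent field), the slow component reflects
genuine binding. The apparent off-rate is $K_\mathrm{off} = 1/\tau_2$; the
association rate $K_\mathrm{on}$ is estimated by counting new molecular
appearances per area and time. Because cell-to-cell variation of these
constants is of the same order as the mobile-immobile difference, all
kinetic comparisons are paired per cell (paired Student's t-test on
per-cell mobile and immobile values).

## What the synthetic-data generator emulates

No raw movies accompany the study, so the package ships a first-class
generator whose defaults encode the acquisition conditions: 20 frames/s,
1000 frames, ~0.5 active molecules/µm² inside corrals, ligand densities of
50–100 molecules/µm², and dwell mixtures with slow components in the
140–510 ms range. The generative chain is:

1. **Layout** (`make_pattern_layout`): disjoint circular corrals on a
   checkerboard of mobile/immobile classes.
2. **Binding events** (`simulate_binding_events`): per-corral Poisson
   arrivals with rate `k_on` · area; dwell times drawn *in continuous
   time* from `f1 · Exp(tau1) + (1 - f1) · Exp(tau2)`; an independent
   exponential photobleach clock with rate `k_b`; the observed dwell is the
   minimum of dwell, bleach and remaining movie time. Frame quantization
   happens only at analysis time, so the generative truth is independent of
   acquisition settings.
3. **Motion**: mobile-region molecules perform reflected Brownian motion
   inside a confinement disk (radius 0.3 µm, D = 0.05 µm²/s by default) —
   the apparent diffusion of receptor-bound adaptors is strongly confined;
   immobile-region molecules only jitter by the localization precision
   (30 nm). Binding positions are uniform over the corral by default;
   `add_cluster_sites()` instead gathers mobile binding around the ligand
   cluster, reproducing clustered localization images.
4. **Rendering** (`render_movie`): integrated 2-D Gaussian PSFs
   (σ = 0.8 px = 0.13 µm at the 0.16 µm pixel of a 100× EMCCD setup),
   500 photons per molecule per frame, Poisson shot noise, constant camera
   background (100 counts) and Gaussian read noise (2 counts). EMCCD excess
   noise can be approximated by doubling the shot-noise variance
   (`excess_noise`, off by default).
5. **Ligand channel** (`render_ligand_channel`): uniform disks; after cell
   contact, 95% of a mobile corral's intensity sits in a single rim
   punctum at 0.7 radius (clusters are trapped at the corral periphery),
   conserving total intensity. The cluster compaction is not reported in
   the source data, so `clustered_fraction` is a free parameter.

The generator reproduces the *statistical* structure the analysis relies
on — arrival statistics, dwell mixtures, censoring, photobleach
competition, shot noise — but not everything about real movies: no drift,
no flat-field or vignetting, no fluorophore blinking within a binding
event, no cell boundary, and lognormal rather than mechanistic cell-to-cell
variability. Passing tests therefore validate the estimators under the
assumed noise model, not the microscope.

## Analysis choices and their rationale

**Detection.** The cross-correlation detector is a matched filter: local
maxima of the correlation with a zero-mean, unit-norm Gaussian kernel,
thresholded at 5 robust noise units (median absolute deviation of the
response — robust against the sparse bright spots themselves). Candidates
are refined by least-squares 2-D Gaussian fits with free width in
[0.5, 2] · σ~PSF~. At 0.5 molecules/µm² about 15% of molecules have a
neighbor within the diffraction limit; a fit substantially wider than the
PSF is therefore re-fitted with a fixed-width two-emitter model and split
when the doublet at least halves the residual sum of squares (the standard
high-density refinement). Fits still pinned at the width bounds are
discarded as aggregates. Detection is invariant to constant offsets by
construction (zero-sum kernel, free background in the fit).

**Tracking.** Plain greedy nearest-neighbor linking, ties broken by
localization index, no gap closing by default (`gap_max = 0`); at low
density this equals the optimal bipartite assignment (property-tested
against exhaustive enumeration). The default search radius is
2 · σ~PSF~ pixels: more than 3 standard deviations of the per-frame
displacement of the confined motion model, but tight enough that molecule
exchanges at the working density rarely mislink. For sparse studies such
as appearance counting a wider radius (4 · σ~PSF~) is preferred, since
splitting a track on one large step creates a spurious appearance while
wrong links are vanishingly rare at low density.

**Dwell times and censoring.** A track's dwell is the number of frames
spanned times the frame interval, so a single-frame appearance has dwell
50 ms at the default settings (the convention is not externally fixed; it
is exposed through the data, not hard-coded into the fit). Tracks touching
the first or last movie frame have unknown true duration and are flagged
censored; they are excluded from fitting by default.

**Survival fitting.** The fit target is the empirical survival
(complementary cumulative) curve rather than a binned histogram: it is
bin-free and avoids an arbitrary bin width. Points where fewer than 0.5%
of the molecules remain are truncated — the sparse long-dwell tail is
noisy but represents a negligible fraction of molecules. The fit is
unweighted nonlinear least squares (Levenberg-Marquardt with positivity
bounds), initialized at τ₁ = dt, τ₂ = 2 · mean dwell, A₁ = A₂ = 0.5 · S₁,
y₀ = 0, with five jittered restarts and best-RSS selection; components are
reordered after convergence so τ₂ ≥ τ₁. Binomial-variance weighting is
available behind the `weights` argument but is not the default. Because
the frame-quantized mixture survival is itself exactly a sum of two
geometric decays with the same time constants, the estimator is unbiased;
tests verify agreement with an independent maximum-likelihood fit of the
quantized mixture on the same draws.

**Photobleaching.** The bleach rate from a membrane-anchored control
(CAAX construct, single-exponential fit) is *reported next to* the species
off-rates, never subtracted: the comparisons are of apparent dwell times
under identical illumination, and an absolute deconvolution of bleaching
is not reliable at these photon budgets. `corrected_koff()` computes
1/τ₂ − k_b for reference.

**Masks and regions.** Corral masks are segmented from the pre-contact
(unclustered) ligand reference — Otsu threshold, connected components,
area within [0.5, 2]× and circularity ≥ 0.6 of the expected disk — then
dilated by one pixel so rim-trapped clusters stay inside their corral;
areas and mean ligand intensities are measured before dilation. Mobility
is classified on the post-contact image by the clustering index
(99th-percentile / mean intensity, threshold 3): clustered corrals are
strongly peaked. Automated segmentation reconstructs what was done by
manual outlining; a ground-truth mask (`layout_to_mask`) can override it
anywhere. A trajectory's region is decided by its *first-appearance*
position — the binding location defines the signaling region — and tracks
starting on background are excluded from region kinetics.

**Quantification.** Corral intensities are background-subtracted (median
of off-pattern pixels by default, or a local 3-px annulus), floored at
zero. Channel ratios are computed per corral, averaged per cell and
region (the per-cell averaging convention), and compared pairwise across
cells. Time-lapse heatmaps divide by the single per-cell maximum so the
hottest block is exactly 1. Maximum and cumulative recruitment use a
30-min window at 30 s sampling by default, the cumulative integral being
the trapezoid rule on that grid, both normalized by the corral's ligand
intensity. Nuclear readouts divide the mean in-mask net signal by the
substrate ligand intensity; nuclear masks are inputs, not computed.

**Photobleach step counting.** Single-molecule status is checked by
piecewise-constant model selection on intensity traces with a BIC-style
penalty of 2 · ln(n) · σ̂² per parameter. A step adds two parameters (a
level and a change point), i.e. 4 · ln(n) · σ̂² per step; the smaller
one-parameter penalty misclassifies roughly a quarter of flat noisy traces
as stepped, while the two-parameter count keeps that error near 3%
without affecting sensitivity to genuine bleach steps.

**Validation metrics.** Ground-truth matching is not one-to-one: a
molecule is recalled if any detection lies within 2 px, and a link agrees
with the truth if a common molecule lies within 2 px of both endpoints.
At sub-diffraction separations a single detection legitimately represents
two molecules, and molecular identity is physically unresolvable, so
exclusive assignment would penalize the detector for physics. The strict
per-molecule identity is still asserted (≥ 95%) alongside the consistency
metric (≥ 99%) in the test suite.

## Numerical conventions and degenerate inputs

* Coordinates are continuous and zero-based in pixel units; a molecule on
  pixel (row r, col c) has x = c − 0.5, y = r − 0.5. Multiply by
  `pixel_size` for µm.
* Empty inputs return empty, typed results (empty event lists, all-zero
  localization images); an all-zero ligand image yields an empty mask with
  a warning status rather than an error.
* Identical paired values give t = 0, p = 1; constant non-zero differences
  are reported as significant beyond machine precision with a
  `zero_variance` flag rather than as an error.
* All randomness is controlled by integer seeds (`sim_config(seed = )`,
  `rng_seed` arguments); the same seed reproduces event tables and movies
  bit for bit, and run reports carry the seed and a configuration hash.

## Problem sizes used by the test suite

The suite regenerates everything programmatically. Dwell-recovery checks
use 10,000 dwells per draw with medians over 50 seeds per condition across
the eight reported kinetic conditions (τ₂ between 140 and 510 ms). The
end-to-end movie check uses one 4×4 corral field (12 × 12 µm at
0.16 µm/px) for 1000 frames at the working density, about 24,000
localizations. Ratio-recovery checks run at the reported sample sizes
(26, 15, 19 cells; 103 + 82 cells for the nuclear readout) and average a
handful of replicate simulations so that the Monte-Carlo error of the
check sits well below the tolerance being asserted. Appearance-rate
checks pool five simulated cells per experiment, the study's sample size
for single-molecule comparisons.

## Known limitations

* The two-exponential model is descriptive, not mechanistic; when the two
  constants are within a factor of ~2 the split between components is
  ill-conditioned, and only τ₂ should be interpreted.
* Greedy nearest-neighbor tracking has no motion model; identity through
  dense crossings is approximate (quantified above), and gap closing is
  off by default.
* Dwell times are not corrected for photobleaching or for tracking-induced
  splitting; both affect mobile and immobile regions alike, so paired
  comparisons are insensitive to them, but absolute off-rates inherit the
  bias.
* The renderer models an idealized camera (no EM gain register, no drift,
  no flat-field error); the EMCCD excess-noise option only doubles the
  shot-noise variance.
* `K_on` normalization per ligand intensity is available
  (`normalize_by_ligand`) but off by default; which normalization the
  original quantification used is ambiguous, and both modes are exposed.

## A minimal run

```{r example, eval = FALSE}
report <- run_simulated_experiment(list(
  layout = list(n_rows = 4, n_cols = 4, radius = 1, spacing = 3),
  sim = list(n_frames = 1000),
  seed = 1
))
report$estimates$mobile$tau2_s     # slow dwell constant, mobile corrals
report$estimates$immobile$tau2_s
```
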