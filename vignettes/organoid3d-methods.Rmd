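---
title: "organoid3d: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{organoid3d: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# Data model and conventions

A well is imaged as a grid of fields; each field is a z-stack of 2D planes
in several channels. `assembleWell()` places tiles edge-to-edge in
row-major field order into one `(channel, z, y, x)` array — the axis order
used everywhere. Coordinates are 0-based; bounding boxes are half-open
`[start, stop)`. Physical units enter through the voxel size
`(dz, dy, dx)` in µm; the default simulated geometry uses `(5, 1, 1)` µm,
i.e. a 9:1-class z anisotropy typical of high-content confocal screens
where coarse z sampling keeps imaging time and data volume manageable.
Fields are assumed to tile with **zero overlap**; overlapping layouts are
rejected rather than silently blended, because no registration model is
implemented. Volumes persist in a minimal Zarr-v2 layout directory store,
chunked one z-plane per chunk so single-plane reads touch a single chunk
file; intensities are unsigned 16-bit by default, and all operations accept
any numeric array.

# Stage 1: organoid segmentation

Per field, in order:

1. **Grayscale** as the per-pixel maximum over the fluorescence channels.
   The maximum (rather than a mean) keeps organoids visible when a
   mixed-clone well puts each organoid's signal predominantly in one
   channel.
2. **Cleaning**: the 2D z-maximum projection is binarised at a low debris
   threshold (default 2% of the dtype range, i.e. 1311 counts for u16),
   opened (disc radius 2 px) and dilated (radius 1 px); the mask is
   broadcast over z and multiplied into every channel. This removes
   isolated hot pixels and faint debris before any statistics are taken.
3. **Smoothing** with a separable Gaussian of sigma `(0.5, 2, 2)` voxels in
   `(z, y, x)` — roughly isotropic in physical units at the default voxel
   size.
4. **Triangle threshold** on the smoothed channel-max volume: build a
   256-bin histogram, scale counts so the peak has height `nbins − 1`,
   draw the chord from the peak to the farthest non-empty bin, and return
   the bin at maximum perpendicular distance (ties: the first bin walking
   from the peak toward the tail; the returned threshold is that bin's
   centre in intensity units). The geometry suits strongly skewed
   fluorescence histograms — a dominant background peak and a long bright
   tail. Thresholding is **per field** because fields differ in noise and
   intensity; a constant field yields an empty mask with a message, not an
   error.

Field masks are stitched to the full well extent *before* 3D
connected-component labeling (26-connectivity by default, the most
permissive choice, which matches the visual merging of touching organoids),
so an organoid straddling a field border receives one label. Components
smaller than `minVolumeVoxels` (default 100 voxels ≈ one nucleus at the
default voxel size) are dropped — a deliberate trade-off: the same cutoff
that suppresses debris also excludes single cells from being called
organoids. Labels are renumbered consecutively in scan order of each
object's first voxel, which makes label ids reproducible.

## Per-object measurements

`organoidFeatures()` / `nucleusFeatures()` share one measurement core.
Voxel counts convert to µm³ via `dz·dy·dx`. Definitions that are genuinely
choices:

* **Filled volume**: cavities are voxels unreachable from the crop border
  by 6-connected background flood fill.
* **Convex volume**: the union over z-slices of the 2D convex hull of each
  hole-filled slice (rasterised by half-plane tests). This slice-wise
  definition guarantees `volume ≤ filled ≤ convex ≤ bbox` on every object
  and is exact for convex solids aligned with z; a true 3D hull would
  differ on objects strongly tilted against the z axis. Solidity is
  filled/convex.
* **Euler number**: the Euler characteristic of the cubical complex of the
  voxel set (`vertices − edges + faces − cubes`). A solid block scores 1;
  every enclosed cavity adds 1; tunnels subtract 1 — so it acts as the
  "holes present" readout.
* **Axis lengths**: from the eigenvalues of the covariance of physical
  voxel coordinates via the uniform-ellipsoid relation (semi-axis
  `= sqrt(5λ)`); eccentricity is minor/major axis length (1 for a sphere,
  defined as 1 for degenerate single-voxel objects).

# Stage 2: nuclei segmentation

Each organoid is cropped by its padded bounding box (default pad
`(1, 3, 3)` voxels); the crop offset is recorded so nucleus coordinates map
back to the well frame. Each fluorescence channel is normalized
independently per crop — `(x − P1.0) / (P99.8 − P1.0)` clipped to [0, 1] —
and segmented separately, so a clone's nuclei only appear in its own
channel's table. Per-crop (rather than per-well) normalization follows the
stage's design: organoids differ widely in brightness.

The backend is a *contract*: any function mapping a normalized crop to an
integer label volume can be registered (`registerNucleiBackend()`), which
is how an externally trained star-convex CNN would plug in; its reference
configuration for this imaging regime (anisotropy (9, 1, 1), 64 rays,
patch (16, 128, 128), receptive field (17, 30, 30)) is recorded in
`nucleiBackendConfig()`. Note that strongly non-star-convex nuclei are a
known failure mode of that model family. The default backend is fully
classical:

1. Gaussian smoothing with a physical sigma (default 1 µm).
2. Otsu threshold on the smoothed crop.
3. Euclidean distance transform of the foreground under the physical voxel
   spacing (exact separable algorithm).
4. Seeds at the 26-neighbourhood local maxima of the **distance-weighted
   smoothed intensity** (the product of steps 1 and 3), greedily pruned to
   a minimum physical separation (default 6 µm, larger peak first, ties by
   index).
5. Seeded watershed (priority flood, 6-connectivity, FIFO tie-break) on
   the negated map of step 4, restricted to the foreground; fragments
   below `minNucleusVolUm3` (default 50 µm³) are dropped.

The distance-weighted seed map is the one place the backend departs from
the plainest distance-transform watershed, and it is load-bearing: with
densely packed soft-edged nuclei above a weakly fluorescent organoid body,
the global Otsu threshold sits near the body level, thresholded masks
merge, and distance maxima alone under-segment badly (about one fifth of
nuclei lost in our synthetic benchmark, versus a fraction of a percent with
the weighted map). For uniform-intensity objects the distance term
dominates and the behaviour is the classical one; both regimes are covered
by tests. Nuclei touching the crop border are kept but flagged.

# Well-level quantities

* **Imaged area**: organoid distribution within a well is variable when a
  fixed z-range is imaged, so raw counts are not comparable across wells.
  On the max-projection of the label mask, 2D objects covering more than
  25% of the projection are discarded as non-organoid artefacts, the mask
  is dilated and closed (disc radii, default 10 px each) so gaps between
  adjacent organoids are bridged, and the pixel count converts to mm².
  The area is monotone in the radii by construction.
* **Dead-cell filter**: per organoid, the dead-dye channel crop is min–max
  normalized to [0, 1] and a nucleus is flagged dead when the mean
  normalized intensity over its *bounding box* exceeds 0.1 — strictly, so
  exactly 0.1 stays alive. The bounding-box (not mask) average is
  implemented as specified even though it dilutes the signal with
  non-nucleus voxels. Two guards: a constant crop flags nothing, and a
  crop whose dynamic range is below 5% of the dtype range is treated as
  carrying no dye signal at all — min–max normalizing pure noise would
  otherwise flag every nucleus. A percentile-based normalization is the
  config alternative for hot-pixel robustness.
* **Summaries**: live counts per channel, densities (counts / imaged
  area), the clone ratio (flagged undefined rather than NaN when the
  denominator clone has no live cells), per-organoid clone fractions, and
  control normalization (per-dose proportion over the mean untreated
  proportion, with replicate mean and SD).

# Dose–response and IC50

The 4/5-parameter logistic is fitted on x = log10(dose) by bounded
Levenberg–Marquardt least squares from a fixed grid of 12 starts (both
slope signs, two magnitudes, three x_mid quantiles); the best RSS wins.
x is centred on the median log-dose internally, which makes dose-scale
equivariance of the IC50 exact rather than optimizer-tolerance-deep. The
reported IC50 is the *relative* one (dose at the midpoint between fitted
asymptotes, the conventional default for this model family); the absolute
variant (curve = 0.5 of control) is also computed when the curve crosses
it, and an IC50 outside the dose range is flagged extrapolated. A response
range below `flatTol` (default 0.05) aborts with "no dose effect" rather
than fitting noise.

The 95% CI is a seeded bootstrap (default 1000 resamples). The default
scheme resamples *pooled fit residuals* onto the fitted curve, with the
residuals inflated by `sqrt(n / (n − p))` for the degrees of freedom
absorbed by the fit. Case resampling of replicate wells within dose is
available (`bootType = "case"`) but was measured on this package's own
coverage experiment (200 seeded simulations, 9 two-fold doses, 3
replicates, noise SD 0.05) to undercover — with only three wells per dose
the within-dose empirical distribution underestimates the sampling
variance — which is why it is not the default. Bootstrap refits warm-start
at the full-fit solution.

# Clone localization statistics

For clone X in one organoid with n cells: each X cell's window of K
nearest neighbours (Euclidean distance in physical µm — the anisotropy is
applied before any distance is taken) gives `Lc = X_n / (K · R_x)`, and
`Lo` is the mean of `Lc` over X cells; 1 corresponds to random mixing.
Two conventions needed fixing where the definitions are ambiguous, both
config-flagged: the focal cell is **excluded from its own window** (a cell
is not its own neighbour) but **included in R_x** (the organoid-wide clone
proportion). Under random labeling the exact expectation of Lo is then
`(n_X − 1) / ((n − 1) R_x)` by the hypergeometric window composition — the
test suite pins this by full enumeration at small n. Distance ties break
by stable index order; with floating-point centroids ties have measure
zero. Organoids with `n ≤ K` are skipped for that K rather than shrinking
the window. The radial variant counts neighbours within
`r_i = i · r_max / 6` (focal excluded; cells with no neighbour at that
radius are skipped with a warning), reported at i = 2 by convention.
Permutation nulls shuffle labels over the fixed geometry with
`p = (1 + #{Lo* ≥ Lo}) / (1 + n_perm)`.

# Morphology classifiers

One binary ridge-logistic classifier per contrast on the nucleus feature
set (four volume variants, three intensity statistics, eccentricity,
solidity, Euler number, inertia-tensor eigenvalues). The split is
stratified 80/20 and seeded; standardization statistics come from the
training split only (leakage guard); constant columns are dropped with a
warning; the penalty is weak (λ = 1e-3) and fixed — the goal is a stable
readout of separability, not a tuned predictor. AUC is the Mann–Whitney
rank statistic with mid-ranks for ties, so it is invariant to monotone
transforms of the decision score and maps to 1 − AUC under label swap.

# The synthetic plate generator

`simulateWell()` emulates the screening regime end to end: non-overlapping
spherical organoids (radius ~N(45, 8) µm truncated to [30, 60], ≥15 µm
clearance) packed into the imaged slab of a 2×2-field, 40-plane,
(5, 1, 1)-µm well; ~Poisson(75) nuclei per organoid (radius ~N(5, 0.4) µm,
minimum centre separation 9 µm); a weak cytoplasmic organoid body
(1500 counts) under bright nuclear blobs (~12000 counts) on a 120-count
background with read noise SD 30; a dead-dye channel (10000 counts) for a
5% dead fraction; optional bright point debris. Clone labels mix a seeded
fraction with a spatial-affinity parameter α: 0 assigns labels uniformly
at random, 1 grows one clone as a contiguous cluster by nearest-neighbour
contagion from a seed cell, intermediate values interpolate.

Nuclei are rendered as spheres of their truth radius convolved with an
isotropic PSF (erf edge profile, σ = max(1, 0.25 r) µm). This puts the
half-maximum contour exactly at the truth radius — so the rendered extent
and the recorded ground truth agree by construction — while the soft skirt
still gives the watershed an intensity valley between neighbours. A pure
Gaussian blob parameterisation was rejected because its measurable extent
(half-max at 0.74 r for the width that keeps valleys) is inconsistent with
its own truth radius, making voxel-overlap evaluation against truth
meaningless for any backend.

Dose ladders thin each clone's nuclei binomially by its survival curve and
apply per-dose nucleus volume/intensity multipliers, so
increase-then-decrease volume patterns and proportion reversals between a
resistant and a dormancy-prone clone are programmable. Everything is
deterministic given the seed; per-well seeds in ladders and plates are
derived arithmetically, so outputs are independent of execution order and
worker count.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: optical PSF anisotropy and depth
attenuation, uneven illumination across fields, touching/fusing organoids,
non-spherical organoid and nucleus shapes, chromatic crosstalk, and
autofluorescence texture. The synthetic benchmark validates the machinery
(geometry handling, statistics, determinism), not instrument-specific
accuracy; on real plates the cleaning threshold, smoothing sigmas, minimum
object size and backend parameters are the knobs to revisit.

# Problem sizes used by the test suite

Chosen to exercise the standard conditions while keeping a single-CPU run
comfortable: the end-to-end checks use one ~20-organoid/~1500-nucleus well
per seeding fraction; the localization checks use a fixed 200-point
geometry with 2000 relabelings and 100 simulated 75-cell organoids; the
bootstrap coverage experiment uses 200 simulated experiments with 300
resamples each; the classifier checks use 5000 nuclei per class; smaller
4-organoid wells back the unit tests.

# Known limitations

* The slice-wise convex hull underestimates the true 3D hull for objects
  tilted against z (solidity is correspondingly conservative there).
* The default backend assumes nuclei are blob-like with a single intensity
  or distance peak; lobulated or non-star-convex nuclei will fragment or
  merge (the CNN backend contract exists for exactly that case).
* Bounding-box dead-dye averaging dilutes signal for large watershed
  regions; with tight boxes the 0.1 threshold separates cleanly, but
  heavily padded regions can under-flag (the mask-based average would be
  the stricter alternative).
* The imaged-area estimate depends on the closing radii: it is a
  normalization device, monotone and reproducible, not a claim about true
  colony area.
* IC50 confidence intervals assume exchangeable homoscedastic residuals;
  strong heteroscedasticity across doses would call for the case bootstrap
  with more replicates, or weighting.
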