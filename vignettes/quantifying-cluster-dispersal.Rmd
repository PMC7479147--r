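---
title: "Quantifying cortical polarity and cluster dispersal in 4D microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical polarity and cluster dispersal in 4D microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcquant)
```

## The measurement problem

Embryonic germ cells (in *Drosophila*, ~30–40 primordial germ cells, PGCs)
begin development as a tight rosette-shaped cluster enveloped by the
endoderm, then disperse: each cell polarizes its contractile cortex toward
the cluster centre ("posterior" in the rosette frame), rounds up, detaches,
and transmigrates through the surrounding tissue. Receptor mutants (e.g. of
the GPCR Tre1) fail to maintain a stable inward polarity — their cortical
reporter caps wander — and the cells neither separate nor migrate
directionally. Quantifying this behaviour from two-photon time-lapse
Z-stacks requires a chain of small measurements: where is the cluster
centre, how is reporter intensity distributed radially around it, where on
each cell's cortex is the reporter concentrated, how does that orientation
evolve, and how do the cells move.

`pgcquant` implements that chain as composable functions plus a synthetic
4D movie generator with exact ground truth, so every stage can be validated
without access to embryo data.

## Quantification procedures

**Cluster centroid and radial profile.** The cluster centroid is the
unweighted mean of all segmented voxel coordinates, in µm (anisotropic
voxel spacing is honoured everywhere). For the radial profile each
segmented voxel's intensity is divided by the mean intensity of a
user-supplied background region *in the same Z plane* — this cancels
depth-dependent signal loss — and its distance to the centroid is assigned
to one of 50 equally spaced bins spanning `[0, max distance]`. Bins are
half-open `[lo, hi)` with the last bin closed, so each voxel is counted
exactly once; empty bins report `NA` rather than 0 to avoid fake dips. The
per-bin SEM is computed over voxel intensities, and `radial_contrast()`
summarizes centre enrichment as the inner-quartile/mid-half ratio of bin
means. The time-resolved variant computes per-frame profiles on a shared
binning and bilinearly interpolates the (time × distance) surface onto a
requested grid, preserving the source nodes.

**Polarity detection and orientation.** A polarized cortical region is
detected on a 2D view of the reporter channel: the cell periphery is
isolated by erosion-subtraction (default two passes of a 3×3 box), pixels
brighter than the whole-cell mean + 1.5 SD are kept, and 4-connected
components larger than 10 pixels qualify; among several, the one with the
greatest total intensity wins (ties: lowest centroid row, then column). The
polarized-to-cytoplasm intensity ratio uses the eroded core as cytoplasm,
with ≥ 1.2-fold as the polarity criterion. Orientation is the angle at the
cell centroid between the vector to the region centroid and the vector to a
reference point (cluster/endoderm centre), in [0°, 180°]. A reorientation
event is an absolute frame-to-frame shift > 60°; undetected frames form
gaps, and by default the first angle after a gap is compared with the last
angle before it (configurable), because real polarity records contain such
gaps within otherwise scorable series.

Three 2D views are supported: a maximum-intensity projection (suited to
thin stacks), a fixed Z slice, and `best_slice`, which selects per cell and
frame the plane with the greatest reporter signal inside the mask. For
fully 3D simulated rosettes `best_slice` is the informative choice — in a
projection of a complete sphere the interior projects through the cortex
and caps pointing along Z leave no in-plane signature, so the default
pipeline configuration uses `best_slice`.

**Posterior intensity.** Each cell is rotated in-plane so its posterior
direction points down (bilinear interpolation for intensities, nearest
neighbour for masks), the rows containing mask pixels are counted, and the
lowest 20 % of them (`ceiling`) define the posterior compartment whose mean
intensity is reported. Cells spanning fewer than 5 rows fall back to the
single lowest row, with a warning. The posterior direction can come from
the detected polarity axis or from the direction to the cluster centre;
both are supported, and the polarity axis is the natural default because it
is defined for detached cells too.

**Shape and localization.** Circularity is 4πA/P² with A the pixel count.
P is the marching-squares contour length at the 0.5 iso-level of the
*Gaussian-smoothed* mask (σ = 1 px): on raw binary masks the staircase
contour overestimates P of smooth shapes by ~8–10 %, deflating disk
circularity to ~0.84, while after smoothing rasterized disks of radius
≥ 10 px measure 0.99–1.00. σ is exposed (σ = 0 recovers the raw contour)
because no perimeter convention is universal. The membrane-to-cytoplasm
ratio divides the mean over the erosion-subtracted rim by the mean over the
eroded core. Time courses can be normalized to their first value (baseline
mode, e.g. contraction series) or to their maximum.

**Tracks.** Tracks are built from labeled movies by greedy global
nearest-neighbour linking under a maximum-displacement gate (default
10 µm/frame ≈ 2 cell radii; ties broken by smallest label, no gap closing —
a missing frame splits the track, mirroring workflows where gaps were
corrected manually). Speed is total path length over elapsed time
(µm/min); straightness is net displacement over path length, in [0, 1].
These are the standard tracking-software definitions; they are stated here
prominently because figure-level "speed" and "straightness" are often left
undefined. Distance-from-reference series can be normalized per track to
the initial distance ("relative" mode). A cell counts as transmigrated from
the first frame it lies outside a boundary (sphere or explicit region), and
an optogenetic-style trajectory scores as a reversal if it exits the
activation ROI within a time window after the pulse.

**Statistics.** Group comparisons use the two-sided Mann–Whitney rank-sum
test (exact p by enumeration when `n1·n2 ≤ 400` and there are no ties,
otherwise the normal approximation with tie and continuity corrections —
the switchover is configurable) and the two-sided Fisher exact test with
the probability-mass criterion for proportions. Summaries report mean, SD
(n−1), and SEM.

## The synthetic generator

`generate_cluster_movie()` renders a rosette of spherical cells as a
T×C×Z×Y×X movie (channels `membrane` and `reporter`) plus exact ground
truth (label masks, positions, cap axes, cluster centroid).

* **Geometry.** Cells are placed on Fibonacci-lattice shells separated by
  one cell diameter, outermost first, with a seed-controlled tangential
  jitter that preserves the non-overlap guarantee; an unplaceable request
  raises a packing error naming the offending parameters. Defaults — 30
  cells of radius 4.5 µm in an 18 µm cluster, 1 µm cortex — approximate a
  germ-cell rosette.
* **Cap.** Cortex voxels within `cap_half_angle_deg` (default 60°) of the
  cap axis carry `cap_enrichment` (default 2) times the cortex baseline.
  In `radial_inward` mode the axis points at the cluster centroid; in
  `random` mode it starts uniform on the sphere and evolves by small-step
  spherical diffusion (~8°/frame) punctuated by Poisson-timed uniform
  resampling at `reorientation_rate_per_min` — producing both slow drift
  and the > 60° jumps characteristic of depolarized mutants.
* **Imaging model.** Intensities: cortex 100, interior 30, background 10
  (arbitrary units); every value is multiplied by `exp(-z/λ)` when a depth
  attenuation length is set, applying to background and signal alike so
  per-depth background normalization cancels it exactly. Optional noise is
  Poisson on the expected value plus additive Gaussian read noise
  (σ default 2); with the default cortex level this corresponds to an SNR
  of ~10. Voxel spacing defaults to 0.5 × 0.2 × 0.2 µm (z, y, x) and the
  frame interval to 30 s — conventional two-photon values adopted as
  package conventions.
* **Tracks.** `generate_tracks()` produces stationary, persistent
  (direction = normalized `p·d + (1−p)·u` with uniform random `u`), or
  target-biased walks with exactly constant per-frame step length, so
  speed is known by construction.

Everything is a pure function of its parameter record, including the seed:
identical parameters give bit-identical output.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: no optical PSF (beyond the option of
Gaussian blur), no photobleaching, no cell deformation or adhesion
mechanics (cells stay spherical; "flattened cell" fixtures for shape
comparisons are built as ellipses instead), no tissue autofluorescence
structure, and no segmentation errors (ground-truth masks are exact).
Validation on this generator demonstrates that the *measurements* are
correct and statistically calibrated, not that segmentation of real
embryos would be.

## Numerical choices and degenerate inputs

* Coordinates are 0-based voxel centres; physical distances always use the
  µm spacing. Axis order is fixed as T×C×Z×Y×X.
* The automatic ROI-refinement threshold is Otsu's criterion evaluated on
  256 candidate cuts spanning the ROI's own intensity range, with class
  statistics computed from the raw values (not bin midpoints), so the
  optimum is exact with respect to the candidate grid; a ROI with fewer
  than two distinct values raises a degenerate-histogram error. The
  largest connected above-threshold component is kept (4-connected in 2D,
  6-connected in 3D).
* Erosion uses a 3×3 box applied per slice by default; a 3×3×3 box is
  available for volumetric masks. Erosion that annihilates a mask raises a
  too-thin-object error rather than returning an empty cytoplasm.
* Empty samples, empty ROIs, zero cytoplasm or background means, zero
  margins in 2×2 tables, zero-length orientation vectors, single-frame
  track metrics, and zero-area shape requests all raise informative errors;
  "no polarity detected" is a valid `NULL`/`NA` outcome, not an error.
* Movie serialization is plain multi-page 32-bit float TIFF plus a JSON
  sidecar (axes, shape, spacing, channels, frame interval, intensity
  scale); round trips are exact to float32 precision. Label stacks use
  16-bit pages and restore exactly.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on deliberately small
instances chosen to exercise every code path with comfortable statistical
margins: clusters of 8–20 cells at 0.25–1 µm spacing, 1–20 frames, 20
clusters per condition for profile comparisons, 50 noisy replicates for
ratio recovery, 500 tracks for walk-ensemble checks. These sizes are a
package choice balancing statistical resolution against quick, repeatable
runs; all scale linearly if larger studies are needed.

## Known limitations

* The polarity detector works on 2D views; a cap pointing along the
  optical axis of a thick cell has no in-plane signature and is reported
  as undetected. This mirrors the underlying 2D workflow but means
  detection rates on fully 3D objects depend on cap geometry.
* The linker is greedy nearest-neighbour without gap closing or identity
  optimization; it is intended for well-separated cells under a
  displacement gate, not for dense crossing trajectories.
* Circularity depends on the perimeter estimator; values are comparable
  within one estimator setting but not across settings, which is why the
  estimator is part of the reported configuration.
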