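# pgcquant

Quantification of cortical polarity and cell-cluster dispersal in
multi-channel 4D fluorescence microscopy.

## What this is for

Embryonic germ cells (in *Drosophila*, ~30–40 primordial germ cells, PGCs)
start out as a tight rosette-shaped cluster inside the endoderm, polarize
their contractile cortex toward the cluster centre, and then disperse and
transmigrate individually. Receptor mutants lose the stable inward
polarity — their cortical reporter caps wander and the cells fail to
separate. Analysing this behaviour from time-lapse Z-stacks requires a
chain of image measurements that `pgcquant` implements for anyone studying
cell-cluster dispersal, cortical polarity, or 3D cell motility:

* **Radial intensity profiling** — intensity of any reporter as a function
  of distance `d` from the cluster centroid `c = mean(x_i)` over all
  segmented voxels, each voxel normalized to the mean background intensity
  at its own imaging depth, discretized into 50 equal bins; plus a
  time-resolved, bilinearly interpolated (distance × time) surface.
* **Cortical polarity** — automatic detection of polarized cortical
  regions on the cell periphery (pixels > mean + 1.5 SD, 4-connected
  regions > 10 px), the polarized/cytoplasm intensity ratio with the
  ≥ 1.2-fold criterion, the orientation angle
  `θ = arccos(v̂₁·v̂₂) ∈ [0°, 180°]` between the cell→region and
  cell→reference vectors, reorientation events (|Δθ| > 60°, scored across
  detection gaps), and posterior-intensity time courses (lowest 20 % of
  rows after rotating the posterior to face down).
* **Morphology** — posterior area/intensity, circularity `4πA/P²`,
  membrane-to-cytoplasm ratios from erosion-subtraction partitions, and
  first/max time-course normalization.
* **Tracking** — nearest-neighbour linking of labeled movies under a
  displacement gate; speed = path/time, straightness = net/path ∈ [0, 1],
  distance-from-reference series (absolute or relative), transmigration
  counts, and optogenetic reversal classification.
* **Statistics** — two-sided Mann–Whitney rank-sum and Fisher exact tests
  with exact small-sample behaviour, and mean/SD/SEM summaries.
* **A synthetic 4D movie generator** with exact ground truth (rosette
  geometry on Fibonacci shells, angular reporter caps that point inward or
  reorient randomly, depth-dependent attenuation, Poisson + Gaussian
  noise, persistent/directed/stationary 3D walks), used to validate every
  stage without any external data.

See the vignette `vignettes/quantifying-cluster-dispersal.Rmd` for the
full description of the procedures, parameters, and design choices.

## Worked example

Simulate a wild-type-like rosette (12 cells, inward-pointing reporter
caps, realistic noise) and quantify it:

```r
library(pgcquant)

params <- cluster_sim_params(
  n_cells = 12, cell_radius_um = 4, cluster_radius_um = 13,
  cortex_thickness_um = 1.2, voxel_spacing_um = c(0.6, 0.25, 0.25),
  cap_enrichment = 2, n_frames = 2, noise = "poisson_gaussian", seed = 42)
sim <- generate_cluster_movie(params)
sim$movie
#> movie: T=2 C=2 Z=65 Y=153 X=153
#>   channels: membrane, reporter
#>   spacing (z,y,x): 0.6 x 0.25 x 0.25 µm; frame interval 30.0 s

reporter <- get_channel(sim$movie, "reporter", 1)
cluster  <- array(sim$truth$label_movie[1, , , ] > 0, dim(reporter))
prof <- radial_intensity_profile(reporter, cluster, !cluster,
                                 n_bins = 50, spacing = sim$movie$spacing)
head(as.data.frame(prof)[prof$n > 0, ], 4)
#>    bin_center_um     mean        sem   n
#> 19      4.865578 20.10807 0.35258977  21
#> 20      5.128582 19.96794 0.11132189 184
#> 21      5.391586 20.10235 0.06698363 462
#> 22      5.654590 19.97695 0.05008008 793
radial_contrast(prof)
#> [1] 2.25
```

The innermost occupied bins sit ~20× above background (cortex caps at
2 × cortex baseline, normalized per depth), and the centre-to-mid-radius
contrast of 2.25 reflects the inward polarization. The polarity time
course then recovers the simulated geometry:

```r
pol <- polarity_timecourse(sim$movie, sim$truth$label_movie,
                           sim$truth$cluster_centroid[1, c("y", "x")],
                           view = "best_slice")
sum(pol$detected); mean(pol$orientation_deg, na.rm = TRUE)
#> [1] 19          # of 24 cell-frames
#> [1] 12.1        # degrees from the cluster-centre axis
```

A detected polarized region in 19/24 cell-frames oriented on average 12°
from the inward axis — i.e. the caps point at the cluster centre, as
constructed. A `random`-orientation simulation instead yields orientations
near 90° and frequent > 60° reorientation events; `run_pipeline()` runs
both conditions end to end and writes the per-cell CSVs, summary JSON, and
a provenance record.

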