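---
title: "Methods: simulated 2-D and 3-D root phenotyping and its trait estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated 2-D and 3-D root phenotyping and its trait estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`rsatraits` is a desk-scale model system for a methodological question in
root phenotyping: when the same pair of contrasting soybean-like root
architectures is measured once in a **2-D system** (a thin rhizobox imaged
as a binary photograph) and once in a **3-D system** (a pot imaged as an
X-ray-CT-like voxel volume), how do the two headline traits — total root
length and fractal dimension (FD) — behave across the two systems? No real
imaging data ship with the package; every input is produced by the
synthetic-root generator, which carries exact geometric ground truth so
that each raster-based estimate can be benchmarked against the geometry
that produced it.

```{r, eval = FALSE}
library(rsatraits)
sys <- generate_root_system(woodstock_archetype(), rhizobox_domain(), seed = 1)
sk  <- skeletonize_2d(rasterize_2d(sys, pitch_cm_per_px = 0.05, thickness_px = 3))
total_root_length(sk); fd_boxcount(sk)
```

# The growth model

A root system is a forest of polylines in cm, with the origin at the
sowing point and z pointing down. Growth is discrete: each axis extends in
steps of `step_cm` (default 0.25 cm). The direction of a step is the
previous direction blended with the downward unit vector by the weight
`gravitropism` (0 = ignore gravity, 1 = aim straight down), then deflected
by a Gaussian angular wobble of SD `step_deflection_sd_deg` about a
uniformly random azimuth. The wobble parameter is part of the archetype
because the step model needs a dispersion scale; without it every taproot
would be a straight plumb line.

Laterals arise as a Poisson process along their parent: the count is
Poisson with mean `lateral_density_per_cm` times the parent arc length,
attachment positions are uniform along the arc (memoryless, matching the
per-cm parameterization), insertion angles are Gaussian
(`branch_angle_mean_deg` ± `branch_angle_sd_deg`) about the parent's local
tangent with uniform azimuth, and lateral lengths are log-normal with
natural-scale mean and SD `lateral_length_mean_cm` /
`lateral_length_sd_cm`. A secondary bears tertiaries with probability
`tertiary_prob` under the same density rule; tertiary lengths are scaled
by `tertiary_length_scale` (default 0.3) because no separate tertiary
length rule is biologically identifiable at this stage — it is a single
fixed design constant, stated here so nobody mistakes it for a fitted
value.

**Confinement.** Two domains are supported: the rhizobox
(40.6 H × 25.4 L × 1.5 W cm, quasi-planar growth) and the cylindrical pot
(15 cm top diameter, 13 cm height). A growth step that would leave the
domain is clipped at the boundary and the *next* step is re-aimed inward
(the tangential component of the old direction plus the inward normal).
We deliberately do not reflect: reflection concentrates artificial root
density along walls. A step that makes no progress four times in a row
(wedged in a corner) forfeits one step of budget, guaranteeing
termination; consequently the realized arc length of a heavily confined
axis can be slightly below its drawn length budget, which is why
`ground_truth_length()` always reports the realized geometry, not the
budget.

**Archetypes.** Two fixed parameter sets span the classic cultivar
contrast at the V1 stage: `casino_archetype()` is taproot-dominant (28 cm
taproot, 0.25 laterals/cm with ~1.2 cm laterals, tertiaries almost absent)
and `woodstock_archetype()` is highly branched (35 cm taproot, 1.8
laterals/cm with ~4 cm laterals, 60% of secondaries bearing tertiaries).
These constants are design choices, chosen once to reproduce the
*qualitative* ordering (the branched type exceeds the taproot-dominant
type in both traits, in both systems) — they are not calibrated to any
measured cultivar, and the package makes no claim that its absolute trait
values match real plants.

**Reproducibility.** Generation runs inside a private RNG scope
(`withr::with_seed`), with child draws consumed in segment order, so equal
`(params, domain, seed)` give bitwise-equal systems and a pipeline rerun
writes byte-identical CSVs.

# Rasterization and the CT surrogate

The 2-D photograph stand-in projects the thin rhizobox axis away and
marks every pixel a polyline edge touches (supercover traversal, with
both cells kept at corner crossings), then dilates to `thickness_px`
(default 3 px ≈ 1.5 mm at the default 0.05 cm/px — a plausible young-root
diameter). Supercover rather than center-sampling guarantees that a thin
root never breaks into disconnected pixels. The 3-D analogue voxelizes
onto a `voxel_grid`; the default pot grid is 128³ (the full
512 × 512 × 500 scanner geometry at 0.21 × 0.21 × 0.2 mm per voxel is
supported — `voxel_grid()` reproduces its printed 1.156 dm³ — but a 128³
grid keeps simulation within desk scale while preserving every contract
being tested).

The CT surrogate is deliberately minimal: root voxels at
`root_intensity`, medium at `medium_intensity`, plus i.i.d. Gaussian noise
— no beam hardening, no partial-volume blur, no soil texture. It exists to
exercise segmentation, not to model scanner physics.

# Segmentation and a hard limitation of global Otsu

`segment_volume()` applies a global threshold — Otsu's 256-bin bimodal
split over the whole volume by default, or a fixed value — keeps the
configured polarity side, labels 26-connected components, and filters
either to the component containing the sowing voxel or to components of
at least `min_component_voxels`.

Otsu's criterion maximizes between-class variance, which silently assumes
the two classes have comparable mass. When the root occupies well under
about 1% of the volume, the maximum moves *inside* the medium's noise
mode: the "segmentation" then admits a large fraction of noise voxels,
which percolate under 26-connectivity into one giant component that
swallows the root. This is a property of the method, not a bug, and the
package does not try to hide it. The defaults are instead chosen so the
surrogate operates in Otsu's valid regime: the default pipeline draws
roots at a 2-voxel radius (≈ 2.3 mm diameter on the 128³ pot grid,
realistic for a young taproot) with noise SD 0.01 against a 0.3 intensity
contrast. For sparser or noisier volumes, use `method = "fixed"` (when
class intensities are known, as in any simulation) or a finer component
filter. No morphological cleanup is applied by default; none is part of
the contract.

# Skeletonization

Both thinning routines delete *simple points* sequentially — cells whose
removal provably leaves local foreground and background topology
unchanged (8/4-connectivity in 2-D; 26/6 in 3-D, with the background test
inside the 18-neighborhood) — in directional subiterations
(N/S/E/W, plus up/down in 3-D) until stable, never deleting curve
endpoints or isolated cells, and re-checking simplicity at deletion time.
This yields the guarantees the trait estimators rely on: the skeleton is
a subset of the mask, has the same number of connected components, is
unit-thick, and re-skeletonizing it changes nothing. The specific
published thinning variant is not normative; these contracts are, and the
test suite checks each of them directly (including component preservation
across 200 random phantoms).

Terminal branches shorter than `prune_px` can optionally be pruned
(default off). Pruning removes digitization spurs and therefore slightly
lowers FD and length; because the effect is a judgment call, it is
exposed rather than imposed.

# Total root length

The estimator builds the adjacency graph of skeleton cells
(8-neighborhood in 2-D, 26 in 3-D) with edge weights equal to Euclidean
distance between cell centers under the anisotropic pitch, and sums a
minimum-spanning forest. The forest prevents double-counting the
diagonal+orthogonal cliques of a digital curve; since all minimum
spanning forests share the same sorted weight sequence, the total is
independent of tie-breaking (igraph's deterministic order is used).

Two known biases are worth stating. Digital 8/26-paths overestimate
oblique straight lines by up to ~8% (worst at 22.5°); root systems under
gravitropism are predominantly steep, and the measured recovery error on
seeded single-root polylines at 0.05 cm/px is under 3% (the tests enforce
5%). Conversely, *projection and raster overlap make the estimator a
lower bound for dense systems*: in 2-D, branches of a heavily branched
system occlude each other in the thin-axis projection, and on coarse 3-D
grids nearby branches merge into shared voxels. That undercount is not a
defect of the estimator — it is precisely the kind of
system-dependent measurement effect the 2-D/3-D comparison is about — but
it means skeleton length for the branched archetype is far below
geometric truth while the taproot-dominant archetype is recovered almost
exactly.

# Fractal dimension

`fd_boxcount()` / `fd_cubecount()` overlay nested dyadic grids anchored
at the array origin, with edge lengths 1, 2, 4, …, ⌊min(dim)/4⌋ (so the
coarsest scale still holds ≥ 4 boxes along the smallest axis; at least 4
scales are required, hence rasters of at least 32 cells per axis). The FD
is the unweighted OLS slope of log count against log(1/size);
`r_squared` is reported as a diagnostic instead of any automatic
linear-range selection, and the grid anchor is fixed (no offset
optimization) for determinism.

This construction makes the dimension bounds provable rather than
empirical: under a nested dyadic refinement each box splits into at most
2^d boxes, so between any two scales the count ratio is bounded by the
volume ratio, every pairwise slope lies in [0, d], and the OLS slope — a
convex combination of pairwise slopes — does too. The Euclidean limits
follow exactly: a full row of a 512² image gives slope 1, the filled
square 2, a single pixel 0, and a filled 128³ cube 3, to floating-point
precision. For stochastic skeletons the estimates land strictly inside
the bounds (typically 0.8–1.5 here).

# Summaries

`summarize_traits()` reports n, mean and the sample SD (n − 1
denominator) per archetype × system, ordered by group label. Published
"± " values for small biological replicates often leave SD vs SE
ambiguous; this package always means the sample SD, and reports `NA`
(never a fabricated 0) for singleton groups. `contrast_ratio()` is the
fold-change arithmetic used in such comparisons (530.4 cm vs 21.2 cm
rounds to a 25-fold contrast).

# Problem sizes and what the tests do and do not show

The shipped tests and the acceptance script run entirely on synthetic
inputs at desk scale — 2-D images up to 813 × 508 px (0.05 cm/px), 3-D
grids of 64³–128³, batches of 20–60 systems — sizes chosen so the whole
suite completes in a few minutes while every contract (supercover
coverage, topology preservation, dimension bounds, ground-truth recovery,
byte-identical reruns) is exercised at full strength. Passing them shows
the estimators are correct on rasters whose generating geometry is known.
It does not show that the growth model matches real soybean roots, that
the CT surrogate matches scanner physics, or that Otsu-style thresholding
would segment real soil volumes — real sand/root scans have texture,
partial-volume effects and class imbalance far beyond the surrogate. The
archetype ordering result (branched > taproot-dominant in mean length and
mean FD, in both systems) is therefore a statement about the pipeline's
ability to preserve a designed contrast through two very different
imaging paths, not a biological finding.
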