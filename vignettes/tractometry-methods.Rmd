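---
title: "Tract profiles from streamline bundles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract profiles from streamline bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractoprof)
```

This vignette is the package's own account of the methods it implements:
what is computed, under which assumptions, which parameters matter, and
where the design was genuinely open and a choice had to be made.

## The tractometry model

A *tract* is a bundle of streamlines — ordered 3D polylines in world RAS
millimeters — selected from a whole-brain tractogram because they cross
(all of) a set of defining ROIs. Its quantitative summary is built in
four steps.

**Orientation alignment.** Streamlines are unoriented curves: "node 37"
only means the same anatomical position across the bundle once every
streamline runs the same way. We pick as reference the streamline whose
resampled-node centroid minimizes the total distance to the other
centroids (deterministic, independent of input order up to exact ties,
which break by input order), and reverse each other streamline iff
reversal reduces the sum of squared node distances to the reference. The
centroid criterion is invariant under per-streamline reversal, which
gives a useful exact property: reversing every streamline reverses the
profile order exactly.

**Resampling and the core fiber.** Each streamline is resampled to
N = 100 points at equal arc-length spacing (linear interpolation,
endpoints included). Core node *j* is the pointwise mean of all
streamlines' node *j*; the node dispersion is the standard deviation of
the streamlines' Euclidean distances to that core node. N = 100 is fixed
by convention — it is the row count of every profile CSV and the node
count of the exported super fiber — and is exposed as a parameter only
for the internal machinery (cleaning uses the same alignment at the same
resolution).

**Gaussian-weighted transverse combination.** At node *j* the metric map
is sampled (trilinear interpolation) at every streamline's node-*j*
position, and the samples are combined with weights

\[ w_{ij} \propto \exp\!\left(-\frac{d_{ij}^2}{2\sigma_j^2}\right), \qquad
   \sum_i w_{ij} = 1, \]

where \(d_{ij}\) is the distance of streamline *i*'s node *j* to the core
node *j*. Streamlines near the bundle center therefore dominate, which
suppresses partial-volume contamination at the bundle edge. The profile
value is the weighted mean; the tract's scalar summary (e.g. mean tract
FA) is the arithmetic mean of the 100 values.

The weighting scheme needs a scale. Nothing in the field fixes \(\sigma\),
so the package defaults to a *per-node adaptive* \(\sigma_j\) equal to the
node dispersion, floored at 0.1 mm to keep weights finite for degenerate
single-streamline nodes. The rationale: the kernel should discount a
streamline relative to how spread the bundle is locally, not by an
absolute distance that would behave differently in tight and loose
bundles. A fixed-\(\sigma\) override (`sigma =`) is provided; Euclidean
rather than covariance-scaled (Mahalanobis) distance is used, a
documented simplification.

**Cleaning.** Anatomically implausible streamlines survive ROI selection.
Cleaning iteratively removes streamlines whose

1. length is more than `maxLenSD` standard deviations from the mean
   length (two-sided: both too-short and too-long are anomalous), or
2. mean node distance to the core fiber exceeds the mean of those
   distances by more than `maxDistSD` standard deviations (one-sided:
   being *close* to the core is never anomalous),

recomputing lengths, core and distances each iteration until nothing is
removed or `maxIter` is reached. Defaults are `maxLenSD = 4`,
`maxDistSD = 4`, `maxIter = 5`; 4 SDs removes only gross outliers, and
iterating matters because a strong outlier inflates the SD enough to
shelter milder ones in the first pass. Degenerate inputs are handled
explicitly: a zero SD disables that criterion for the iteration (a bundle
of identical streamlines is never eroded), and cleaning stops rather than
errors when fewer than 3 streamlines would remain. Once converged,
cleaning is idempotent, and it is tested to never remove the streamline
closest to the core.

**Clip-to-ROI (C2ROI).** The segment between the two defining ROIs — the
trunk — is the stable part of a tract; endpoints fan out toward cortex.
Optionally each streamline is truncated to the sub-polyline from its last
point inside the start ROI to its first subsequent point inside the end
ROI (streamlines never visiting both are dropped), and the core and
profiles are recomputed on the trunk. Profiles carry a `c2roi` flag so
trunk and full-tract profiles are never conflated.

## Coordinates, voxelization and selection

All volumes share one spatial frame: a `VolumeGrid` of integer shape plus
an invertible 4×4 voxel-to-world affine (RAS mm, 0-based indices, sform
preferred over qform when reading NIfTI). A world point lies in voxel *i*
iff rounding each continuous voxel coordinate gives *i* — the
voxel-center convention. Frames must agree to 1e-5 mm; mismatches are
errors, never silent resampling, because a frame mismatch at this stage
is almost always an upstream registration bug.

A streamline's voxel set is computed by sub-voxel sampling: the polyline
is densified so consecutive samples are at most 1% of the smallest voxel
dimension apart, and samples map to voxels by the rounding convention.
At that density only corner slivers whose intersection path is shorter
than the step can be missed — a geometrically negligible fraction of any
voxel — and the result matches a 0.01 mm brute-force oracle exactly on
the test suites. ROI-crossing selection, the binary mask (1 where any
streamline visits) and the fiber-count mask (number of distinct
streamlines per voxel; each streamline counts at most once per voxel) are
all defined on top of this primitive, so selection and mask export cannot
disagree.

ROI post-processing mirrors common practice: dilation uses the full
3×3×3 (26-connected) structuring element per iteration, and combining
ROIs defaults to set *union* — the operation that "grows" ROIs from
existing ones, e.g. merging two gray-matter patches into one selection
target — with an intersection mode provided for when a literal AND is
wanted.

## Tensor fitting

The single-tensor model \(S = S_0 e^{-b\,g^\top D g}\) is fitted per voxel
on log-signals with two-pass weighted least squares: an OLS pass, then
one weighted pass with weights equal to the squared predicted signals
(the standard first-order variance correction for log-transformed
Gaussian noise). This estimator is deterministic, has no iteration-count
ambiguity, and recovers noiseless signals exactly — which the tests
exploit (planted-tensor recovery to < 1e-9 relative error, rotation
invariance of the scalar metrics to < 1e-9).

Choices around the edges: at least 7 usable measurements spanning 6
non-collinear b>0 directions are required (rank checked, not assumed);
voxels with non-positive signals are flagged and excluded (NaN metrics)
rather than fitted on garbage; negative fitted eigenvalues are clamped to
zero *for metric computation only*, keeping FA in [0, 1] without hiding
fit diagnostics in the raw tensors; FA of the all-zero tensor is defined
as 0; multi-shell data enter one joint fit by default with a
`maxBValue` restriction flag.

## Agreement metrics

For two reconstructions of the same tract:

- **Dice** \(= 2|A\cap B|/(|A|+|B|)\) on the binary masks.
- **Density correlation**: Pearson correlation of per-voxel streamline
  counts over the *union of supports*. The whole grid would inflate the
  correlation with jointly empty voxels; the intersection would discard
  exactly the disagreement the statistic should capture.
- **Bundle adjacency**: over voxels in \(A\setminus B\), the mean
  world-space distance to the nearest voxel center of \(B\); symmetrically
  for \(B\setminus A\); the mean of the two directional means, in mm, and
  exactly 0 for identical masks.
- **Profile correlation**: Pearson correlation of two 100-node profiles.

Undefined statistics (zero variance, empty differences) surface as `NA`
plus an explicit flag — never a silently propagated NaN. These estimator
definitions are this package's stated choices; the metric *names* are
standard but their exact estimators vary across tools, so toy cases with
hand-computable values (and a brute-force oracle over random masks) pin
down the behavior in the tests.

## The synthetic phantom

Every stage is testable without acquired data through seeded generators:

- **Bundles**: a parametric centerline (line, circular arc, helix) plus
  per-streamline smooth correlated Gaussian offsets —
  Gaussian-kernel-smoothed white noise along arc, rescaled to an exact
  marginal SD — each streamline randomly reversed with probability 1/2 to
  exercise orientation alignment. Defaults: 200 streamlines, 1 mm jitter
  with 10 mm correlation length, 60 points per streamline, around a
  30 mm-radius, 60° arc.
- **Scalar fields**: a tube of radius 6 mm around the centerline carrying
  a known along-arc function (the standard case is a linear FA-like ramp
  0.2 → 0.8), background outside — so the true profile is known exactly.
- **ROIs**: spheres centered on the centerline at chosen arc positions.
- **DWI**: closed-form tensor-model signals with optional additive
  Gaussian noise.

The default grid is 40×40×40 at 1 mm, sized so each test runs in well
under a second. Generators set the RNG locally from an explicit seed and
restore the session state, so pipeline runs are bitwise reproducible.

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: crossing and kissing fiber configurations, partial
volume against gray matter and CSF, Rician (magnitude) noise,
susceptibility distortion, and tractography's own biases (the phantom's
streamlines are ground truth plus noise, not the output of a tracking
algorithm). Results on the phantom validate the *computations*;
biological validity of a profile still depends on the upstream
reconstruction.

## Determinism and problem sizes

The pipeline is single-threaded and deterministic end to end: identical
inputs and configuration reproduce every output byte for byte (the
manifest timestamp is the only exception, and the manifest records the
full resolved parameter set and input digests needed to re-run). The
repeat-run analysis in `scripts/acceptance.R` uses the default phantom —
200 streamlines, 40³ grid, 1 mm jitter — and two full pipeline
executions, which together take on the order of ten seconds; the test
suite uses smaller bundles (10–200 streamlines) and grids (8³–40³),
chosen as the smallest sizes at which each property is non-trivial.

## Known limitations

- Selection is the only tract-generation mode; seed/target tracking,
  ensemble tractography and streamline filtering (SIFT/LiFE-style) are
  upstream concerns out of scope here.
- `.tck` and NIfTI-1 are the only geometry formats (no TRK, no DICOM).
- Gaussian-kernel weights use Euclidean distance; anisotropic bundle
  cross-sections are not modeled.
- The cleaning distance criterion uses the mean over nodes; a streamline
  that deviates sharply over a short span can survive if its average
  distance stays moderate.
- Tensor fitting assumes the single-tensor model; it will happily fit
  crossing-fiber voxels and report the usual misleadingly low FA there.
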