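---
title: "Methods: whole-brain LSFM c-Fos quantification in fosmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain LSFM c-Fos quantification in fosmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `fosmap`, the
assumptions they make, the parameters that matter, and the design choices
taken where the problem left the design genuinely open. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute themselves.

## The problem

Light-sheet fluorescence microscopy (LSFM) of solvent-cleared mouse brains
images the whole organ at micrometre-scale resolution in two channels: an
autofluorescence channel that shows anatomy, and a marker-specific channel
in which immunolabelled c-Fos — an immediate-early gene product used as a
proxy for neuronal activation — appears as bright, point-like cells.
Brain-wide activity mapping needs four things: a common coordinate frame
(a population-average template), region annotations in that frame, a cell
detector robust to the elevated tissue autofluorescence that clearing
introduces, and count statistics per brain region. Clearing shrinks and
de-lipidates tissue, so a template built from LSFM volumes themselves
registers LSFM data better than a template from another modality — which
is why the pipeline builds its own average template rather than
registering directly to an external reference.

## Conventions

All volumes are 3-D arrays in `(z, y, x)` axis order (first index is z,
matching slice-stack acquisition), with 0-based voxel-centred coordinates
and isotropic spacing in micrometres (20 um is the working resolution
throughout). A transform maps *fixed*-image coordinates to *moving*-image
coordinates — the resampling (pull-back) convention,
`out(x) = moving(T(x))` — and a displacement field is the transform minus
the identity, in voxel units of the fixed grid. This single convention is
stated on every interface because silently transposed axes and
inverted-by-convention transforms are the dominant failure mode of atlas
pipelines. Region id 0 is reserved for background everywhere.

## Preprocessing

Order is fixed: down-sampling, bias correction, histogram
normalization/equalization.

* `downsample_isotropic()` block-averages for integer factors (exactly
  mean-preserving) and otherwise Gaussian-pre-smooths (sd = half the
  factor) before linear resampling at block centres. Up-sampling is
  refused rather than silently interpolated.
* `correct_bias()` removes smooth multiplicative shading. It estimates the
  log-domain bias as a mask-weighted (normalized-convolution) Gaussian
  smooth of the log intensities over the positive-foreground mask, divides
  it out, and rescales the foreground mean. The smoothing sd defaults to a
  quarter of the smallest volume edge — wide enough that anatomy is not
  treated as bias. This is a smooth-field estimator chosen for its
  testable contract (recovery of an injected multiplicative gradient with
  r >= 0.9, halving of the flat-region coefficient of variation); it is
  not a histogram-sharpening N3/N4 port.
* `equalize()` optionally matches the volume's histogram to a reference by
  monotone quantile mapping — during template building the reference is
  the current average, giving all subjects a common intensity target —
  then applies contrast-limited adaptive histogram equalization per
  z-slice (tile 8 voxels, clip 1% of tile histogram mass; both mild,
  both configurable, since no principled values exist). Output spans the
  16-bit range. A single-valued volume is returned unchanged: equalizing
  a degenerate histogram is ill-posed, and identity is the only
  continuous choice.

## Registration

`register()` implements multi-resolution intensity-based registration with
a mutual-information (MI) criterion, natively: MI is estimated from a
32-bin joint histogram with linear (tent) binning; the affine model (12
parameters) is optimised by BFGS on the negated MI with a coarse
exhaustive translation search at the coarsest pyramid level for
initialisation; the deformable model is a cubic B-spline free-form
deformation optimised coarse-to-fine, with control-point spacing halving
per level (16 to 4 fixed-image voxels at the defaults). The B-spline
update is the analytic MI ascent force — the derivative of the pointwise
log-ratio table with respect to the moving intensity, times the warped
moving gradient — splatted onto the control grid (the exact adjoint of
the B-spline densification), with per-control-point normalised steps
(maximum 0.4 voxels per iteration) and a halve-on-failure step schedule.

Numerical choices worth knowing:

* The metric at fine pyramid levels is evaluated on a deterministic
  strided subsample (capped near 150k voxels). This keeps cost bounded
  without random sampling, so registration is bit-reproducible.
* If the final MI is worse than the identity alignment, the identity
  transform is returned with a warning — an accepted registration never
  degrades the metric.
* Inversion of deformable transforms is the fixed-point iteration
  `v(x) = -u(x + v(x))`; the compose-with-inverse round trip stays below
  0.5 voxel at 99% of in-mask voxels on smooth fields, and
  non-convergence is reported with the residual step, never hidden.
* Flat image regions constrain MI weakly, so recovered fields are only
  accurate where the image has structure; the acceptance tolerance for
  warp recovery (mean in-mask residual <= 1.5 voxels) reflects that
  information limit rather than optimiser quality.

The 2-D per-slice variant used for channel alignment evaluates MI on
lightly smoothed slices (Gaussian sd 0.8 voxels) because linear-binned MI
has sub-voxel interpolation ripple; the raw slice is resampled with the
recovered transform. Near-empty slices (degenerate intensity range)
return the identity.

## Template construction and symmetrization

`build_template()` is the reference-then-average iteration: iteration 1
registers every subject to a chosen reference brain; iteration k >= 2
registers every *original* subject to the iteration-(k-1) average. The
default schedule is six iterations — affine first, then five B-spline.
Averaging is the voxelwise arithmetic mean of histogram-matched registered
volumes: the mean is the standard variational-atlas choice, and matching
prevents one bright acquisition from dominating it. The per-iteration mean
voxelwise variance of the registered stack is recorded as a convergence
diagnostic; it must fall across iterations on warped-phantom sets.

`symmetrize()` blends the template with its mirror image using a logistic
weight centred on the midplane: `out = w*T + (1-w)*mirror(T)` with
`w = 0.5` exactly at the midplane. The weights are constructed exactly
antisymmetric (`w(n-1-i) = 1 - w(i)` enforced in floating point), which
makes the output bit-exactly mirror-invariant — a property the tests
assert with `identical()`. The blend scale defaults to 1 voxel (a 10-90%
transition of about 4.4 voxels); which hemisphere dominates is a flag,
since anatomy gives no reason to prefer one. The manual coronal-slab
rotation some atlas builds apply is replaced by an optional rigid
pre-alignment to a user-supplied orientation reference; interactive
editing is out of scope.

## Annotation transfer

`transfer_annotations()` works in three steps: a whole-brain deformable
registration of the source template to the target; per parental block
(six blocks by default), registration of the pair masked to the block's
support dilated by 5 voxels — hard crops create boundary artifacts, so
block registrations keep context — composed with the whole-brain
transform; and nearest-neighbour warping of each block's labels followed
by recombination. Recombination (`resolve_overlaps()`) keeps voxels
claimed by exactly one block; voxels claimed by several blocks, or by none
while inside the tissue mask, take the label of the nearest single-claim
voxel (exact Euclidean distance, ties to the smaller region id — a
deterministic, oracle-checkable rule). Manual corrections near the
ventricular system are supported only as a user-supplied label-patch
overlay applied last.

`collapse_to_parents()` re-maps leaf regions to designated ancestors using
a level map and conserves totals exactly; the level map is data (it ships
with an atlas ontology), not something inferred from the tree, because no
single ontology depth defines "the" analysis level. The package's
`synthetic_atlas_ontology()` builds a stand-in hierarchy with the
documented shape of the LSFM atlas ontology — 666 leaves under six
parental blocks collapsing to 284 analysis regions — for tests and the
acceptance run; it is synthetic, and only its tree shape is meaningful.

## Cell detection

The detector is the adapted ClearMap-style chain, with the published
parameter values as defaults:

| parameter | default | meaning |
|---|---|---|
| filter cube | 3 x 5 x 5 (z, y, x) | maxima neighbourhood; z-extent smaller because axial resolution is lower |
| opening disk radius | 7 voxels | per-slice top-hat structuring element; must exceed the cell radius so cells survive |
| intensity cut-off | 800 | watershed background threshold on the *corrected* specific channel |
| size bounds | 8–194 voxels | inclusive survival range of watershed segments |

Two decisions the published description leaves open are fixed here and
recorded in the configuration so either variant is reproducible:

* The cut-off is applied after background subtraction and
  autofluorescence removal, because the watershed (where the cut-off
  belongs) runs after those corrections.
* "Removing signal appearing in both channels" is implemented as the
  voxelwise scaled, zero-clamped subtraction
  `max(spec - s*auto, 0)`, with `s` estimated robustly as the median
  specific/autofluorescence ratio over voxels where the autofluorescence
  exceeds its 99th percentile (artifact voxels dominate that tail), or
  fixed by configuration. The ablation test demonstrates the operator's
  effect: with removal disabled, implanted shared artifacts come back as
  false positives.

A cell's centre is its watershed *seed* (the local intensity peak), not
the segment centroid — heatmaps sum spheres around the peaks. Plateaus of
equal-valued maxima are broken deterministically to the
lexicographically-first `(z, y, x)` voxel, and the watershed priority
flood breaks intensity ties first-in-first-out, so the whole chain is
bit-reproducible and each primitive matches an exhaustive brute-force
reference on small random volumes. Raising the cut-off can only remove
cells; widening the size bounds can only add them (monotonicity is
property-tested). `assign_cells()` counts every cell: cells falling on
label 0 go to an explicit unassigned row, never silently dropped.

## Heatmaps

`render_heatmap()` adds 1 to every voxel whose centre lies within the
sphere radius (closed ball, physical units) of each cell centre; spheres
sum where they overlap and clip at borders. The closed-ball convention
makes the 20 um sphere on the 20 um grid a well-defined 7-voxel digital
ball, giving the exact mass identity (7 per interior lattice-centred
cell) the tests assert. Group difference maps are voxelwise differences
of group means — no smoothing, no voxelwise inference (statistics are
per-region by design).

## Registration-quality metrics

* Deformation magnitude: the voxelwise Euclidean norm of a displacement
  field, in voxel units.
* Intensity variance (IV): the unbiased (n-1) voxelwise variance across
  registered volumes, averaged over each region's voxels
  (mean-of-voxelwise-variance, the NIREP-style definition; the
  alternative — variance of region means — measures something else and is
  not used). Block summaries average the member regions' IVs. IV is
  invariant to adding a common constant and scales with the square of a
  common gain, both property-tested.
* Landmark distances: matched by name, reported in micrometres; two atlas
  conditions are compared per landmark with a two-tailed Welch's t-test
  (unequal variances, Welch–Satterthwaite degrees of freedom), which the
  tests pin to the closed form at 1e-9.

## Per-region count statistics

Counts are modelled per region with a negative-binomial GLM with log link
on group indicators, dispersion `theta` estimated per region by maximum
likelihood (`MASS::glm.nb`; variance `mu + mu^2/theta`). No information is
shared across regions — empirical-Bayes shrinkage would change the model
and is deliberately out of scope. All-zero and non-converged regions are
flagged and excluded from inference, never silently dropped.

Dunnett many-to-one contrasts compare each treatment with the control
using the joint multivariate-t distribution of the Wald statistics (the
model's estimated contrast correlation; residual degrees of freedom; the
`mvtnorm` quasi-Monte-Carlo integrator under a fixed seed). Because the
maximum-likelihood `theta` underestimates dispersion with few animals per
group — which makes raw Wald statistics anti-conservative — the Wald
covariance is inflated by the fit's Pearson dispersion statistic
(`X^2/df`, floored at 1), the usual quasi-likelihood moment correction;
in simulation at six animals per group this brings the type-I error from
about 7% to the nominal 5% at a modest cost in power, and it leaves the
effect estimates untouched. With a single
treatment this reduces to the unadjusted two-sided t-based p (verified to
1e-3, the integration tolerance). BH-FDR is then applied across regions
within each comparison — Dunnett within models first, FDR across the many
regions second; the reverse order would mix the two error scales.

Diagnostics per region: a Shapiro screen on the deviance residuals
(threshold 0.01 — a declared configuration value, since "severe violation"
is not quantifiable in the abstract), Cook's distance per observation
(flag above 4/n), and the low-count rule (any group mean below 10 is too
low to judge). A spillover-candidate column (a neighbouring region with at
least 10x the count density, computed from label adjacency when a label
volume is supplied) aids the manual visual check for signal bleeding
across region borders; it never changes significance on its own — the
visual confirmation itself is inherently manual and out of scope.

## The phantom generator, and what passing tests mean

`make_phantom()` builds a smooth ellipsoidal "brain" partitioned into
adjacent Voronoi subregions (each at least 100 voxels), with a smooth base
intensity, mild per-region offsets, low-frequency texture and Gaussian
noise (sd 10 on a base of 1200 — a conservative signal-to-noise choice for
averaged autofluorescence). `implant_cells()` adds isotropic Gaussian
cells (sd 1.5 voxels, peak 3000 over a 200 background), matching
point-like nuclear c-Fos signal at 20 um; `add_shared_artifacts()` adds
brighter, wider blobs (sd 2 voxels, peak 2500) identically to both
channels; `warp_phantom()` applies smooth random fields with a known
maximum amplitude; `simulate_counts()` draws from the same NB
parameterisation the GLM estimates. Every generator is a pure function of
its parameters and seed, and ground truth is returned alongside the data.

What the phantoms do *not* emulate: light-sheet stripe and shadow
artifacts, depth-dependent attenuation, vasculature and fibre tracts,
anisotropic point-spread functions, real anatomical variability, or
cross-modality intensity relationships. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
specified under controlled conditions — not that the default parameters
are optimal for any particular microscope or clearing protocol.

## Problem sizes used by tests and the acceptance run

The test suite runs most contracts on 40 x 56 x 56 phantoms; registration
recovery is verified at the full 96 x 128 x 128 working size, template
behaviour on four warped 40 x 56 x 56 phantoms over the full six-iteration
schedule, detection end-to-end on 64 x 96 x 96 with 50 cells and 10
artifacts, and the statistics calibration on 200 simulated replicates at
six animals per group. These sizes are the package's own choice of a
thorough-but-quick verification scale; all of them are parameters, not
limits.

## Known limitations

* The registration engine targets the same-modality, moderate-deformation
  regime of within-pipeline alignment; it is not a general cross-modality
  or large-deformation (diffeomorphic) solver, and flat regions are only
  as accurate as the surrounding image structure allows.
* Dorsal-cortex patching from auxiliary acquisitions, manual mask editing
  and interactive segmentation refinement are acquisition-specific manual
  steps and are not reproduced; masks and label patches are accepted as
  inputs instead.
* The NB-GLM treats animals as independent; cage, batch or litter effects
  need an explicit design column and are not modelled by default.
* On-disk TIFF intensities are clamped to the 16-bit range by convention;
  internal computation is double precision throughout.
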