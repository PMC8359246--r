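---
title: "Multiparametric knee MRI analysis with kneemap: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric knee MRI analysis with kneemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemap)
```

# Overview

`kneemap` implements a complete analysis chain for multiparametric
quantitative knee MRI: voxel-wise T1rho and T2 relaxometry, rigid and
nonrigid registration of all knees into a common atlas space, compartmental
and depth-dependent cartilage statistics with covariate adjustment,
voxel-based relaxometry (VBR) group maps, statistical shape modeling (SSM) of
subchondral bone, and morphological prevalence statistics for ordinal
cartilage grades. Because raw clinical MRI of this kind is rarely shareable,
the package ships a synthetic knee-cohort generator with complete ground
truth, so that every stage is testable end to end: planted effects must be
recovered, and null cohorts must stay null.

This vignette explains the models and the choices behind them, in the order
the pipeline runs.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
structure of a combined T1rho/T2 study of two athlete cohorts:

* **Acquisition timing.** Spin-lock times 0/10/40/80 ms and echo times
  0/12.8/25.7/51.4 ms, with the t = 0 image shared between the two decays:
  a series holds 7 distinct volumes for the 8 time points. Signals follow
  `S(t) = S0 * exp(-t / T)` with `T = T1rho` along the spin-lock axis and
  `T = T2` along the echo axis.
* **Geometry.** A stylized knee: ellipsoidal femur, tibia and patella with
  shell cartilage, labelled into the six standard compartments (LFC, MFC,
  TRO, PAT, LT, MT). The default grid is 96^3 voxels at 1 mm isotropic;
  the cartilage shell is 3 mm along its short axis (both configurable; a
  shell thinner than one voxel is rejected). This is deliberately not an
  anatomical template — it is the simplest geometry that exercises every
  algorithm (curved bone-cartilage interfaces, six disjoint compartments,
  three bones).
* **Composition.** Per-compartment baseline T1rho values span 36-46 ms and
  T2 values 25.5-32.5 ms, inside the ranges reported for healthy collegiate
  athletes. The superficial cartilage half is prolonged by +10% relative to
  the deep half (cartilage T2/T1rho rise toward the articular surface).
  Group effects are planted per compartment and layer; the defaults place
  +6/+7% (deep/superficial) in the MFC, +5% in the MT and +2.5% in the deep
  LFC — the medial-dominant pattern of a few percent reported for
  high-knee-impact athletes.
* **Cohort structure.** Two groups of 40 and 25 subjects; each subject
  contributes both knees with probability 0.6 (configurable), so knee counts
  exceed subject counts as in per-knee accounting. Modified Noyes grades
  (0/1/2) are drawn per compartment from per-group probability tables whose
  defaults match the observed per-compartment frequencies (about 25% of
  group-A knees and 6% of group-B knees abnormal).
* **Deformations.** Each knee receives a smooth subject-specific
  displacement: a small random affine plus a low-frequency field from a
  5^3 control grid, capped at `deform_amplitude_mm` (default 3 mm) so the
  mapping stays invertible. The displacement that returns the knee to the
  atlas grid is computed by fixed-point inversion and stored as ground
  truth; composing the two fields gives identity to well under 0.1 voxel.
* **Noise.** Additive Gaussian by default (`noise_model = "rician"` is
  available, since magnitude MRI noise is Rician and fitting-bias behaviour
  should be testable under both). The default SD is 20 signal units against
  S0 = 1000.

What the generator does **not** emulate: anatomical shape realism, B0/B1
field artifacts, fat suppression, partial-volume mixtures at 4 mm slice
thickness, or motion between echoes (unless planted). Tests passing on this
cohort therefore demonstrate algorithmic correctness — recovery of planted
truth under controlled conditions — not clinical performance.

## Bone populations with planted shape modes

`generate_bone_population()` builds voxelized bones as level sets of an
ellipsoid perturbed radially by Gaussian bumps on the unit sphere of
directions. Three *fixed* asymmetric features are shared by every subject:
real bones have no mirror symmetry, and without them a symmetric template
makes surface correspondence ill-posed (mirror-image solutions are exact
isometries). Planted variation modes are additional bumps whose per-subject
scores are normal with a stated SD in mm. Two normalizations make planted
variances exact rather than merely expected: each mode's angular weight is
scaled to 1 mm RMS surface displacement per unit score, and drawn scores are
standardized to their nominal SD (and truncated at 2.5 SD so the level-set
masks stay connected). `bone_pointsets()` maps any point set on the base
surface through the planted displacement fields, producing point sets in
exact material correspondence — the reference route for shape-model
recovery tests, independent of estimated correspondences.

# Relaxometry

Each voxel is fitted independently ("voxel by voxel") with the
two-parameter mono-exponential model by damped Gauss-Newton
(Levenberg-Marquardt) iterations, vectorized across all voxels of a map.
The fit is seeded by a log-linear regression of `ln S` on `t` over the
positive samples; negative or zero samples (possible under noise) are
excluded from the seed but retained in the nonlinear objective. `T` is
constrained to `(0, t_max]` with `t_max = 200` ms, a physiologic ceiling for
cartilage. Non-convergent voxels are flagged invalid, never raised as
errors. A profiled grid search (closed-form S0 for each candidate T on a
0.05 ms grid) serves as the independent oracle in tests; the two agree for
over 99% of noisy signals.

Where the tests speak of SNR, it is defined against the *mean signal over
the sampled decay* (SNR 50 means the noise SD is 1/50 of that mean). The
sampled timings support a median T error under 2% at that level — close to
the Cramer-Rao bound for this design, which is why the definition matters
and is stated explicitly.

The shared t = 0 image enters both the T1rho and the T2 fit; the two fits
are otherwise independent (the simplest defensible reading of a shared-first
acquisition).

`quality_filter()` intersects the valid mask with `r2 >= r2_min` and T
bounds; on low-SNR maps this demonstrably moves compartment means toward
ground truth.

# Registration

Within a knee, every echo/spin-lock volume is rigidly registered to the
t = 0 volume: a multi-resolution Nelder-Mead search over 3 rotation angles
(intrinsic ZYX about the volume centre) and 3 translations, maximizing
normalized mutual information computed from a Parzen-windowed joint
histogram. Both images are pre-smoothed by 0.75 voxel, which stabilizes the
similarity on the weakest echo (signal ~1/7 of baseline) without biasing
translation estimates; planted translations are recovered to well under
0.1 mm on noiseless data and spurious motion stays below 0.2 mm at low SNR.

Across knees, the t = 0 volume is nonrigidly registered to the atlas — by
default a designated generator subject with zero deformation ("atlas
mode"). The nonrigid solver is a self-contained multi-resolution dense
free-form registration of the demons family: intensity-normalized images
drive per-voxel displacement updates (residual times warped-image gradient,
step-capped at 0.6 voxel), with Gaussian *fluid* smoothing of each update
(sigma 2.5 voxels) and *elastic* smoothing of the accumulated field (sigma
1.5 voxels), run over levels 4x/2x/1x. The similarity is intensity
difference rather than mutual information: after robust rescaling the
within-study registration problem is mono-modal, the SSD force has an
analytic per-voxel form, and the resulting solver meets all recovery
invariants (landmark-error reduction >= 70% at 96^3, cartilage Dice from
below 0.6 to above 0.9, positive Jacobian determinants essentially
everywhere, inverse consistency below 0.5 voxel) within a desk-scale
runtime. The `config` argument is the plug-in seam: any substituted backend
must pass the same invariant tests, which are written against the contract,
not the implementation. Regularization strengths were chosen by the
synthetic recovery experiments, since no reference settings exist for this
geometry.

Transform application follows the study order exactly: the rigid and
nonrigid transforms estimated on t = 0 are applied to *all* echoes
(`transport_series()`), and maps are fitted in atlas space. Intensity
volumes are interpolated linearly and label volumes nearest-neighbour;
asking for linear interpolation of a label volume is an error, since
averaging label codes is a classic silent bug. Transport-then-fit and
fit-then-transport agree to well under 0.5 ms away from cartilage edges.

# Cartilage compartments and layers

Each compartment is split into a deep half (adjacent to subchondral bone)
and a superficial half (adjacent to the articular surface) by normalized
depth `d = D_bone / (D_bone + D_surface)`, where both distances are
Euclidean distance transforms in physical millimetres — anisotropy-aware,
because voxel-count depth is meaningless with thick slices. Deep is
`d <= 0.5` (ties to deep, documented); the two masks partition the
compartment exactly. A radial ray-casting oracle on a curved shell agrees
with the assignment for over 95% of voxels; disagreement concentrates where
the two definitions legitimately differ (oblique interfaces).

Compartment summaries are means/SDs over valid voxels only; empty
compartments are flagged, never silently dropped.

# Covariate-adjusted group statistics

Group comparisons use ordinary least squares of
`value ~ group + gender + BMI + site`, with site as unordered categorical
dummies (first level reference), and a 1-df F test on the group term — the
F statistic equals the squared group t statistic, and with no covariates
the test reduces exactly to the pooled two-sample t test. Rank-deficient
designs (e.g. site confounded with group) fail loudly with the aliased
terms named. Percent differences use the symmetric form
`100 * (mean_A - mean_B) / ((mean_A + mean_B) / 2)`; raw group means are
the primary definition, with covariate-adjusted means also reported, since
the underlying convention is ambiguous in the literature the package
follows.

The voxel-wise analysis fits the same model independently at every voxel,
vectorized by grouping voxels with a common pattern of valid knees (one QR
decomposition per pattern). Voxels with fewer than `min_n = 3` valid knees
per group, or with no residual degrees of freedom, are undefined and
counted. No multiple-comparison correction is applied by default — the
convention being reproduced thresholds uncorrected p at .05 — but a
Benjamini-Hochberg mode is available and clearly labelled. Null
calibration is enforced by test: with no planted effect, both the
compartmental and the voxel-wise tests reject at 5% +/- 2%.

Per-compartment roll-ups report the fraction of defined voxels significant
at alpha and the mean percentage difference over all defined voxels
(primary), with the significant-only average as a secondary column, because
the roll-up convention is also ambiguous.

The knee is the statistical unit throughout; bilateral within-subject
correlation is not modelled (no mixed model), a documented limitation —
subject-level aggregation can be performed upstream of the ANCOVA when
desired.

# Subchondral bone shape modeling

Surfaces are extracted from binary masks by marching tetrahedra (six
tetrahedra per cell around a consistent diagonal), which yields watertight,
consistently oriented triangle meshes in mm coordinates; the 0.5 iso-level
of a lightly smoothed mask gives sub-voxel boundary placement. Meshes are
decimated by grid vertex clustering to a tractable size (default budgets
around 1,000-2,000 vertices) before eigen-decomposition.

Correspondence between meshes is spectral: the first k nontrivial
eigenvectors of the cotangent-weighted (combinatorial fallback) normalized
graph Laplacian embed each mesh; sign and order ambiguities between the two
eigenbases are resolved by feature matching of eigenvector value profiles,
refined by a spectral ICP over orthogonal alignments of the embeddings.
Because eigenvalue multiplets of nearly symmetric shapes mix arbitrarily,
the embedding dimension is adjusted to the nearest spectral gap (a multiplet
is kept or dropped whole), and candidate alignments — the profile-matched
start, all sign flips of the identity ordering, and deterministic random
orthogonal restarts — are scored by the spatial residual of the implied
matches under the best proper rigid motion: an eigenvector flip corresponds
to a spatial reflection, which no proper rotation can absorb, so wrong
flips score badly. A final nearest-point pass with projection onto the
target surface removes tessellation quantization. Correspondence on a
relabelled copy of a (non-symmetric) mesh is exact; on a rotated,
radially perturbed sphere the spectral match recovers the true map while a
plain spatial nearest-neighbour oracle fails by an order of magnitude.

Point sets in correspondence are aligned by generalized Procrustes
(rotation and translation only — scaling is off so that size differences
remain shape modes; reflections are corrected to proper rotations), then
modelled by PCA of the stacked vertex coordinates. Modes are orthonormal
displacement fields with descending variances; reconstruction with all
modes is exact, and the implementation is verified against a dense Gram
matrix eigen-decomposition. Per-mode group differences use the same ANCOVA
as the compositional analysis. Shaft-dominated modes can be flagged
(threshold on the displacement energy fraction in a configurable
superior/inferior z-band) but are never dropped automatically; exclusion is
an explicit argument. Mode visualization returns the mean surface displaced
by +/- k SD along a mode and the per-vertex displacement norm for colour
mapping (`norm = k * sqrt(variance) * |mode|`, exactly).

**Known limitation.** Estimated spectral correspondences carry a
correspondence-noise floor (tangential drift across subjects) that
attenuates weak modes: in the planted two-mode experiment (SDs 2 mm and
1 mm) the pipeline run from masks alone recovers the dominant mode with
score correlation above 0.9, but the 1-mm mode is partially absorbed into
the noise floor. Shape-model *recovery* claims (4:1 eigenvalue ratio within
25%, subspace angle below 10 degrees) are therefore verified on the
generator's exact material correspondences over decimated meshes, which is
the contract of `build_shape_model()` (its precondition is corresponded
point sets); correspondence estimation is verified by its own exactness and
oracle tests.

# Morphological prevalence statistics

A knee is abnormal if any compartment's modified Noyes grade is >= 1; this
drives the exclusion list for the compositional stages (shape and
morphological stages keep all knees). Prevalence tables report per-group,
per-compartment grade counts with percentages of group knee totals, and the
Pearson chi-square without continuity correction — the convention verified
to reproduce the published statistics exactly (6.658 for the combined
knee-level table, 5.51 for the LFC) — with `df = (r-1)(c-1)`. A zero
margin makes the test undefined: per-compartment tests where one grade
never occurs drop empty columns, and a compartment with no abnormalities at
all is reported as NA, not an error. Grade-level tables are primary; the
binary (abnormal/normal) collapse is also emitted and agrees closely on
data like these. Percentages print at one decimal, rounded half-up.

Phantom repeatability uses the two-instances-of-three-concentrations
design: per-vial decay series are fitted and the coefficient of variation
(sample SD convention, n-1, recorded in the report) is computed over
repeats within scanner (intra) and over scanner means (inter). Error
propagation through the exponential fit roughly doubles relative noise, so
1% signal noise produces ~2% CV in T — the tested band reflects this
computed relationship.

# Pipeline

`run_pipeline()` executes the stages in study order: metadata and
morphological accounting -> Noyes >= 1 exclusion (compositional stages
only) -> optional within-knee rigid echo alignment -> nonrigid morph to the
atlas -> atlas-space T1rho/T2 fitting with quality filtering -> ROI and
layer ANCOVA -> voxel-wise statistics and roll-ups -> bone meshing,
correspondence, PCA and per-mode tests -> phantom QC -> report assembly
with a provenance block (seed, alpha, covariates, package version). Stages
are cached on disk keyed by a hash of the configuration, so reruns with an
unchanged configuration perform no recomputation and reproduce the report;
`validate_inputs()` checks grids, label vocabularies, timing conventions
and metadata completeness without mutating anything. Whether shape
modeling excludes Noyes >= 1 knees is configurable and off by default (the
exclusion is tied to compositional analysis).

# Problem sizes used by the test suite

The unit suite runs on reduced geometries chosen to exercise every code
path with comfortable margins: 40^3 grids at 2.4 mm for fitting and layer
tests, 48^3 at 2 mm for registration recovery, 64^3 masks for shape
recovery, and a 32^3, 8-knee cohort for the end-to-end pipeline. The
acceptance checks run the registration criterion at the study's native
96^3 / 1 mm resolution and the statistical calibrations at 2,000 and 5,000
replicates. These sizes are the package's own verification design; the
generator defaults remain at study scale.
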