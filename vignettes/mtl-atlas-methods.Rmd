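---
title: "Probabilistic MTL atlasing and sulcal conformation statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic MTL atlasing and sulcal conformation statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlatlas)
```

## The problem

The folds bordering the medial temporal lobe (MTL) — the rhinal sulcus (RS)
and the collateral sulcus, split into a rostral segment (CS proper) and a
caudal segment (CS post) — are landmarks for delineating the entorhinal,
perirhinal and parahippocampal cortices. Their morphology is bimodal: in
some hemispheres the RS and CS proper run into each other as one continuous
fold (the *connected* conformation, Type 1), in others they are clearly
*separated* (Type 2). A probabilistic atlas built from many co-registered
subjects summarizes, voxel by voxel, how often each structure occupies each
location of a stereotaxic space; before pooling subjects into one atlas,
one must check whether the two conformations actually occupy different
locations.

`mtlatlas` implements that whole chain as reusable, tested functions:
occurrence-map construction, fraction thresholding into blobs, bounding-box
extrema and centroid permutation tests between conformation types,
orthogonal-distance line fits to centroid clouds, and the cohort-level
proportion/t-test/phi statistics. Because cohorts of manually segmented MRI
masks are not generally distributable, the package also ships a synthetic
cohort generator that reproduces the *statistical structure* those analyses
assume, so every stage can be exercised and validated end to end.

## Occurrence maps, smoothing and blobs

Given per-subject binary masks $M_i$ on one grid, the probabilistic map is
the voxelwise mean $P(v) = \frac{1}{N}\sum_i M_i(v)$, optionally after
per-subject Gaussian smoothing. Without smoothing every value is an
occurrence fraction $k/N$: the share of subjects whose mask contains the
voxel. A *blob* at fraction $f$ is the set of voxels with $P(v) \ge f$
(inclusive, reading "present in at least $f$ of subjects"); the pipeline
uses $f = 0.05$ (outlier removal for atlas display) and $f = 0.25$ (a
sensitivity threshold).

Numerical choices:

* The "3 mm Gaussian kernel" is interpreted as FWHM, the convention of the
  SPM toolchain: $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, i.e.
  $\sigma = 1.274$ voxels on a 1 mm grid at 3 mm FWHM.
* The kernel is the sampled Gaussian truncated at $4\sigma$ and
  renormalized to unit sum, applied separably per axis, so an interior
  impulse keeps exactly unit mass.
* Boundaries are zero-padded; a relative mass loss above $10^{-6}$ raises
  an error rather than silently deflating occurrence values. Structures
  are therefore required to lie at least $2\,\mathrm{FWHM}$ from the grid
  edge, and the synthetic generator enforces a 7 mm margin (kernel
  half-width plus jitter allowance) by re-drawing jitter.
* Smoothing is linear, so smoothing each mask then averaging equals
  averaging then smoothing; the test suite checks this to $10^{-9}$
  relative tolerance, and per-subject smoothed volumes are cached inside
  the permutation tests (mathematically identical to re-smoothing every
  permutation, far cheaper).
* Sulcal maps are smoothed; compact cortical/hippocampal structures are
  large enough to overlap across subjects without smoothing and are
  averaged raw.

## Geometry: extrema, centroids, line fits

All geometry works on world millimetre coordinates of voxel *centers*
(0-based indices through the NIfTI affine). A blob's *bounding box* is the
per-axis minimum and maximum of its member voxel centers — on the
mediolateral (x), rostrocaudal (y) and dorsoventral (z) axes these are the
structure's extrema. The *center of mass* of a mask or blob is the
unweighted mean of member-voxel coordinates: a blob is a voxel set, not a
weighted cloud, so occurrence values do not weight the mean (a weighted
variant is exposed for exploration but is not part of the pipeline).

Per-subject centroids of one sulcus form a 3D cloud per conformation type,
summarized by the total-least-squares line $P = p_0 + t\,d$: $p_0$ is the
coordinate mean, $d$ the dominant right singular vector of the centered
cloud (the direction minimizing total squared orthogonal distance), and
$t$ the per-point projections. The SVD sign is arbitrary, so $d$ is
canonicalized: the component of largest absolute value is made positive,
ties broken in x, y, z order. When the two leading singular values tie the
direction is ill-determined; the fit carries a `degenerate_direction` flag
and a warning instead of silently picking one axis.

## Permutation inference between conformation types

For a given sulcus, hemisphere and threshold, the two groups' masks are
merged into group blobs and compared through 6 extremum statistics
(min/max × 3 axes), each the signed difference (Type 1 − Type 2) in mm.
The null distribution is built from `n_perm` random relabelings that
preserve the group sizes, recomputing both group blobs and their extrema
each time (default `n_perm = 1000`, sampled with replacement from the
relabeling space rather than enumerated). Centroid tests work the same way
on the difference of group-mean centroid coordinates per axis.

The decision rule is two-sided: the observed difference is significant
when it falls strictly outside the central 95% interval of the null
(2.5th–97.5th centiles, linear-interpolation quantiles). The methods
wording of a one-sided 95th-centile rule is irreconcilable with the
reported example of −5 mm declared significant against an interval of
(−2, 3); the two-sided central interval reproduces that decision, and a
one-sided option remains available (`alternative = "greater"`). Reported
intervals are centile bounds, not null min/max. A permutation that yields
an empty blob is redrawn (bounded at 100 redraws per permutation, with a
message), keeping the null at exactly `n_perm` values. Everything is
deterministic given the seed, and results are invariant to the input
order of masks (subjects are canonically ordered internally).

Two statistical caveats are worth stating plainly. First, extremum
statistics on a 1 mm grid are integer-valued; with the narrow nulls that
tight cohorts produce, the strict-outside interval rule is conservative,
and its realized type-I rate sits below the nominal 0.05 (the calibration
suite quantifies this). Second, the direction comparison pairs only the
three components of two unit vectors in a paired t-test with 2 degrees of
freedom: it has very low power and is blind to symmetric component swaps.
It is included as the complementary descriptive analysis it is, not as a
powerful detector.

No multiple-testing correction is applied across the extrema tests — the
analysis reports each of the 12 statistics (6 extrema × 2 thresholds) per
sulcus at its own level. The cohort-level morphometry and covariate
t-tests, in contrast, are corrected with Benjamini–Hochberg FDR within
the column family of each call.

## Cohort statistics

* Type percentages are reported with the Type-1 share truncated to two
  decimals and Type 2 as its complement to 100, matching the reporting
  convention of the cohort literature (29/76 prints as 38.15% / 61.85%);
  full-precision fractions are retained in the returned object.
* The one-proportion z-test defaults to the sample-proportion standard
  error $\sqrt{\hat p(1-\hat p)/n}$ (the behaviour of the commonly used
  statsmodels implementation); a null-variance score variant is
  selectable. The two-sample variant uses the pooled-proportion variance.
* Group comparisons are pooled-variance Student t-tests, two-sided —
  contrasts against brain surface reported elsewhere as one-way F
  statistics are equivalent to the squared t here, so only the t path
  exists. Binary contrasts (sex, conformation type) run through the same
  path on 0/1 codings.
* Inter-hemispheric type concordance is the Pearson correlation of the
  0/1-coded type across L/R pairs, identical to the closed-form 2×2 phi
  coefficient (verified to $10^{-12}$ in the tests).

## The synthetic cohort generator

The generator emulates exactly the features the analyses rely on, in a
shared 1 mm isotropic RAS+ space (default grid 80×96×72 voxels with
origin (−40, −86, −50) mm, large enough to hold both hemispheres' sulci
at least 2 FWHM from every edge):

* **Tubular sulcal imprints.** Each sulcus is a tube of radius 2 mm around
  a smooth control polyline, rasterized by exact distance-to-curve
  evaluation on a dense (≤ 0.25 mm) sampling; every sampled curve point's
  nearest voxel is always included, so even sub-voxel radii produce
  connected rods. The RS runs rostral-medial, the CS proper caudal-lateral,
  and the CS post caudal to a fixed transition plane (y = −52 mm in the
  template frame), echoing the landmark at the caudal tip of the
  hippocampal body.
* **Two conformations.** The base templates keep the caudal RS endpoint
  ~10 mm from the rostral CS proper endpoint. Type-1 hemispheres add a
  bridging tube (radius 1.5 mm) between those endpoints — merged into the
  RS mask, so the RS∪CSproper voxel set is one 26-connected component by
  construction. Type-2 hemispheres omit the bridge and must keep the two
  sulci at least `connection_gap` = 3 mm apart (checked on voxel-center
  distances; violating jitter draws are redrawn). The classifier
  (`classify_conformation`) declares Type 1 exactly when the union is one
  26-connected component; 26-connectivity is the most permissive standard
  neighbourhood and best matches visual "connectedness" of sulcal casts.
* **Inter-subject variability.** Each structure receives a rigid
  translation drawn per subject (`jitter_sd` = 1.5 mm per axis) plus
  small control-point noise (0.3 mm). No nonlinear warps: masks model
  *post-normalization* data, where residual misalignment is approximately
  a local translation. The 1.5 mm default is a free parameter (the source
  analyses publish no per-subject spatial statistics); it was chosen once
  because it makes the permutation null intervals span a few millimetres,
  the scale of the published intervals, and it is deliberately not tuned
  further.
* **Systematic effects.** `type_shift` adds a fixed millimetre offset to
  Type-2 hemispheres' templates (for power studies), and
  `type_affects_geometry = FALSE` builds *all* hemispheres from the
  separated template so the conformation label is pure bookkeeping on
  exchangeable geometry — the configuration used for null-calibration
  (type-I) studies, where any real bridge/shape difference between groups
  would confound the null.
* **Metadata and morphometry surrogates.** Ages uniform on 7–17 years,
  sexes exactly balanced, hemisphere volumes/surfaces from plausible
  normal distributions (5.5×10⁵ ± 4.5×10⁴ mm³, 9.0×10⁴ ± 8×10³ mm²).
  Conformation types are drawn at `p_type1` = 0.38 with inter-hemispheric
  concordance 0.71, mirroring the cohort rates those analyses report.
  Depth surrogates are drawn per sulcus and type from normal
  distributions whose means mirror the published morphometry (connected
  sulci slightly deeper), truncated to stay positive and to keep mean
  depth below maximum depth. These are surrogate *tables*, not
  measurements from the rasterized geometry.

What the generator does **not** emulate — folding mechanics, intensity
data, nonlinear inter-subject deformation, asymmetric hemispheric
geometry beyond mirroring, and any correlation between a hemisphere's
depth surrogate and its rasterized tube — bounds what green tests mean:
they validate the statistical machinery under its own assumptions, not
anatomical claims about real cohorts.

## Simulation problem sizes

The calibration and power suites run on a compact single-hemisphere grid
(48×56×48 voxels for calibration, 48×64×48 for the shifted-power setting)
holding one rhinal sulcus, with 30 subjects split 15/15: the same
statistics on a smaller canvas, chosen to keep full replicate studies
(200 null cohorts at 200 permutations; 100 shifted cohorts at 500
permutations) comfortably runnable on one CPU. The end-to-end experiment
(`run_experiment()`) defaults to the full 38-subject, both-hemisphere
cohort at 1000 permutations.

## Reproducibility

`run_experiment()` consumes a nested configuration (R list or YAML),
derives per-stage seeds from one top-level seed (simulation uses the seed
itself; each extrema test uses seed + 1000 + test index; each centroid
test seed + 2000 + test index), and writes `report.json` alongside a
manifest recording the package version, config snapshot, stage seeds and
MD5 hashes of every output. Re-running with the same config and seed
reproduces the JSON outputs byte for byte.

## Known limitations

* Extremum statistics inherit the grid quantization; sub-voxel location
  differences are invisible and realized test levels are conservative
  (see above).
* The generator's jitter model is uncalibrated against real segmentations
  by construction; absolute power numbers from it should be read as
  properties of the simulation conditions.
* `classify_conformation` depends on voxel connectivity, so masks
  resampled from another space must be re-binarized before
  classification; the readers require strictly binary input.
* The one-sample z-test variant ambiguity (sample vs null variance)
  changes p-values for proportions far from the reference; both variants
  are exposed and the default is documented rather than hidden.
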