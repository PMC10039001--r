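---
title: "Methods: virtual reconstruction and shape analysis of fragmentary crania"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual reconstruction and shape analysis of fragmentary crania}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtucrania)
```

## The problem

A fossil cranium is often recovered, or can only be digitised, in pieces. When
the pieces share no conjoining surfaces, they cannot be re-assembled by
surface matching: the only usable signal is anatomy itself. `virtucrania`
implements a reference-guided protocol for that situation, plus the
geometric-morphometric analyses that typically follow a virtual
reconstruction: shape-space PCA with out-of-sample projection of the
reconstructed individual, cranial-capacity estimation by warping a reference
endocast, region-level comparison of the occipital squama, contour-polyline
mapping of the external vault topology, and discrete-trait clustering by
neighbour joining and exhaustive maximum parsimony.

Everything is exercised on a fully synthetic specimen generator with known
ground truth, so the whole pipeline is testable without any external data.

## Procrustes machinery

Landmark configurations are named, ordered sets of 3D points in mm
(`landmark_config`), with a missing-value mask and a bilateral pairing table
(left/right pairs plus midline names).

* **OPA** (`opa_align`) superimposes a source onto a target by translation,
  rotation and (optionally) uniform scale, solved in closed form by SVD of the
  cross-covariance. Reflections are never permitted (the rotation determinant
  is forced to +1): anatomical chirality must survive every registration.
  Landmarks missing in either configuration are excluded pairwise from the
  fit; the transform still applies to all points.
* **GPA** (`gpa`) iterates rotate-to-consensus / re-average, starting from the
  first configuration, scaling each input once to unit centroid size when
  `with_scaling = TRUE`. Iteration stops when the consensus moves by less
  than `1e-10`; the deterministic initialization makes results reproducible,
  at the cost of fixing the consensus orientation by the first specimen
  (shape is unaffected, and the order-invariance of the consensus *shape* is
  tested).
* **Symmetrisation** (`symmetrise`) reflects the configuration across the
  least-squares plane through its midline landmarks, swaps left/right labels,
  rigidly registers the mirror back onto the original, and averages. The
  midline-based plane is used because the downstream protocols name midline
  landmarks (glabella, bregma, lambda) as their alignment anchors.

Two distances are exposed: the Procrustes distance (on centred, unit-size
shapes) and the cumulative Euclidean distance in mm, the *sum* of pointwise
landmark distances. Whether "cumulative" should be a sum or a mean is not
fixed by usage in the field; the sum is the default and a `reduce = "mean"`
flag switches, which only rescales rankings by a constant and therefore never
changes them.

## Thin-plate splines

The 3D interpolating spline uses the kernel U(r) = r, the standard choice of
3D geometric-morphometric software, recorded in the model object as its
kernel identifier. With this kernel the quadratic form of the non-affine
weights is conditionally *negative* definite, so the physical bending energy
is its negative; `tps_bending_energy` and the bending-energy matrix are
sign-corrected accordingly and are zero exactly when the target is an affine
image of the source. Warp evaluation computes distances difference-first per
source landmark, which avoids the catastrophic cancellation of the expanded
inner-product formula and keeps the interpolation residual near machine
precision even at cranial scales (hundreds of mm).

Missing landmarks are estimated (`estimate_missing_landmarks`) by registering
a complete reference onto the target over the shared landmarks (OPA with
scaling), fitting a TPS on those landmarks, and mapping the reference's
positions of the missing ones through it. Estimated points are flagged, not
silently merged with observed ones. The estimator cannot beat a specimen's
own idiosyncratic deviation from the reference — the error floor is the
individual noise at that landmark — but it does absorb smooth systematic
shape differences between reference and target, which is what the tests
verify: with a template differing smoothly by ~9 mm per landmark, the
recovery error stays at the ~3.5 mm individual-noise floor.

## Reference ranking and fragment alignment

The re-assembly protocol treats the two fragments as one individual:

1. both fragment and reference sub-configuration are symmetrised (when their
   pairing supports it — at least three midline landmarks);
2. the reference sub-configuration is scaled to the fragment's centroid size;
3. rigid Procrustes registration;
4. cumulative Euclidean distance (and Procrustes distance) recorded.

The combined score of a reference is the *sum* of the two fragments'
cumulative Euclidean distances; no combination rule is canonical, so the sum
of the primary metric is used and both per-fragment columns (plus Procrustes
distances) are always reported. Ties break on the Procrustes sum, then
reference id, so rankings are deterministic.

During *ranking* the reference is scaled to each fragment separately (each
fragment is its own registration problem). During *alignment*
(`align_fragments`) the reference is scaled **once**, preserving the
fragments' true mutual scale, and each fragment is then registered by
rotation and translation only — both fragments belong to one individual, so
per-fragment scaling is anatomically wrong. The "combined size" of a fragment
pair is defined pose-invariantly as the root of the pooled squared deviations
about the per-fragment centroids, `sqrt(cs_a^2 + cs_b^2)`; the naive centroid
size of the pooled landmarks would depend on the fragments' arbitrary
relative pose.

## The comparative shape space

`shape_space()` is the package's model-fitting function: GPA with scaling,
then PCA by eigen-decomposition of the covariance matrix of the aligned
coordinates (covariance, not correlation — coordinates share units, and
standardising per coordinate would distort shape variation). Eigenvector
signs are fixed by making the largest-magnitude loading positive. The fitted
object has `print`, `summary`, `predict` and `plot` methods; `predict`
projects out-of-sample specimens without updating the space.

Projection registers the query exactly as the training sample was registered:
centre, scale to unit centroid size, optimal rotation onto the consensus,
subtract the training mean, project onto the eigenvectors. Three desirable
contracts — exact re-projection of training specimens, exactly zero-mean
training scores, and the mean shape projecting exactly to the origin — cannot
all hold at once for any registration-based projector, because the arithmetic
mean of unit-size shapes has centroid size strictly below one. The package
keeps the first two exact (plus exact similarity-invariance of projections)
and accepts that the consensus projects to the origin only up to the square
of the sample's Procrustes spread; on realistic samples that residual is two
orders of magnitude below the score spread, and the tests bound it at 5% of
it.

`pc_extreme_maps` visualises a component by TPS-warping a template mesh to
the shapes at mean ± k·SD along it, reporting each facet's signed relative
area change against the mean-shape mesh (positive = local expansion). The
plus and minus maps are near-opposite at small excursions, which the tests
use as a linearity check.

## Cranial capacity

`estimate_capacity` fits a single TPS on the union of fixed landmarks and
surface semilandmarks (reference onto target), warps the reference endocast
mesh through it, and integrates the warped volume by the divergence theorem
(mm³ → cc). Fixed-plus-semilandmarks is the default because both sets
describe the vault geometry the endocast must follow; a `use_semis = FALSE`
flag restricts the warp to fixed landmarks for sensitivity analysis.

Surface semilandmarks are transferred to a new specimen by
`project_surface_semilandmarks` (TPS on the fixed landmarks, then
closest-point projection onto the target surface) and refined by
`slide_semilandmarks`: each semilandmark moves within the tangent plane at
its surface position, the displacements minimising the TPS bending energy
towards the reference are solved in closed form (a quadratic program with a
tiny ridge for rank safety), points are re-projected onto the surface, and
the cycle repeats (3 iterations by default). Sliding minimises bending
energy because that is the standard criterion of the field's toolchains when
no other is specified; the energy is tested to be non-increasing, with the
best configuration returned (and a warning) if re-projection ever makes it
climb twice in a row.

Mesh volume requires watertightness; face orientation is repaired by
flood-fill winding consistency and a global sign check, so scrambled input
windings cannot flip or corrupt the volume.

## Contour polylines

The slicing frame runs from the glabella to the opisthocranion (the
maximum-cranial-length chord); cutting planes are perpendicular to it, spaced
evenly (2.0 mm by default), starting *at* the opisthocranion. The last plane
is the largest offset not exceeding the chord, so a plane passes through the
glabella only when the chord is an exact multiple of the spacing — the
starting plane is fixed by convention, the endpoint behaviour is documented
rather than guessed. An optional rigid pre-alignment registers the specimen's
glabella–bregma–lambda triple onto a reference's, so sections of different
specimens share a frame.

Sections are computed by triangle–plane intersection; segments are chained
through shared mesh edges, which makes endpoint matching exact rather than
tolerance-based, and chains are emitted as closed polygons (watertight
meshes) or flagged open chains (holes). Polygons with fewer than three
distinct vertices are discarded. A stacked-sections cross-check (sum of
section areas × spacing vs. the divergence-theorem volume) guards the whole
construction.

## Occipital analyses

Group mean shapes are coordinate-wise means of already-superimposed
configurations. Semilandmark configurations become meshes through a fixed
triangulation template, so meshes built from homologous configurations share
topology exactly and `local_mesh_diff` can compare them facet by facet:
`(area_b − area_a) / area_a`, positive where `b` is locally expanded. The
direction of the comparison (which specimen is `a`) is recorded in the output
metadata because the sign convention is the entire meaning of the map.

The midsagittal profile intersects the mesh with the midline plane, picks the
chain nearest to the start and end anchors (distances measured to chain
*segments*, not vertices, so coarse meshes do not break the matching), takes
the shorter arc between them on closed sections, and resamples to `n`
(default 30) points equally spaced in arc length. Scalar measurements — the
angle at lambda subtended by the two asteria, and the maximum breadth
measured as the range of signed vertex distances from the midsagittal plane —
are tested against constructed geometries and for rigid invariance.

## Discrete traits

The character matrix holds single-symbol states with `?` for
missing/uncertain. Composite taxa are built conservatively: the majority rule
returns `?` on ties, and combining two individuals returns `?` on
disagreement — inventing a state would manufacture signal. Derived-trait
counts keep the full character count in the denominator, so an
all-uncertain row scores 0/20, matching how such counts are conventionally
printed.

Pairwise distance is the proportion of mismatches over characters scored in
both taxa (the "mean character difference" a distance-based clustering of
such data conventionally uses), exposed as a parameter-free default.
Neighbour joining is the canonical agglomeration with the Studier–Keppler
criterion; negative branch lengths are clamped to zero with the deficit moved
to the sister branch (preserving path lengths), and criterion ties break on
the lexicographically smallest label pair. Parsimony is exact: every unrooted
binary topology is enumerated by stepwise edge insertion (3·5·…·(2n−5)
trees, capped at 10 taxa), scored by Fitch counts with `?` as full ambiguity,
and the strict consensus keeps exactly the splits present in every
most-parsimonious tree. Exhaustive search is preferred over heuristics
because the comparative problems this targets have ≤ 8 taxa, where exactness
is affordable and testable; `ape` and `phangorn` serve as independent
cross-checks in the test suite, never as the implementation.

## The synthetic generator

`generate_template` builds a deterministic cranium-like surface: an ellipsoid
with semi-axes 90 × 70 × 65 mm (a realistic adult braincase envelope),
smoothly modulated by six seeded Gaussian bumps of ~5% relative amplitude, so
the surface has anatomy-like regional structure without being a sphere. It
carries 30 named landmarks at fixed surface directions (glabella, bregma,
lambda, opisthocranion, asterion/porion/mastoidale/… pairs), a bilateral
pairing table, and an occipital patch of 5 fixed landmarks plus 150 surface
semilandmarks on a 15 × 10 grid with its triangulation template.

`generate_population` adds, per group, a smooth random displacement field (a
symmetric strain plus four broad Gaussian bumps, rescaled to an rms of
`offset` mm) and, per individual, iid Gaussian landmark noise of `sd` mm per
coordinate; meshes and semilandmarks ride the same TPS warp, so surface and
landmarks never disagree. The defaults — 20 specimens in 4 groups, 8 mm group
offset, 2 mm individual noise — give between-group shape differences about
four times the within-group spread, the regime in which comparative cranial
samples separate clearly in a PCA while individuals still overlap; they are
also small enough that the whole suite runs in about a minute.

`fragment_specimen` splits a specimen by a roughly coronal plane with a 2 mm
exclusion band (no conjoining points survive, matching the situation the
alignment protocol exists for), applies a fixed rigid motion to each fragment
(plus optional seeded jitter), and returns the exact motions as ground truth.
`generate_endocast` rebuilds the surface on semi-axes reduced by the shell
thickness; with bumps disabled its volume is exactly the analytic ellipsoid
volume, giving the capacity pipeline an oracle. `simulate_characters` evolves
binary characters along a given tree with per-branch flip probability
1 − exp(−rate·length).

What the generator does *not* emulate: taphonomic distortion, surface
concretions, measurement error correlated along the surface, allometry, and
integration patterns between cranial modules. Tests passing on this generator
therefore demonstrate the correctness of the algorithms under known truth,
not the biological validity of any particular empirical result.

## Numerical conventions and problem sizes

* Coordinates are mm everywhere; volumes are reported in cc.
* Faces are 1-based internally (the natural R convention); PLY's 0-based and
  OBJ's 1-based indices are converted at I/O. Mesh I/O is ASCII (PLY with an
  optional per-face `quality` scalar, OBJ, STL with vertex merging at
  1e-6 mm); text formats serialise with 9 significant digits.
* GPA converges at 1e-10 with a 100-iteration cap; TPS systems are solved
  densely (configurations here are ≤ ~200 points); duplicate source landmarks
  are reported by name rather than producing a silent singular solve.
* All generator randomness flows through explicit seeds via a local RNG that
  never disturbs the caller's `.Random.seed`.
* Test and acceptance problem sizes: populations of 20 specimens with 30
  landmarks, meshes of 642–2562 vertices (icosphere subdivisions 3–4),
  100-replicate simulation checks for the alignment protocol, 200 replicates
  for missing-landmark recovery, and exhaustive parsimony up to 8 taxa
  (10,395 topologies, ~2 s). These sizes make every stochastic claim cheap to
  re-verify while keeping each property's effect size far from its threshold.

## Known limitations

* Fragment alignment is landmark-based by design; no landmark-free (ICP-style)
  fallback exists, and fragments with fewer than four landmarks cannot be
  processed.
* The shape-space projector's mean-shape-to-origin property is exact only to
  second order in the sample spread (see above) — inherent to
  registration-based projection, not an implementation defect.
* Exhaustive parsimony is deliberately capped at 10 taxa; larger matrices
  need heuristic search, which is out of scope.
* Binary PLY and curve (ridge) semilandmarks are not supported; 2D
  morphometrics and asymmetry decomposition are out of scope.
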