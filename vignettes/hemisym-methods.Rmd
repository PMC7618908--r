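---
title: "hemisym: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemisym: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hemisym` implements a complete vertex-wise analysis chain for left-right
asymmetry of paired cortical hemispheres: construction of a left-right
symmetric spatiotemporal surface template, registration of individual
hemispheres into it, per-subject asymmetry-index mapping, a
mirror-symmetrised group ICA / dual-regression stream for resting-state
timeseries, and permutation inference with threshold-free cluster
enhancement (TFCE). Real cortical surface data is not required: the
package ships a synthetic-cohort generator that emulates the relevant
structure of a neonatal imaging cohort on octasphere meshes, with planted
ground truth, and the whole pipeline is validated against it. This
vignette explains the models, the numerical choices, and where the design
was genuinely open, what was decided and why.

## The coordinate system: octasphere meshes with an exact mirror

Every map lives on a shared triangulated sphere. We use octaspheres
(recursively subdivided octahedra, `make_octasphere()`) rather than
icospheres for one decisive reason: the octahedron's vertex set is exactly
invariant under the reflection `x -> -x`, and midpoint subdivision
preserves that invariance *bitwise* in IEEE arithmetic. Left-right
mirroring is therefore an exact vertex permutation (`mirror_map()`), not
an approximate resampling, and "a map equals its mirror" is a testable
identity at `1e-10` rather than at interpolation tolerance. Subdivision
levels are nested (the first `4*4^l + 2` vertices of level `l+1` are the
level-`l` vertices), which the registration pyramid exploits.

Hemispheric convention: both hemispheres share the mesh. Left-hemisphere
maps are indexed directly; right-hemisphere maps live in the right
hemisphere's own frame and reach the left frame through the mirror
permutation. Anatomical (mm) surfaces use RAS-like axes with the mirror
plane at `x = 0`.

## Geometry primitives

* **Thickness** is the Euclidean distance between corresponding white and
  pial vertices (mm).
* **Vertex area** assigns one third of each incident triangle's area to a
  vertex, so vertex areas sum exactly to the mesh area.
* **Mean curvature** is half the norm of the area-normalised cotangent
  Laplacian of the coordinates, signed positive towards the outward
  normal; a sphere of radius r measures `1/r` (within 0.2% at subdivision
  level 4). Vertices whose total cotangent weight is non-positive
  (obtuse-degenerate patches) fall back to uniform weights and are
  flagged. The estimator is standard, chosen because an analytic sphere
  oracle exists; no equivalence with any specific imaging pipeline's
  curvature is claimed.
* **Folding-bias removal** regresses a metric on `[1, curvature]` and
  returns the residual plus the original mean. Keeping the mean matters:
  asymmetry indices are ratios and depend on absolute level. The output is
  exactly uncorrelated with curvature and the operation is idempotent.
* **Smoothing** realises a geodesic Gaussian of width sigma as heat
  diffusion for time `t = sigma^2/2`, using explicit Euler steps of the
  area-weighted cotangent Laplacian. The step size is held at half the
  Gershgorin stability bound, so the iteration cannot diverge; negative
  cotangent weights are clamped to zero (keeping the operator symmetric,
  hence mass-conserving). On a sphere the scheme reproduces the
  closed-form eigenvalue decay `exp(-l(l+1) sigma^2 / (2 r^2))` of
  spherical harmonics within a few percent up to degree 8, which is the
  module's main numerical acceptance test. Defaults follow the analysis
  conventions: 2 mm for structural asymmetry maps, 4 mm for functional
  timeseries.

## Deformation fields and registration

A deformation field stores one unit-vector target per grid vertex and is
used in *pull-back* convention: `resample_metric(m, d)` evaluates `m` at
`d`'s targets by spherical barycentric interpolation (gnomonic
point-location with nonnegative weights summing to 1). Composition
interpolates the second field's targets at the first field's targets and
re-projects to the sphere; radial projection makes this exact for the
identity and for rotations. Inversion uses a scattered-data initial guess
(locating grid vertices in the deformed mesh) refined by a damped fixed
point on the residual; `compose(d, invert(d))` stays within `1e-3`
radians of the identity for the small smooth warps the pipeline produces.
Averaging is the weighted Euclidean mean of targets re-projected to the
sphere — valid for small displacements; near-antipodal means are refused.
Note one inherent limit: averaging the two images of a point under
`R(+theta)` and `R(-theta)` cancels the rotation only to first order; the
chordal (and indeed geodesic) mean tilts towards the axis by
`O(theta^2)`. Tests assert exactly this behaviour.

Registration (`register_spherical()`) plays the interface role of an
MSM-style tool but is deliberately lightweight: sum of squared metric
differences plus a Dirichlet (first-difference) penalty on tangent
displacements. Three implementation decisions came out of validation
rather than first principles, and replaced the initially planned plain
coarse-to-fine gradient descent, which stalled far short of the
planted-warp recovery target:

1. **Incremental composition with re-smoothing.** The pyramid is a
   schedule of smoothing scales (`mean_edge * {4, 2, 1, 0.5, 0}`); at
   each stage the current warp is applied to the moving image, *both*
   images are re-smoothed at the stage scale, and a small correction is
   estimated and composed into the total. Smoothing does not commute with
   warping, so smoothing the original image once (the classic pyramid)
   makes the coarse objective actively wrong under large accumulated
   warps; re-smoothing the warped image avoids that.
2. **Gauss-Newton with Levenberg-Marquardt damping.** Each correction
   solves a sparse linearised least-squares problem in a per-vertex
   tangent basis (Horn-Schunck style), with damping adapted until a step
   is accepted. Per-vertex gradients are area-weighted averages of
   triangle gradients; single-triangle one-sided gradients make the
   linearisation unusable at vertex locations. Steps that would fold a
   spherical triangle are rejected, so every returned field is fold-free,
   and each stage's objective is non-increasing over accepted steps. The
   optimiser is deterministic (no randomness anywhere).
3. **Symmetric consensus.** By default the registration is also run
   backwards and the result is `average(forward, invert(backward))` — the
   same construction the left-right halfway space uses. On planted smooth
   warps of 2-10 degrees mean displacement this raises recovery from
   ~65-70% to ~75-85% error reduction.

The Dirichlet weight default is `lambda = 10` on the normalised objective
(mean squared data residual + `lambda` x mean squared edge difference of
displacements). The data term only constrains displacement along the
metric gradient (the aperture problem); the prior supplies the orthogonal
component, and weaker settings let the estimate drift in the data null
space. The value 10 was selected on planted-warp recovery experiments
*before* the acceptance criteria were frozen.

## The symmetric spatiotemporal atlas

Weekly templates are adaptive-kernel weighted averages: Gaussian weights
in age whose width grows until the effective sample size
`(sum w)^2 / sum w^2` reaches `min_effective_n` (default 8). Templates are
refined by alternating subject-to-template registration with template
rebuilding until the mean within-template variance changes by less than
`1e-3` relative (at most 10 iterations); the variance trajectory is
monitored and an increase on two consecutive iterations is an error, not
a warning. Ensemble bias is removed by `dedrift()`: every field is
composed with the inverse of the ensemble average, after which the
average of the fields is the identity to `1e-3` radians. (The source
pipeline's rigid-alignment-to-adult-reference bias removal is collapsed
into this dedrifting step; synthetic data has no adult reference.)

**Left-right symmetrisation** registers the left sulcal depth map to the
mirrored right map in both directions, forms the consensus warp
`average(forward, invert(backward))`, and takes its halfway interpolation
(average with the identity) to define the intermediate space; the
mirrored-right hemisphere enters through the conjugate half-warp. Both
hemispheres' maps are resampled into that space, averaged across
hemispheres, and finally averaged over the mirror orbit
`(s + mirror(s))/2`. The last step is what makes the released template
satisfy `s == mirror(s)` *exactly* (to `1e-10`) on the shared mesh — the
analogue of the vanishing left-minus-right template difference after
cross-hemispheric registration and averaging. On an already-symmetric
template the whole operation is a fixed point (half-warps within `1e-3`
radians of the identity).

Consecutive weekly templates are registered pairwise and the links
composed into a single pull-back field per week (`to40`), so a subject's
native data reaches the reference week with *one* interpolation:
`subject -> local week` is registered directly, composed with `to40`,
and resampled once. A test verifies that the one-step resampling beats a
deliberately double-interpolated alternative against analytic ground
truth.

## Asymmetry maps

The asymmetry index is `AI = (L - R) / ((L + R)/2)`, leftward positive,
computed after the right map is mirror-indexed into the left frame.
For nonnegative inputs it is bounded in `[-2, 2]`. Where the denominator
falls below `eps = 1e-8` (native units) the index is set to 0 and the
vertex flagged missing — flagged vertices are excluded from statistics,
and missingness is always an explicit flag, never a NaN. Structural AI
maps are smoothed (sigma = 2 mm) on the subject's *symmetric
midthickness* surface — the average of the left and YZ-flipped right
midthickness coordinates, relaxed for 10 iterations at strength 0.75 —
so smoothing geometry favours neither hemisphere. Functional AI maps are
not smoothed further. Functional analyses are restricted to one common
mask per component, `Z > 5.1` on the signed symmetric group map, so every
subject shares one spatial extent; signed (not absolute) thresholding is
used, as written in the source convention.

## Functional stream

Per-vertex-demeaned timeseries are smoothed frame-by-frame (sigma = 4 mm),
reduced per hemisphere by incremental group PCA (MIGP: streaming
concatenate-then-truncate SVD over subjects in a seeded random order),
and concatenated as `[L; mirror(R); mirror(L); R]`. That multiset of rows
is exactly invariant both under the mirror permutation and under
exchanging the hemispheres, which is what forces group components to be
hemispherically unbiased; a subject's dual-regressed asymmetry then
reflects that subject's data, not the group template's asymmetry. Note
the stacked matrix has twice the rows of the two inputs — the price of
exact exchange invariance.

Group ICA is fixed-point (FastICA) spatial ICA with the logcosh contrast
and deflation on the PCA-whitened reduced matrix, seeded and
deterministic; component signs are fixed by nonnegative skewness,
components ordered by explained variance, maps Z-scored by plain
standardisation (no mixture-model Z — this affects only the calibration
of the 5.1 threshold, which the synthetic generator accounts for).
Desk-scale defaults are MIGP dimension 64 and ICA dimension 8 (the
full-scale analysis values, 2000 and 25, remain configurable). Signal
components are selected by an explicit keep-list, mirroring manual
labelling. Dual regression is the standard two stages, with stage-1
timecourses variance-normalised before stage 2 (flag-exposed).

With left amplitudes `(1 + delta) x` right, the mask-mean of the subject
map AI estimates the amplitude AI `2 delta / (2 + delta)`; the package's
tests invert this to recover `delta` itself.

## Permutation inference

Vertex-wise OLS t statistics feed TFCE with `H = 2.0`, `E = 0.6`,
`dh = max(observed)/100` (fixed across the permutations of an analysis so
observed and null enhancements are on one scale), and group-average
midthickness vertex areas as the extent measure. The TFCE kernel is the
literal definition — a full per-threshold connected-component sweep — in
C++, with component areas accumulated in ascending vertex order so an
independent R implementation of the same sweep reproduces it bit for bit
(an acceptance requirement, tested on 66-vertex meshes).

The null distribution is the maximum TFCE over vertices, *features and
contrasts* under one shared shuffle schedule — joint family-wise error
control, so correcting across more features can only raise p-values.
One-sample designs sign-flip nuisance-residualised data (errors assumed
symmetric); general designs use Freedman-Lane. p-values follow the
`(1 + #{null >= obs}) / (1 + n_perm)` convention, never below
`1/(n_perm+1)`; significance is the strict rule `-log10(p) > 1.301` at
alpha 0.05 (the conventional "1.3" cut-off). Zero-variance vertices carry
a capped sentinel t of `1e6`. One-sided contrast pairs are separate
analyses on the signed statistic; internally a `+c/-c` pair shares one
GLM fit per permutation. Nuisance covariates are mean-centred in the
standard design builder so the intercept contrast tests the cohort mean —
without centring, a one-sample "mean asymmetry" test would actually test
the extrapolated asymmetry at covariate zero.

In the validated null world the realised family-wise false-positive rate
over 200 synthetic cohorts is 0.09 at alpha = 0.05 (two one-sided
contrasts, joint correction) — at the upper edge of, but inside, the
accepted `[0.02, 0.09]` band.

Cohort-level demographics use one-sample t (hemispheric volume
asymmetry), Welch two-sample t (continuous covariates between groups),
and the chi-squared independence test (sex by group), with median/IQR
summaries.

## The synthetic world — what it does and does not emulate

`generate_structural_cohort()` draws, per subject: a sulcal-depth-like
field (linear age interpolation between two band-limited random fields,
degrees 3-8, unit variance), a thickness-like field (2 mm baseline plus
0.25 mm of pattern), a smooth random warp per hemisphere (spherical
harmonic band 1-2, default mean displacement 3 degrees), vertex-wise
Gaussian noise (default sd 0.05), and covariates loosely patterned on a
term neonatal cohort: GA uniform 37-42 weeks, PMA uniform in the cohort
age range (default 37-44), sex Bernoulli(0.5), birthweight Z standard
normal, total brain volume N(340, 30) cm^3, hemispheric volume asymmetry
N(-1.8, 1.5) cm^3. These distributions are stated inputs, not asserted
reproductions of any published table. Planted asymmetries scale the right
map by `(2-d)/(2+d)` inside geodesic caps so the true AI is exactly `d`
there, with optional additive sex and age modulation of `d`; anatomical
surfaces are radial displacements of the sphere (white at
`50 + 2 x depth` mm, pial one thickness further out).

`generate_functional_cohort()` builds bilateral, *mirror-symmetric*
network maps (Gaussian bumps plus their mirror images, default radius 14
degrees — chosen a priori so a bump's Z-scored peak, about
`sqrt((1-f)/f)` for active fraction `f`, clears the 5.1 mask threshold),
shared unit-variance Gaussian timecourses, per-hemisphere amplitudes with
`a_L = (1 + delta_f) a_R` on lateralised networks, and Gaussian sensor
noise.

What the generator does *not* emulate: cortical folding dynamics,
haemodynamics, motion or acquisition artefacts, spatially structured
noise, or the empirical covariance of real covariates. A green test
therefore establishes that the pipeline's mathematics and software are
correct under its stated assumptions — not that the source study's
biological findings are reproduced. The validation worlds are fixed as
follows, decided before the acceptance criteria were first run: the
type-I-error world keeps 3-degree subject warps (misalignment as
structured noise under the null); the effect-recovery world omits warps,
because registration recovery is a separate criterion and 600 extra
registrations would not fit the test budget; the registration world uses
band-1-2 warps with mean displacements drawn uniformly from 2-10 degrees.

## Known limitations

* Barycentric interpolation is linear: deformation algebra identities
  (associativity, generic-angle rotation composition/inversion) hold
  exactly only in the small-warp or lattice-rotation limits, and to
  interpolation order otherwise.
* The registration is not MSM: no discrete optimisation, no higher-order
  regularisers, no claim of equivalence with the source pipeline's warps
  — only the same interface contracts and planted-warp recovery targets.
* Sign-flip inference assumes symmetric errors; the realised family-wise
  rate in the validated world sits at the upper edge of the nominal band.
* Heat-kernel smoothing is accurate to a few percent for features above
  the mesh scale; sub-edge-scale structure is not represented.
* The whole package is validated on spheres with planted effects; no
  claims are made about Draw-EM/FreeSurfer surface extraction, volume
  registration, or ribbon-constrained projection, which are out of scope.
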