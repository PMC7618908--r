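# hemisym

Vertex-wise mapping of left–right structural and functional asymmetry of
paired cortical hemispheres, on spherical surface meshes.

Quantifying cortical asymmetry at every vertex requires machinery that is
easy to get subtly wrong: the two hemispheres must be brought into
vertex-wise correspondence in a template space that favours neither side,
per-subject differences must be expressed on unbiased smoothing geometry,
functional group decompositions must not project group-level asymmetry
into individual maps, and inference must control the family-wise error
rate across thousands of vertices, several image features and paired
one-sided contrasts. `hemisym` implements that full chain for researchers
in developmental and population neuroimaging — and, because the real
cohorts such studies use are access-restricted, validates every stage on
synthetic spherical cortices with planted, machine-readable ground truth.

## What it computes

For paired hemispheric maps `L` and `R` in vertex-wise correspondence,
the **asymmetry index** at each vertex is

    AI = (L − R) / ((L + R) / 2),        leftward positive, AI ∈ [−2, 2]

Correspondence comes from a **left–right symmetric spatiotemporal
template**: weekly adaptive-kernel templates, iteratively refined by
spherical registration, symmetrised by cross-hemispheric registration in
both directions (the halfway warp is `average(forward, invert(backward))`)
and by averaging the hemispheres' maps, then chained week-to-week so any
subject reaches the reference week with a single interpolation.

Functional asymmetry uses **mirror-symmetrised group ICA**: per-hemisphere
MIGP reductions are concatenated with their mirrored copies, so group
components are exactly hemisphere-exchange invariant, and subject maps are
obtained by dual regression inside fixed `Z > 5.1` component masks.

Inference is vertex-wise GLM + **TFCE** (`H = 2.0`, `E = 0.6`, vertex
areas as the extent measure) with sign-flip or Freedman–Lane permutation
and joint max-statistic FWE correction across vertices, features and
contrasts; significance is `−log10(p) > 1.3` (alpha 0.05).

## Worked example

Thirty synthetic subjects, a leftward thickness asymmetry of AI = 0.2
planted in a cap covering 5% of the cortex, vertex noise sd 0.05:

```r
library(hemisym)

spec <- cohort_spec(n_subjects = 30, seed = 42, level = 3,
                    warp_mean_deg = 0, noise_sd = 0.05,
                    effects = list(list(feature = "thickness",
                                        center = c(0, 0, 1),
                                        radius_deg = 25.8, delta = 0.2)))
cohort <- generate_structural_cohort(spec)
mesh <- cohort$mesh

# per-subject AI maps, smoothed on the subject's symmetric midthickness
ai <- lapply(cohort$subjects, function(s) {
  raw <- asymmetry_index(s$thickness_left,
                         mirror_metric(s$thickness_right, mesh))
  smooth_asymmetry(raw, symmetric_midthickness(s$mid_left, s$mid_right),
                   sigma_mm = 2)
})
Y <- do.call(rbind, lapply(ai, `[[`, "values"))

# one-sample design with centred nuisance covariates; paired one-sided
# contrasts; sign-flip TFCE permutation inference
X <- make_design(cohort$ground_truth$covariates)
areas <- Reduce(`+`, lapply(cohort$subjects,
  function(s) vertex_areas(s$mid_left)$values)) / 30
res <- permutation_test(
  features = list(thickness_ai = Y), X = X,
  contrasts = list(C1_left_gt_right = c(1, rep(0, 6)),
                   C2_right_gt_left = c(-1, rep(0, 6))),
  mesh = mesh, params = tfce_params(areas = areas),
  n_perm = 500, seed = 7, scheme = "sign_flip")

r <- res$results[["thickness_ai:C1_left_gt_right"]]
sig <- significance_mask(r)
truth <- cohort$ground_truth$effect_masks[[1]]
```

Output:

```
planted patch: 13 vertices (5.0% of cortex)
mean AI inside patch: 0.195 (planted 0.2)
max t: 48.4;  min FWE p: 0.0020;  significant vertices: 13
Dice overlap with planted patch: 1.00
```

The cohort mean AI recovers the planted 0.2 (slightly attenuated by the
2 mm smoothing at the patch edge), the minimum FWE-corrected p saturates
at `1/(n_perm + 1)`, and the significant cluster coincides exactly with
the planted region. A null cohort (`effects = list()`) run the same way
reports no significant vertices.

The same pipeline is scriptable end to end:

```sh
Rscript -e 'hemisym::hemisym_cli()' full --seed 7 --out out/ --n-perm 500
```

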