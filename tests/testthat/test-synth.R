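test_that("template patterns are seeded, band-limited and standardised", {
  m <- make_octasphere(4)
  a <- generate_template_pattern(m, 9)
  b <- generate_template_pattern(m, 9)
  expect_identical(a$values, b$values)
  expect_false(identical(generate_template_pattern(m, 10)$values, a$values))
  # unit variance within 10% at level >= 4, near-zero mean
  A <- vertex_areas(sphere_surface(m, 1))$values
  mu <- sum(A * a$values) / sum(A)
  v <- sum(A * (a$values - mu)^2) / sum(A)
  expect_lt(abs(mu), 0.05)
  expect_lt(abs(v - 1), 0.1)
})

test_that("spherical harmonics are orthonormal eigenfunctions", {
  m <- make_octasphere(4)
  A <- vertex_areas(sphere_surface(m, 1))$values
  y1 <- real_sph_harm(3, 2, m$vertices)
  y2 <- real_sph_harm(3, -1, m$vertices)
  y3 <- real_sph_harm(5, 0, m$vertices)
  expect_equal(sum(A * y1^2), 1, tolerance = 0.02)
  expect_lt(abs(sum(A * y1 * y2)), 0.02)
  expect_lt(abs(sum(A * y1 * y3)), 0.02)
})

test_that("structural cohorts: null construction, planted AI, determinism", {
  # delta 0, no noise, no warps: identically zero AI
  sp0 <- cohort_spec(n_subjects = 3, seed = 31, level = 2,
                     warp_mean_deg = 0, noise_sd = 0)
  c0 <- generate_structural_cohort(sp0)
  for (s in c0$subjects) {
    ai <- asymmetry_index(s$thickness_left,
                          mirror_metric(s$thickness_right, c0$mesh))
    expect_lt(max(abs(ai$values)), 1e-12)
  }
  # planted delta recovered in the cohort mean
  sp <- cohort_spec(n_subjects = 40, seed = 32, level = 3,
                    warp_mean_deg = 0, noise_sd = 0.05,
                    effects = list(list(feature = "thickness",
                                        center = c(0, 0, 1),
                                        radius_deg = 25.8, delta = 0.2)))
  coh <- generate_structural_cohort(sp)
  mask <- coh$ground_truth$effect_masks[[1]]
  expect_gt(mean(mask), 0.02)
  Y <- vapply(coh$subjects, function(s)
    asymmetry_index(s$thickness_left,
                    mirror_metric(s$thickness_right, coh$mesh))$values,
    numeric(coh$mesh$V))
  mbar <- mean(Y[mask, ])
  se <- sd(colMeans(Y[mask, , drop = FALSE])) / sqrt(ncol(Y))
  expect_lt(abs(mbar - 0.2), 3 * se)
  expect_lt(max(abs(rowMeans(Y[!mask, , drop = FALSE]))), 0.05)
  # same seed, same cohort (bitwise)
  c2 <- generate_structural_cohort(sp)
  expect_identical(coh$subjects[[5]]$thickness_right$values,
                   c2$subjects[[5]]$thickness_right$values)
  expect_identical(coh$ground_truth$covariates, c2$ground_truth$covariates)
  expect_error(generate_structural_cohort(
    cohort_spec(2, seed = 1, level = 2,
                effects = list(list(feature = "thickness",
                                    center = c(1, 1, 1), radius_deg = 0.1,
                                    delta = 0.1)))), "empty effect region")
})

test_that("covariate effects modulate the planted asymmetry", {
  sp <- cohort_spec(n_subjects = 60, seed = 33, level = 2,
                    warp_mean_deg = 0, noise_sd = 0,
                    sex_effect = 0.1,
                    effects = list(list(feature = "thickness",
                                        center = c(0, 0, 1),
                                        radius_deg = 30, delta = 0.1)))
  coh <- generate_structural_cohort(sp)
  mask <- coh$ground_truth$effect_masks[[1]]
  sex <- coh$ground_truth$covariates$sex
  ai_mean <- vapply(coh$subjects, function(s)
    mean(asymmetry_index(s$thickness_left,
                         mirror_metric(s$thickness_right,
                                       coh$mesh))$values[mask]), 0)
  expect_equal(mean(ai_mean[sex == 1]) - mean(ai_mean[sex == 0]), 0.1,
               tolerance = 1e-6)
})

test_that("functional cohorts: exact mirrors, amplitude recovery, seeds", {
  sp <- cohort_spec(n_subjects = 2, seed = 41, level = 2,
                    ts = list(n_networks = 3, frames = 60, delta_f = 0,
                              noise_sd = 0))
  coh <- generate_functional_cohort(sp)
  p <- mirror_map(coh$mesh)
  for (s in coh$subjects)
    expect_lt(max(abs(s$ts_left$data - s$ts_right$data[, p])), 1e-10)
  # regression on the known maps recovers the amplitudes exactly
  spl <- cohort_spec(n_subjects = 1, seed = 42, level = 2,
                     ts = list(n_networks = 3, frames = 80, delta_f = 0.3,
                               noise_sd = 0))
  cl <- generate_functional_cohort(spl)
  M <- cl$ground_truth$network_maps
  S <- cl$ground_truth$timecourses[[1]]
  Y <- cl$subjects[[1]]$ts_left$data
  Ahat <- solve(crossprod(S), t(S) %*% Y) %*% t(M) %*% solve(M %*% t(M))
  expect_equal(diag(Ahat), rep(1.3, 3), tolerance = 1e-6)
  c2 <- generate_functional_cohort(spl)
  expect_identical(cl$subjects[[1]]$ts_left$data,
                   c2$subjects[[1]]$ts_left$data)
  expect_error(generate_functional_cohort(
    cohort_spec(1, seed = 1, level = 2,
                ts = list(n_networks = 10, frames = 20))),
    "n_networks")
})
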