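test_that("adaptive kernel weights: normalisation and effective N", {
  expect_error(adaptive_kernel_weights(c(40, 41), 40, 8), "smaller")
  w <- adaptive_kernel_weights(rep(40, 12), 40, 8)
  expect_equal(w, rep(1 / 12, 12))
  set.seed(3)
  for (i in 1:10) {
    ages <- runif(15, 37, 44)
    tw <- sample(37:44, 1)
    w <- adaptive_kernel_weights(ages, tw, 8)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_gte(sum(w)^2 / sum(w^2), 8)
  }
})

test_that("weekly template averaging equals an independent summation", {
  m <- oct3
  set.seed(5)
  mets <- lapply(1:4, function(i) metric_map(rnorm(m$V), "left", "sulc"))
  defs <- replicate(4, identity_deformation(m), simplify = FALSE)
  # identical subjects reproduce any subject
  same <- build_weekly_template(mets[c(1, 1, 1)], defs[1:3], m)
  expect_equal(same$values, mets[[1]]$values, tolerance = 1e-10)
  # two equal-weight subjects give the arithmetic mean
  two <- build_weekly_template(mets[1:2], defs[1:2], m)
  expect_equal(two$values, (mets[[1]]$values + mets[[2]]$values) / 2,
               tolerance = 1e-12)
  # weighted mean equals a reordered direct summation
  wts <- c(0.1, 0.4, 0.2, 0.3)
  got <- build_weekly_template(mets, defs, m, weights = wts)
  direct <- Reduce(`+`, Map(function(mm, w) w * mm$values,
                            rev(mets), rev(wts)))
  expect_equal(got$values, direct, tolerance = 1e-12)
})

test_that("dedrift removes a planted common rotation", {
  m <- oct3
  rot <- rotation_deformation(m, c(0, 0, 1), 8, "a", "a")
  originals <- lapply(1:5, function(i) smooth_warp(m, 20 + i, 0.02,
                                                   spaces = c("a", "a")))
  drifted <- lapply(originals, function(d) compose_deformations(d, rot))
  out <- dedrift(drifted)
  avg <- average_deformations(out)
  expect_lt(mean_geo(avg$targets, m$vertices), 1e-3)
  # all-identity input stays the identity
  ids <- replicate(3, identity_deformation(m, "a"), simplify = FALSE)
  out0 <- dedrift(ids)
  for (d in out0) expect_lt(max_chord(d$targets, m$vertices), 1e-9)
})

test_that("template refinement reduces within-template variance", {
  m <- oct3
  set.seed(6)
  pat <- generate_template_pattern(m, 55)
  cohort <- lapply(1:8, function(i) {
    w <- smooth_warp(m, 60 + i, 0.06, spaces = c("native", "native"))
    list(sulc = resample_metric(pat, w, m), age_weeks = 40)
  })
  ref <- refine_atlas(cohort, m, weeks = 40, max_iter = 2,
                      min_effective_n = 8)
  expect_lte(length(ref$variance), 4)
  expect_true(all(diff(ref$variance) <= 1e-6))
  expect_lt(tail(ref$variance, 1), 0.5 * ref$variance[1])
  # zero-noise identity cohort converges immediately
  cohort0 <- lapply(1:8, function(i) list(sulc = pat, age_weeks = 40))
  ref0 <- refine_atlas(cohort0, m, weeks = 40, max_iter = 3,
                       min_effective_n = 8)
  expect_lt(ref0$variance[1], 1e-20)
})

test_that("symmetrize_template enforces the mirror invariant exactly", {
  m <- oct3
  p <- mirror_map(m)
  base <- generate_template_pattern(m, 21)
  pert <- generate_template_pattern(m, 22)
  L <- metric_map(base$values, "left", "sulc")
  R <- metric_map(base$values[p] + 0.15 * pert$values[p], "right", "sulc")
  sy <- symmetrize_template(template(40, m, left = list(sulc = L),
                                     right = list(sulc = R)))
  s <- sy$template$metrics$sulc
  expect_lte(max(abs(s$values - s$values[p])), 1e-10)
  expect_true(sy$template$symmetric)
  # already-symmetric input is a fixed point: halfway fields near identity,
  # metrics preserved, and re-symmetrising changes nothing
  tpl2 <- template(40, m,
                   left = list(sulc = metric_map(s$values, "left", "sulc")),
                   right = list(sulc = metric_map(s$values[p], "right",
                                                  "sulc")))
  sy2 <- symmetrize_template(tpl2)
  expect_lt(mean_geo(sy2$d_half_L$targets, m$vertices), 1e-3)
  expect_lt(max(abs(sy2$template$metrics$sulc$values - s$values)), 0.02)
})

test_that("template chain composes to the reference week", {
  m <- oct3
  p <- mirror_map(m)
  set.seed(8)
  pat1 <- generate_template_pattern(m, 31)
  pat2 <- generate_template_pattern(m, 32)
  tpls <- list()
  for (w in 39:41) {
    a <- (w - 28) / 16
    v <- (1 - a) * pat1$values + a * pat2$values
    tpls[[as.character(w)]] <- metric_map((v + v[p]) / 2, "symmetric",
                                          "sulc")
  }
  ch <- build_template_chain(tpls, m, reference = 40)
  expect_lt(max_geo(ch$to40[["40"]]$targets, m$vertices), 1e-7)
  expect_setequal(names(ch$chain), c("39->40", "41->40"))
  expect_error(build_template_chain(tpls[c("39", "41")], m, reference = 39),
               "missing")
  # identical weekly templates give near-identity links
  same <- list(`39` = tpls[["40"]], `40` = tpls[["40"]])
  ch0 <- build_template_chain(same, m, reference = 40)
  expect_lt(max_geo(ch0$to40[["39"]]$targets, m$vertices), 1e-3)
  # planted-warp subject: one-step resampling recovers the template
  w <- rotation_deformation(m, c(0, 1, 0), 6, "native", "native")
  subj <- list(sulc = resample_metric(tpls[["40"]], w, m), age_weeks = 40.2)
  d <- subject_to_template(subj, tpls, ch, m)
  res <- resample_metric(subj$sulc, d, m)
  expect_gte(cor(res$values, tpls[["40"]]$values), 0.98)
})

test_that("single interpolation beats double interpolation", {
  # analytic ground truth: a quadratic field pulled back through two
  # rotations, for which the composed map is known in closed form
  m <- oct3
  f <- function(v) v[, 1] * v[, 2] + 0.5 * v[, 3]
  pat <- metric_map(f(m$vertices), "left", "q")
  w1 <- rotation_deformation(m, c(0, 1, 2), 17, "b", "native")
  w2 <- rotation_deformation(m, c(1, 0, 0), 23, "tpl", "b")
  R1 <- hemisym:::rotation_matrix(c(0, 1, 2), 17 * pi / 180)
  R2 <- hemisym:::rotation_matrix(c(1, 0, 0), 23 * pi / 180)
  truth <- f(m$vertices %*% t(R2) %*% t(R1))
  one <- resample_metric(pat, compose_deformations(w2, w1), m)
  two <- resample_metric(resample_metric(pat, w1, m), w2, m)
  expect_lt(mean((one$values - truth)^2), mean((two$values - truth)^2))
})
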