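test_that("barycentric resampling: identity, linear reproduction, rotation", {
  m <- oct3
  set.seed(1)
  pat <- generate_template_pattern(m, 3)
  idd <- identity_deformation(m)
  expect_identical(resample_metric(pat, idd, m)$values, pat$values)
  # linear field is reproduced exactly at the interpolated point defined by
  # the (nonnegative, sum-1) weights
  d <- smooth_warp(m, 4, 0.05, spaces = c("b", "a"))
  loc <- hemisym:::locate_on_mesh(m, d$targets)
  expect_true(all(loc$weights >= -1e-12))
  expect_lt(max(abs(rowSums(loc$weights) - 1)), 1e-12)
  a <- c(0.3, -1.2, 0.7)
  lin <- metric_map(as.numeric(m$vertices %*% a), "left", "lin")
  out <- resample_metric(lin, d, m)
  pts <- hemisym:::interp_values(m$vertices, loc)
  expect_lt(max(abs(out$values - as.numeric(pts %*% a))), 1e-12)
  # 90 degree rotation about z maps octasphere vertices onto vertices:
  # resampling f(v) = v_x through it gives a +/- v_y pattern exactly
  # R90 about z maps (x, y, z) to (-y, x, z), so f(Rv) = -v_y
  r90 <- rotation_deformation(m, c(0, 0, 1), 90)
  fx <- metric_map(m$vertices[, 1], "left", "x")
  got <- resample_metric(fx, r90, m)$values
  expect_lt(max(abs(got + m$vertices[, 2])), 1e-10)
})

test_that("composition obeys the rotation-group oracle and identity law", {
  m <- oct3
  d <- smooth_warp(m, 5, 0.04, spaces = c("a", "a"))
  idd <- identity_deformation(m, "a")
  expect_lt(max_chord(compose_deformations(d, idd)$targets, d$targets),
            1e-10)
  # 90 + 90 = 180 about z is exact on the octasphere lattice
  r90 <- rotation_deformation(m, c(0, 0, 1), 90, "a", "a")
  r180 <- rotation_deformation(m, c(0, 0, 1), 180, "a", "a")
  expect_lt(max_chord(compose_deformations(r90, r90)$targets,
                      r180$targets), 1e-8)
  # generic angles: interpolation-order accuracy on a fine mesh
  m5 <- make_octasphere(5)
  ra <- rotation_deformation(m5, c(0, 0, 1), 10, "a", "a")
  rb <- rotation_deformation(m5, c(0, 0, 1), 15, "a", "a")
  rc <- rotation_deformation(m5, c(0, 0, 1), 25, "a", "a")
  expect_lt(max_chord(compose_deformations(ra, rb)$targets, rc$targets),
            1e-8)
  expect_error(compose_deformations(
    smooth_warp(m, 1, 0.01, spaces = c("a", "b")),
    smooth_warp(m, 2, 0.01, spaces = c("c", "d"))), "defined on")
})

test_that("composition is associative in the small-warp regime", {
  m <- oct3
  for (i in 1:10) {
    d1 <- smooth_warp(m, i, 3e-5, c(1, 2), c("a", "a"))
    d2 <- smooth_warp(m, i + 100, 3e-5, c(1, 3), c("a", "a"))
    d3 <- smooth_warp(m, i + 200, 3e-5, c(2, 3), c("a", "a"))
    lhs <- compose_deformations(compose_deformations(d1, d2), d3)
    rhs <- compose_deformations(d1, compose_deformations(d2, d3))
    expect_lt(max_chord(lhs$targets, rhs$targets), 1e-8)
  }
})

test_that("inversion: identity, lattice rotations, defining property", {
  m4 <- make_octasphere(4)
  idd <- identity_deformation(m4)
  expect_lt(max_chord(invert_deformation(idd)$targets, m4$vertices), 1e-12)
  # lattice-preserving rotation inverts exactly
  r90 <- rotation_deformation(m4, c(0, 0, 1), 90, "a", "b")
  rm90 <- rotation_deformation(m4, c(0, 0, 1), -90, "b", "a")
  expect_lt(max_chord(invert_deformation(r90)$targets, rm90$targets), 1e-8)
  # generic rotation: interpolation-order accuracy
  r10 <- rotation_deformation(m4, c(0.3, 1, 0.2), 10, "a", "b")
  rt <- rotation_deformation(m4, c(0.3, 1, 0.2), -10, "b", "a")
  expect_lt(max_geo(invert_deformation(r10)$targets, rt$targets), 1e-3)
  # compose(d, invert(d)) stays within 1e-3 radians of the identity for
  # small smooth warps
  for (i in 1:8) {
    d <- smooth_warp(m4, i, 0.015, c(1, 2), c("a", "b"))
    dd <- compose_deformations(d, invert_deformation(d))
    expect_lt(max_geo(dd$targets, m4$vertices), 1e-3)
  }
})

test_that("deformation averaging: fixed points and symmetric rotations", {
  m <- oct3
  d <- smooth_warp(m, 9, 0.05)
  same <- average_deformations(list(d, d, d))
  expect_lt(max_chord(same$targets, d$targets), 1e-14)
  expect_lt(max_chord(average_deformations(list(d,
    smooth_warp(m, 10, 0.05)), weights = c(1, 0))$targets, d$targets),
    1e-14)
  # averaging R+theta with R-theta cancels the rotation to first order;
  # the residual is the second-order tilt (1 - cos theta) of chordal
  # averaging, bounded by theta^2 / 2
  errs <- vapply(c(5, 20), function(th) {
    rp <- rotation_deformation(m, c(0, 1, 0), th, "a", "a")
    rn <- rotation_deformation(m, c(0, 1, 0), -th, "a", "a")
    avg <- average_deformations(list(rp, rn))
    e <- max_chord(avg$targets, m$vertices)
    expect_lt(e, (th * pi / 180)^2 / 2)
    e
  }, 0)
  expect_equal(errs[2] / errs[1], 16, tolerance = 0.05)
  anti <- deformation_field(-m$vertices, m, "a", "a", check_folds = FALSE)
  expect_error(average_deformations(list(d, anti)), "antipodal")
})

test_that("group-law property suite holds over many random smooth warps", {
  m <- oct3
  idd <- identity_deformation(m, "a")
  for (i in 1:100) {
    d <- smooth_warp(m, 1000 + i, 0.03, c(1, 2), c("a", "a"))
    expect_false(any(hemisym:::folded_triangles(d)))
    expect_lt(max_chord(compose_deformations(d, idd)$targets, d$targets),
              1e-10)
    expect_lt(max_chord(compose_deformations(idd, d)$targets, d$targets),
              1e-10)
  }
})

test_that("registration: perfect match, descent, fold-free output", {
  m <- oct3
  set.seed(1)
  pat <- generate_template_pattern(m, 7)
  reg0 <- register_spherical(pat, pat, m)
  expect_lt(max_geo(reg0$targets, m$vertices), 1e-3)
  # planted rotation at level 3: data term decreases, no folds
  w <- rotation_deformation(m, c(1, 0.5, 0), 5, "g", "g")
  moving <- resample_metric(pat, w, m)
  reg <- register_spherical(moving, pat, m)
  expect_false(any(hemisym:::folded_triangles(reg)))
  fit0 <- mean((moving$values - pat$values)^2)
  fit1 <- mean((resample_metric(moving, reg, m)$values - pat$values)^2)
  expect_lt(fit1, fit0)
})

test_that("mirror operations: involution, odd and even fields", {
  m <- oct3
  p <- mirror_map(m)
  fx <- metric_map(m$vertices[, 1], "left", "x")
  fy <- metric_map(m$vertices[, 2], "left", "y")
  expect_identical(mirror_metric(fx, m)$values, -fx$values)
  expect_identical(mirror_metric(fy, m)$values, fy$values)
  expect_identical(mirror_metric(mirror_metric(fx, m), m)$values, fx$values)
  expect_identical(mirror_metric(fx, m)$hemisphere, "right")
  nom <- spherical_mesh(oct2$vertices, oct2$triangles)
  expect_error(mirror_map(nom), "symmetric mesh")
})
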