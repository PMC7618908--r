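# shared fixtures: small octaspheres and reproducible smooth warps

oct2 <- make_octasphere(2)
oct3 <- make_octasphere(3)

# sphere of radius r as an anatomical surface on `mesh`
sphere_surface <- function(mesh, r, role = "white") {
  anatomical_surface(mesh$vertices * r, mesh, role)
}

# random smooth fold-free warp field on `mesh` (uses the generator's own
# tangent-field machinery; seeded for reproducibility)
smooth_warp <- function(mesh, seed, mean_rad = 0.02, band = c(1, 2),
                        spaces = c("a", "b")) {
  set.seed(seed)
  t <- hemisym:::random_warp_targets(mesh, band, mean_rad)
  deformation_field(t, mesh, spaces[1], spaces[2], check_folds = FALSE)
}

# frozen analytic helpers; chordal distance is used for tight (<= 1e-8)
# assertions because acos() has a ~2e-8 floor near zero
max_geo <- function(a, b) max(geodesic_distance(a, b))
mean_geo <- function(a, b) mean(geodesic_distance(a, b))
max_chord <- function(a, b) max(sqrt(rowSums((a - b)^2)))
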