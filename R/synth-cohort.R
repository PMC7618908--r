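#' Cohort specification for the synthetic generator
#'
#' Describes a synthetic neonatal-style cohort on an octasphere: weekly age
#' structure, sulcal-depth-like template fields, subject-specific smooth
#' spherical warps, planted lateralised effects in geodesic-cap regions,
#' covariate effects, metric noise, and (optionally) network-structured
#' timeseries with lateralised amplitude.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed (mandatory; the whole cohort is a deterministic
#'   function of the spec).
#' @param level octasphere subdivision level (default 3).
#' @param age_range age range in weeks (default 37 to 44, term-equivalent).
#' @param effects list of planted asymmetries, each
#'   `list(feature, center, radius_deg, delta)`: inside the geodesic cap the
#'   true asymmetry index equals `delta` (leftward positive).
#' @param sex_effect,age_slope additive modulation of the planted delta by
#'   covariates (per unit sex indicator / per week of PMA minus 40).
#' @param warp_mean_deg mean geodesic displacement of the subject warps in
#'   degrees (default 3; 0 disables warping).
#' @param warp_band spherical-harmonic band of the warps (default 1 to 2).
#' @param noise_sd Gaussian metric noise standard deviation (default 0.05,
#'   in the metric's own units).
#' @param ts optional timeseries spec:
#'   `list(n_networks, frames, delta_f, noise_sd, radius_deg)`.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed, level = 3,
                        age_range = c(37, 44), effects = list(),
                        sex_effect = 0, age_slope = 0,
                        warp_mean_deg = 3, warp_band = c(1, 2),
                        noise_sd = 0.05, ts = NULL) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory")
  stopifnot(n_subjects >= 1, is.finite(noise_sd), is.finite(warp_mean_deg))
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 level = level, age_range = age_range, effects = effects,
                 sex_effect = sex_effect, age_slope = age_slope,
                 warp_mean_deg = warp_mean_deg, warp_band = warp_band,
                 noise_sd = noise_sd, ts = ts),
            class = "cohort_spec")
}

#' Geodesic cap mask
#'
#' @param mesh `spherical_mesh`; `center` direction; `radius_deg` angular
#'   radius in degrees.
#' @return logical vertex mask.
#' @export
cap_mask <- function(mesh, center, radius_deg) {
  center <- center / sqrt(sum(center^2))
  as.numeric(mesh$vertices %*% center) >= cos(radius_deg * pi / 180)
}

# random smooth tangent warp field; returns targets (or NULL if folded)
random_warp_targets <- function(mesh, band, mean_rad) {
  if (mean_rad == 0) return(mesh$vertices)
  co <- matrix(stats::rnorm(3 * n_band_coefs(band)), ncol = 3)
  u <- vapply(1:3, function(k)
    band_limited_field(mesh$vertices, band, co[, k]),
    numeric(mesh$V))
  u <- u - rowSums(u * mesh$vertices) * mesh$vertices
  u <- u * (mean_rad / mean(sqrt(rowSums(u^2))))
  for (shrink in seq_len(20)) {
    t <- mesh$vertices + u
    t <- t / sqrt(rowSums(t^2))
    if (!any(folded_triangles(list(targets = t, mesh = mesh)))) return(t)
    u <- 0.8 * u
  }
  mesh$vertices
}

#' Generate a structural synthetic cohort with planted asymmetries
#'
#' For each subject, the left sulcal depth map is the age-interpolated
#' template warped by a subject-specific smooth deformation plus Gaussian
#' noise; thickness-like feature maps get the planted asymmetry: inside
#' each effect cap the right map is scaled by `(2 - d) / (2 + d)` relative
#' to the mirrored left map, so the true asymmetry index equals
#' `d = delta + sex_effect * sex + age_slope * (pma - 40)` there and 0
#' elsewhere. The right hemisphere is stored in its own (mirrored) frame
#' and is warped and noised independently of the left. Covariates are drawn
#' from distributions patterned on a term neonatal cohort.
#'
#' @param spec `cohort_spec`.
#' @return list with `mesh`, `subjects` (each: `sulc_left`, `sulc_right`,
#'   `thickness_left`, `thickness_right`, `age_weeks`, `covariates`,
#'   surfaces) and `ground_truth` (true warps, per-subject true AI fields,
#'   covariate table, effect masks).
#' @export
generate_structural_cohort <- function(spec) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  mesh <- make_octasphere(spec$level)
  p <- mirror_map(mesh)
  # two anchor patterns define the age evolution by linear interpolation
  co1 <- stats::rnorm(n_band_coefs(c(3, 8)))
  co2 <- stats::rnorm(n_band_coefs(c(3, 8)))
  pat1 <- band_limited_field(mesh$vertices, c(3, 8), co1)
  pat2 <- band_limited_field(mesh$vertices, c(3, 8), co2)
  co_th <- stats::rnorm(n_band_coefs(c(3, 8)))
  pat_th <- band_limited_field(mesh$vertices, c(3, 8), co_th)
  masks <- lapply(spec$effects, function(e) {
    mk <- cap_mask(mesh, e$center, e$radius_deg)
    if (!any(mk)) stop("generate_structural_cohort: empty effect region")
    mk
  })
  n <- spec$n_subjects
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  cov <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    ga_weeks = stats::runif(n, 37, 42),
    pma_weeks = ages,
    sex = sex,
    bwz = stats::rnorm(n),
    tbv_cm3 = stats::rnorm(n, 340, 30),
    hemi_vol_asym_cm3 = stats::rnorm(n, -1.8, 1.5))
  subjects <- list()
  truth <- list(warps_left = list(), warps_right = list(), true_ai = list())
  wrad <- spec$warp_mean_deg * pi / 180
  for (s in seq_len(n)) {
    alpha <- (ages[s] - 28) / (44 - 28)
    sulc_tpl <- (1 - alpha) * pat1 + alpha * pat2
    thick_tpl <- 2 + 0.25 * pat_th          # mm, positive
    # per-subject true asymmetry field (on the template grid, left frame)
    dtrue <- numeric(mesh$V)
    for (k in seq_along(masks)) {
      e <- spec$effects[[k]]
      d <- e$delta + spec$sex_effect * sex[s] +
        spec$age_slope * (ages[s] - 40)
      dtrue[masks[[k]]] <- d
    }
    thick_left_true <- thick_tpl
    thick_right_true <- thick_tpl * (2 - dtrue) / (2 + dtrue)
    wl <- random_warp_targets(mesh, spec$warp_band, wrad)
    wr <- random_warp_targets(mesh, spec$warp_band, wrad)
    dl <- deformation_field(wl, mesh, "native_L", "template",
                            check_folds = FALSE)
    dr <- deformation_field(wr, mesh, "native_R", "template",
                            check_folds = FALSE)
    noise <- function(sd) stats::rnorm(mesh$V, 0, sd)
    sulc_L <- resample_metric(metric_map(sulc_tpl, "left", "sulc"),
                              dl, mesh)$values + noise(spec$noise_sd)
    th_L <- resample_metric(metric_map(thick_left_true, "left", "thickness"),
                            dl, mesh)$values + noise(spec$noise_sd)
    # right maps: mirrored truth, independently warped/noised, right frame
    sulc_R <- resample_metric(metric_map(sulc_tpl[p], "right", "sulc"),
                              dr, mesh)$values + noise(spec$noise_sd)
    th_R <- resample_metric(
      metric_map(thick_right_true[p], "right", "thickness"),
      dr, mesh)$values + noise(spec$noise_sd)
    # anatomical geometry: white at radius 50 mm modulated by sulcal depth,
    # pial one thickness further out along the radius
    r_white <- 50 + 2 * sulc_L
    white_L <- anatomical_surface(mesh$vertices * r_white, mesh, "white")
    pial_L <- anatomical_surface(mesh$vertices * (r_white + th_L), mesh,
                                 "pial")
    mid_L <- anatomical_surface(mesh$vertices * (r_white + th_L / 2), mesh,
                                "midthickness")
    # right-frame geometry uses the same spherical directions; the mirror
    # correspondence is carried entirely by the mesh's mirror permutation
    r_white_R <- 50 + 2 * sulc_R
    white_R <- anatomical_surface(mesh$vertices * r_white_R, mesh, "white")
    pial_R <- anatomical_surface(mesh$vertices * (r_white_R + th_R), mesh,
                                 "pial")
    mid_R <- anatomical_surface(mesh$vertices * (r_white_R + th_R / 2),
                                mesh, "midthickness")
    subjects[[s]] <- list(
      subject_id = cov$subject_id[s], age_weeks = ages[s],
      sulc_left = metric_map(sulc_L, "left", "sulc"),
      sulc_right = metric_map(sulc_R, "right", "sulc"),
      thickness_left = metric_map(th_L, "left", "thickness"),
      thickness_right = metric_map(th_R, "right", "thickness"),
      white_left = white_L, pial_left = pial_L, mid_left = mid_L,
      white_right = white_R, pial_right = pial_R, mid_right = mid_R,
      covariates = cov[s, ])
    truth$warps_left[[s]] <- wl
    truth$warps_right[[s]] <- wr
    truth$true_ai[[s]] <- dtrue
  }
  truth$covariates <- cov
  truth$effect_masks <- masks
  truth$templates <- list(sulc_28 = pat1, sulc_44 = pat2,
                          thickness = 2 + 0.25 * pat_th)
  list(mesh = mesh, subjects = subjects, ground_truth = truth, spec = spec)
}

#' Generate a functional synthetic cohort
#'
#' Per subject and hemisphere, the timeseries is
#' `Y = sum_k a_k s_k(t) m_k(v) + noise`, where the network maps `m_k` are
#' geodesic Gaussian bumps at mirror-symmetric locations (the same
#' left-frame field serves both hemispheres; the right hemisphere's copy is
#' index-mirrored into its own frame), `s_k` are unit-variance Gaussian
#' timecourses shared across hemispheres, and the left amplitude of
#' lateralised networks is `(1 + delta_f)` times the right amplitude.
#'
#' @param spec `cohort_spec` with a `ts` component: `n_networks` (default
#'   4), `frames` (default 200), `delta_f` (amplitude lateralisation,
#'   default 0), `noise_sd` (default 0.3), `radius_deg` (bump radius,
#'   default 14), `lateralised` (indices of lateralised networks, default
#'   all).
#' @return list with `mesh`, `subjects` (each: `ts_left`, `ts_right`
#'   `timeseries_matrix` in each hemisphere's own frame), and
#'   `ground_truth` (`network_maps` (k x V, left frame), `amplitudes`,
#'   `timecourses`, `delta_f`).
#' @export
generate_functional_cohort <- function(spec) {
  ts <- spec$ts %||% list()
  K <- ts$n_networks %||% 4
  frames <- ts$frames %||% 200
  delta_f <- ts$delta_f %||% 0
  nsd <- ts$noise_sd %||% 0.3
  radius <- ts$radius_deg %||% 14
  lateralised <- ts$lateralised %||% seq_len(K)
  if (K > frames / 4)
    stop("generate_functional_cohort: n_networks > frames / 4")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  mesh <- make_octasphere(spec$level)
  p <- mirror_map(mesh)
  # well-separated bump centres: greedy farthest-point selection from a
  # seeded random pool, treating each centre and its mirror image as one
  # site so the bilateral maps do not overlap
  pool <- matrix(stats::rnorm(3 * 200), ncol = 3)
  pool <- pool / sqrt(rowSums(pool^2))
  refl <- function(x) { x[1] <- -x[1]; x }
  centres <- pool[1, , drop = FALSE]
  while (nrow(centres) < K) {
    sites <- rbind(centres, t(apply(centres, 1, refl)))
    dist <- apply(pool %*% t(sites), 1, max)
    centres <- rbind(centres, pool[which.min(dist), ])
  }
  sig <- radius * pi / 180
  bump <- function(c0) {
    ang <- geodesic_distance(mesh$vertices,
                             matrix(c0, mesh$V, 3, byrow = TRUE))
    exp(-ang^2 / (2 * sig^2))
  }
  # bilateral, mirror-symmetric network maps on the shared mesh
  M <- t(vapply(seq_len(K), function(k)
    bump(centres[k, ]) + bump(refl(centres[k, ])),
    numeric(mesh$V)))                      # K x V, symmetric
  n <- spec$n_subjects
  subjects <- list()
  amps <- array(1, c(n, K, 2), dimnames = list(NULL, NULL, c("L", "R")))
  amps[, lateralised, "L"] <- 1 + delta_f
  tcs <- list()
  for (s in seq_len(n)) {
    S <- matrix(stats::rnorm(frames * K), frames, K)
    S <- scale(S)
    YL <- S %*% (amps[s, , "L"] * M) +
      matrix(stats::rnorm(frames * mesh$V, 0, nsd), frames)
    YR <- S %*% (amps[s, , "R"] * M[, p, drop = FALSE]) +
      matrix(stats::rnorm(frames * mesh$V, 0, nsd), frames)
    subjects[[s]] <- list(
      subject_id = sprintf("sub-%03d", s),
      ts_left = timeseries_matrix(YL, "left", sprintf("sub-%03d", s)),
      ts_right = timeseries_matrix(YR, "right", sprintf("sub-%03d", s)))
    tcs[[s]] <- S
  }
  list(mesh = mesh, subjects = subjects,
       ground_truth = list(network_maps = M, amplitudes = amps,
                           timecourses = tcs, delta_f = delta_f,
                           lateralised = lateralised),
       spec = spec)
}
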