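#' Weekly template objects and the symmetric spatiotemporal atlas
#'
#' A `template` bundles the per-vertex metric maps describing the population
#' average cortex at one postmenstrual week. Before symmetrisation it holds
#' separate `left` and `right` hemispheric map lists; after
#' [symmetrize_template()] it holds a single `metrics` list in which every
#' map equals its own mirror (the shared mesh's mirror permutation) to
#' 1e-10, so one map serves both hemispheres.
#'
#' @param age_weeks integer postmenstrual age in weeks.
#' @param mesh shared `spherical_mesh` (mirror permutation required for
#'   symmetrisation).
#' @param left,right named lists of `metric_map`s (must include `sulc`).
#' @param metrics named list of symmetric maps (for symmetric templates).
#' @param symmetric logical flag; validated against the mirror invariant.
#' @return object of class `template`.
#' @export
template <- function(age_weeks, mesh, left = NULL, right = NULL,
                     metrics = NULL, symmetric = FALSE) {
  t <- structure(list(age_weeks = as.integer(age_weeks), mesh = mesh,
                      left = left, right = right, metrics = metrics,
                      symmetric = symmetric),
                 class = "template")
  if (symmetric) {
    stopifnot(!is.null(metrics))
    for (nm in names(metrics)) {
      mm <- mirror_metric(metrics[[nm]], mesh)
      if (max(abs(mm$values - metrics[[nm]]$values)) > 1e-10)
        stop("template: metric '", nm, "' violates the mirror invariant")
    }
  }
  t
}

#' Adaptive-kernel age weights for weekly template averaging
#'
#' Gaussian weights in age whose kernel width is grown until the effective
#' sample size `(sum w)^2 / sum w^2` reaches `min_effective_n`, so sparsely
#' sampled weeks borrow strength from neighbouring ages. Weights sum to one.
#'
#' @param subject_ages numeric vector of ages (weeks).
#' @param target_week target template age (weeks).
#' @param min_effective_n minimum effective sample size (default 8).
#' @return numeric weight vector summing to 1.
#' @export
adaptive_kernel_weights <- function(subject_ages, target_week,
                                    min_effective_n = 8) {
  n <- length(subject_ages)
  if (n < min_effective_n)
    stop("adaptive_kernel_weights: cohort of ", n,
         " is smaller than min_effective_n = ", min_effective_n)
  h <- 0.25
  repeat {
    w <- exp(-(subject_ages - target_week)^2 / (2 * h^2))
    sw <- sum(w)
    if (sw > 0 && sw^2 / sum(w^2) >= min_effective_n) break
    h <- h * 1.25
    if (h > 1e4) stop("adaptive_kernel_weights: kernel width diverged")
  }
  w / sum(w)
}

#' Build one weekly template by weighted averaging of resampled metrics
#'
#' Each subject's metric is pulled onto the template grid through its
#' deformation (one interpolation) and the per-vertex weighted mean is
#' taken.
#'
#' @param metrics list (one per subject) of `metric_map`s in native space.
#' @param deformations list of `deformation_field`s pulling each subject
#'   onto the template grid (identity fields for already-aligned data).
#' @param mesh template `spherical_mesh`.
#' @param weights subject weights (default uniform; normalised).
#' @param age_weeks template age.
#' @return `metric_map` of the weighted template average.
#' @export
build_weekly_template <- function(metrics, deformations, mesh,
                                  weights = NULL, age_weeks = NA) {
  n <- length(metrics)
  stopifnot(n >= 1, length(deformations) == n)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / sum(weights)
  acc <- numeric(mesh$V)
  for (s in seq_len(n)) {
    r <- resample_metric(metrics[[s]], deformations[[s]], mesh)
    acc <- acc + weights[s] * r$values
  }
  metric_map(acc, metrics[[1]]$hemisphere, metrics[[1]]$feature)
}

#' Iterative template refinement
#'
#' Alternates (a) registration of every subject's sulcal depth map to its
#' nearest weekly template and (b) rebuilding the weekly templates from the
#' resampled maps with adaptive-kernel age weights, until the relative
#' change of the mean within-template variance falls below `tol` or
#' `max_iter` is reached. The variance trajectory is returned; a variance
#' increase beyond tolerance on two consecutive iterations is an error.
#'
#' @param cohort list of subjects, each a list with `sulc` (`metric_map` in
#'   native space) and `age_weeks`.
#' @param mesh template `spherical_mesh`.
#' @param weeks integer vector of template weeks (default range of ages).
#' @param max_iter,tol convergence controls (defaults 10 and 1e-3).
#' @param min_effective_n passed to [adaptive_kernel_weights()].
#' @param reg_params passed to [register_spherical()].
#' @return list with `templates` (named list of `metric_map` per week),
#'   `deformations` (per subject), `variance` trajectory, `weeks`.
#' @export
refine_atlas <- function(cohort, mesh, weeks = NULL, max_iter = 10,
                         tol = 1e-3, min_effective_n = 8,
                         reg_params = list()) {
  ages <- vapply(cohort, function(s) as.numeric(s$age_weeks), 0)
  if (is.null(weeks)) weeks <- seq(round(min(ages)), round(max(ages)))
  nearest <- weeks[apply(abs(outer(ages, weeks, "-")), 1, which.min)]
  n <- length(cohort)
  defs <- replicate(n, identity_deformation(mesh, "native"),
                    simplify = FALSE)
  templates <- NULL
  variance <- numeric(0)
  for (it in seq_len(max_iter + 1)) {
    resampled <- lapply(seq_len(n), function(s)
      resample_metric(cohort[[s]]$sulc, defs[[s]], mesh)$values)
    R <- do.call(cbind, resampled)
    templates <- list()
    vsum <- 0
    for (w in weeks) {
      wt <- adaptive_kernel_weights(ages, w, min_effective_n)
      mu <- as.numeric(R %*% wt)
      templates[[as.character(w)]] <- metric_map(mu, "left", "sulc")
      dv <- sweep(R, 1, mu)
      vsum <- vsum + mean(as.numeric(dv^2 %*% wt))
    }
    variance <- c(variance, vsum / length(weeks))
    k <- length(variance)
    if (k >= 3 && variance[k] > variance[k - 1] + 1e-6 &&
        variance[k - 1] > variance[k - 2] + 1e-6)
      stop("refine_atlas: within-template variance increased on two ",
           "consecutive iterations: ",
           paste(format(variance), collapse = ", "))
    if (k >= 2 &&
        abs(variance[k] - variance[k - 1]) < tol * variance[k - 1])
      break
    if (it > max_iter) break
    for (s in seq_len(n)) {
      fixed <- templates[[as.character(nearest[s])]]
      defs[[s]] <- register_spherical(cohort[[s]]$sulc, fixed, mesh,
                                      reg_params)
      defs[[s]]$source_space <- "template"
      defs[[s]]$target_space <- "native"
    }
  }
  list(templates = templates, deformations = defs, variance = variance,
       weeks = weeks, assigned_week = nearest)
}

#' Remove the common drift from an ensemble of deformation fields
#'
#' Composes every field with the inverse of the ensemble average, so the
#' average of the returned fields is the identity (within 1e-3 radians) and
#' the template space is unbiased towards any input.
#'
#' @param deformations list of `deformation_field`s sharing grid and spaces.
#' @return list of dedrifted `deformation_field`s.
#' @export
dedrift <- function(deformations) {
  avg <- average_deformations(deformations)
  inv <- invert_deformation(avg)
  inv$source_space <- deformations[[1]]$source_space
  inv$target_space <- deformations[[1]]$source_space
  lapply(deformations, function(d) compose_deformations(inv, d))
}

#' Symmetrise a weekly template across hemispheres
#'
#' Registers the left sulcal depth map to the mirrored right map in both
#' directions, forms the consensus left-to-right warp as the average of the
#' forward warp and the inverse of the backward warp, and takes its halfway
#' interpolation to define the intermediate (halfway) space. Both
#' hemispheres' metrics are resampled into the halfway space, averaged, and
#' finally averaged over the mirror orbit, which enforces the mirror
#' invariant exactly. The two returned fields pull the left-frame and the
#' (mirrored) right-frame data into the halfway space.
#'
#' @param tpl `template` with `left` and `right` map lists (sulc required).
#' @param reg_params passed to the two directional registrations.
#' @return list with `template` (symmetric), `d_half_L`, `d_half_R`.
#' @export
symmetrize_template <- function(tpl, reg_params = list()) {
  mesh <- tpl$mesh
  if (is.null(tpl$left$sulc) || is.null(tpl$right$sulc))
    stop("symmetrize_template: template lacks left/right sulc maps")
  L <- tpl$left$sulc
  mR <- mirror_metric(tpl$right$sulc, mesh)
  rp <- reg_params
  rp$symmetric <- FALSE
  c1 <- register_directional(L, mR, mesh, rp)   # map mR-frame -> L-frame
  c2 <- register_directional(mR, L, mesh, rp)   # map L-frame -> mR-frame
  c1i <- invert_deformation(c1)
  c1i$source_space <- c2$source_space
  c1i$target_space <- c2$target_space
  M <- average_deformations(list(c1i, c2))      # consensus L -> mR map
  idf <- identity_deformation(mesh)
  idf$source_space <- M$source_space
  idf$target_space <- M$target_space
  Mhalf <- average_deformations(list(M, idf))   # L-frame -> halfway
  d_half_L <- invert_deformation(Mhalf)         # pulls L data to halfway
  Mi <- invert_deformation(M)
  Mi$source_space <- idf$source_space
  Mi$target_space <- idf$target_space
  Nhalf <- average_deformations(list(Mi, idf))  # mR-frame -> halfway
  d_half_R <- invert_deformation(Nhalf)         # pulls mirrored-R to halfway
  feats <- union(names(tpl$left), names(tpl$right))
  metrics <- list()
  for (nm in feats) {
    lh <- resample_metric(tpl$left[[nm]], d_half_L, mesh)
    rh <- resample_metric(mirror_metric(tpl$right[[nm]], mesh), d_half_R,
                          mesh)
    s0 <- (lh$values + rh$values) / 2
    s <- (s0 + s0[mirror_map(mesh)]) / 2
    metrics[[nm]] <- metric_map(s, "symmetric", nm)
  }
  list(template = template(tpl$age_weeks, mesh, metrics = metrics,
                           symmetric = TRUE),
       d_half_L = d_half_L, d_half_R = d_half_R)
}

#' Chain weekly templates to the 40-week reference
#'
#' Registers every pair of consecutive weekly templates and composes the
#' links into a single pull-back field per week (`to40`), so subject data
#' can be carried from any local week to the 40-week space in one
#' interpolation. `to40[["40"]]` is the identity.
#'
#' @param templates named list (by week) of symmetric `template`s or
#'   `metric_map`s of sulcal depth.
#' @param mesh shared `spherical_mesh`.
#' @param reference reference week (default 40).
#' @param reg_params passed to [register_spherical()].
#' @return list with `chain` (per consecutive pair) and `to40` (per week).
#' @export
build_template_chain <- function(templates, mesh, reference = 40,
                                 reg_params = list()) {
  weeks <- sort(as.integer(names(templates)))
  if (!(reference %in% weeks))
    stop("build_template_chain: reference week ", reference,
         " missing from templates")
  if (!identical(weeks, seq(min(weeks), max(weeks))))
    stop("build_template_chain: missing week(s): ",
         paste(setdiff(seq(min(weeks), max(weeks)), weeks), collapse = ", "))
  sulc_of <- function(w) {
    t <- templates[[as.character(w)]]
    if (inherits(t, "template")) t$metrics$sulc else t
  }
  chain <- list()
  to40 <- list()
  to40[[as.character(reference)]] <- identity_deformation(mesh, "template")
  for (w in rev(weeks[weeks < reference])) {
    lnk <- register_spherical(sulc_of(w), sulc_of(w + 1), mesh, reg_params)
    lnk$source_space <- "template"
    lnk$target_space <- "template"
    chain[[paste(w, w + 1, sep = "->")]] <- lnk
    to40[[as.character(w)]] <-
      compose_deformations(to40[[as.character(w + 1)]], lnk)
  }
  for (w in weeks[weeks > reference]) {
    lnk <- register_spherical(sulc_of(w), sulc_of(w - 1), mesh, reg_params)
    lnk$source_space <- "template"
    lnk$target_space <- "template"
    chain[[paste(w, w - 1, sep = "->")]] <- lnk
    to40[[as.character(w)]] <-
      compose_deformations(to40[[as.character(w - 1)]], lnk)
  }
  list(chain = chain, to40 = to40, weeks = weeks, reference = reference)
}

#' Map one subject into the 40-week symmetric space
#'
#' Registers the subject's native sulcal depth to its local weekly template
#' and composes with the template chain, so the subject's metrics can be
#' resampled into the reference space with a single interpolation.
#'
#' @param subject list with `sulc` (`metric_map`) and `age_weeks`.
#' @param templates named list of weekly sulc `metric_map`s (or templates).
#' @param chain result of [build_template_chain()].
#' @param mesh shared mesh; `reg_params` passed to registration.
#' @param reg_params passed to [register_spherical()].
#' @return `deformation_field` pulling native data onto the reference grid.
#' @export
subject_to_template <- function(subject, templates, chain, mesh,
                                reg_params = list()) {
  weeks <- chain$weeks
  wk <- weeks[which.min(abs(weeks - subject$age_weeks))]
  t <- templates[[as.character(wk)]]
  fixed <- if (inherits(t, "template")) t$metrics$sulc else t
  d_loc <- register_spherical(subject$sulc, fixed, mesh, reg_params)
  d_loc$source_space <- "template"
  d_loc$target_space <- "native"
  compose_deformations(chain$to40[[as.character(wk)]], d_loc)
}
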