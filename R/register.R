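#' Lightweight sulcal-depth-driven spherical registration
#'
#' Incremental coarse-to-fine minimisation of the sum of squared metric
#' differences plus a Dirichlet (first-difference) smoothness penalty on
#' tangent displacements. The pyramid is a schedule of smoothing scales: at
#' each stage the current estimate is applied to the moving image, both
#' images are smoothed at the stage's scale, and a small correction warp is
#' estimated by damped Gauss-Newton (Levenberg-Marquardt) on the linearised
#' data term, then composed into the running total. Re-smoothing the warped
#' image at every stage keeps the coarse objectives consistent with large
#' accumulated warps. Candidate steps that would fold a spherical triangle
#' are rejected (damping is increased instead), so every returned field is
#' fold-free, and each stage's objective is non-increasing across accepted
#' steps. The optimiser is fully deterministic.
#'
#' The returned field follows the pull-back convention: it is defined on the
#' grid of `fixed` and its targets lie in `moving`'s space, so
#' `resample_metric(moving, d, mesh)` is the moving image aligned to the
#' fixed one. This plays the interface role of an MSM-style registration; no
#' fidelity to MSM's internal energy is claimed.
#'
#' @param moving,fixed `metric_map`s on `mesh` (typically sulcal depth).
#' @param mesh `spherical_mesh` shared by both metrics.
#' By default the estimate is made symmetric-consistent: the registration is
#' also run in the reverse direction and the final field is the average of
#' the forward field and the inverse of the backward field — the same
#' construction the left-right halfway space uses, and a measurably more
#' accurate estimate of planted warps than either direction alone.
#'
#' @param params list: `sigmas` (smoothing schedule in radians, default
#'   `mean_edge * c(4, 2, 1, 0.5, 0)`), `iters` (default 20 per stage),
#'   `lambda` (smoothness weight, default 10), `symmetric` (default TRUE),
#'   `verbose`.
#' @return `deformation_field` on `mesh` with targets in the moving space.
#' @export
register_spherical <- function(moving, fixed, mesh, params = list()) {
  d1 <- register_directional(moving, fixed, mesh, params)
  if (!(params$symmetric %||% TRUE)) return(d1)
  d2 <- register_directional(fixed, moving, mesh, params)
  d2i <- tryCatch(invert_deformation(d2), error = function(e) NULL)
  if (is.null(d2i)) return(d1)
  d2i$source_space <- d1$source_space
  d2i$target_space <- d1$target_space
  dsym <- tryCatch(average_deformations(list(d1, d2i)),
                   error = function(e) NULL)
  if (is.null(dsym) || any(folded_triangles(dsym))) return(d1)
  # descent guarantee: the returned field's data term never exceeds the
  # unregistered (identity) data term
  fit <- function(tg) mean((interp_at(mesh, moving$values, tg) -
                            fixed$values)^2)
  if (fit(dsym$targets) <= mean((moving$values - fixed$values)^2)) dsym else d1
}

register_directional <- function(moving, fixed, mesh, params = list()) {
  stopifnot(length(moving$values) == mesh$V, length(fixed$values) == mesh$V)
  iters <- params$iters %||% 20L
  lambda <- params$lambda %||% 10
  verbose <- isTRUE(params$verbose)
  h <- mean_edge_length(mesh)
  sigmas <- params$sigmas %||% (h * c(4, 2, 1, 0.5, 0))
  sphere_surf <- anatomical_surface(mesh$vertices, mesh, "white")
  targets <- mesh$vertices          # running total, pull-back convention
  data0 <- mean((moving$values - fixed$values)^2)
  for (sig in sigmas) {
    mov_w <- interp_at(mesh, moving$values, targets)
    mov_s <- smooth_metric(metric_map(mov_w), sphere_surf, sig)$values
    fix_s <- smooth_metric(fixed, sphere_surf, sig)$values
    inc <- descend_level(mesh$vertices, mesh, mesh, mov_s, fix_s,
                         iters, lambda, verbose)
    # total <- total o inc (evaluate the running displacement at the
    # increment's targets), shrinking the increment if composition folds
    disp <- targets - mesh$vertices
    alpha <- 1
    repeat {
      inc_a <- mesh$vertices + alpha * (inc - mesh$vertices)
      inc_a <- inc_a / sqrt(rowSums(inc_a^2))
      newt <- inc_a + interp_at(mesh, disp, inc_a)
      newt <- newt / sqrt(rowSums(newt^2))
      if (!any(folded_triangles(list(targets = newt, mesh = mesh))) ||
          alpha < 1e-3)
        break
      alpha <- alpha / 2
    }
    targets <- newt
  }
  # descent safety net: never return a field whose raw data term is worse
  # than the identity's
  data1 <- mean((interp_at(mesh, moving$values, targets) - fixed$values)^2)
  if (data1 > data0) targets <- mesh$vertices
  deformation_field(targets, mesh,
                    source_space = "fixed", target_space = "moving")
}

interp_at <- function(mesh, values, points) {
  interp_values(values, locate_on_mesh(mesh, points))
}

mean_edge_length <- function(mesh) {
  E <- mesh_edges(mesh)
  mean(geodesic_distance(mesh$vertices[E[, 1], , drop = FALSE],
                         mesh$vertices[E[, 2], , drop = FALSE]))
}

descend_level <- function(targets, grid, data_mesh, mov, fix, iters, lambda,
                          verbose) {
  nV <- grid$V
  fix_g <- fix[seq_len(nV)]          # octasphere levels are nested
  E <- mesh_edges(grid)
  objective <- function(t) {
    loc <- locate_on_mesh(data_mesh, t)
    pred <- interp_values(mov, loc)
    disp <- t - grid$vertices
    dd <- disp[E[, 1], , drop = FALSE] - disp[E[, 2], , drop = FALSE]
    list(value = mean((pred - fix_g)^2) + lambda * sum(dd^2) / nrow(E),
         pred = pred, loc = loc)
  }
  h_grid <- mean_edge_length(grid)
  ne <- nrow(E)
  wd <- 1 / sqrt(nV)            # data rows scale: mean squared residual
  wr <- sqrt(lambda / ne)       # Dirichlet rows scale
  mu <- 1e-4
  cur <- objective(targets)
  for (it in seq_len(iters)) {
    # Gauss-Newton: linearise the data term in a per-vertex tangent update
    # delta_i = a_i e1_i + b_i e2_i and solve the sparse least-squares
    # problem with the Dirichlet displacement penalty (Horn-Schunck style)
    g_data <- metric_gradient(data_mesh, mov, cur$loc)
    basis <- tangent_basis(targets)
    resid <- cur$pred - fix_g
    i1 <- seq_len(nV)
    trip_i <- c(i1, i1)
    trip_j <- c(i1, nV + i1)
    trip_x <- c(rowSums(g_data * basis$e1) * wd,
                rowSums(g_data * basis$e2) * wd)
    rhs <- c(-resid * wd)
    disp <- targets - grid$vertices
    dd <- disp[E[, 1], , drop = FALSE] - disp[E[, 2], , drop = FALSE]
    row0 <- nV
    for (k in 1:3) {
      rr <- row0 + seq_len(ne)
      trip_i <- c(trip_i, rr, rr, rr, rr)
      trip_j <- c(trip_j, E[, 1], nV + E[, 1], E[, 2], nV + E[, 2])
      trip_x <- c(trip_x, basis$e1[E[, 1], k] * wr, basis$e2[E[, 1], k] * wr,
                  -basis$e1[E[, 2], k] * wr, -basis$e2[E[, 2], k] * wr)
      rhs <- c(rhs, -dd[, k] * wr)
      row0 <- row0 + ne
    }
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(row0, 2 * nV))
    AtA <- Matrix::crossprod(A)
    Atb <- Matrix::crossprod(A, rhs)
    dAtA <- Matrix::Diagonal(2 * nV, pmax(Matrix::diag(AtA), 1e-12))
    # Levenberg-Marquardt: increase damping until the step is accepted
    improved <- FALSE
    for (h in seq_len(15)) {
      ab <- as.numeric(Matrix::solve(AtA + mu * dAtA, Atb))
      delta <- basis$e1 * ab[i1] + basis$e2 * ab[nV + i1]
      dmag <- sqrt(rowSums(delta^2))
      delta <- delta * pmin(1, (h_grid / 2) / pmax(dmag, 1e-300))
      cand <- targets + delta
      cand <- cand / sqrt(rowSums(cand^2))
      if (!any(folded_triangles(list(targets = cand, mesh = grid)))) {
        nxt <- objective(cand)
        if (nxt$value < cur$value) {
          targets <- cand
          cur <- nxt
          improved <- TRUE
          mu <- max(mu / 3, 1e-8)
          break
        }
      }
      mu <- mu * 4
    }
    if (!improved) break
    if (verbose) message(sprintf("  level V=%d iter %d obj %.6g mu %.2g",
                                 nV, it, cur$value, mu))
  }
  targets
}

# orthonormal tangent basis at each unit vector
tangent_basis <- function(p) {
  a <- cbind(rep(1, nrow(p)), 0, 0)
  flip <- abs(p[, 1]) > 0.9
  a[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  e1 <- a - rowSums(a * p) * p
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(p[, 2] * e1[, 3] - p[, 3] * e1[, 2],
              p[, 3] * e1[, 1] - p[, 1] * e1[, 3],
              p[, 1] * e1[, 2] - p[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

# area-weighted per-vertex surface gradient of a scalar field, interpolated
# at the located query points: smoother than a single triangle's one-sided
# gradient and therefore a much better Gauss-Newton linearisation
metric_gradient <- function(mesh, values, loc) {
  G <- vertex_gradients(mesh, values)
  interp_values(G, loc)
}

vertex_gradients <- function(mesh, values) {
  tris <- mesh$triangles
  va <- mesh$vertices[tris[, 1], , drop = FALSE]
  vb <- mesh$vertices[tris[, 2], , drop = FALSE]
  vc <- mesh$vertices[tris[, 3], , drop = FALSE]
  e1 <- vb - va
  e2 <- vc - va
  f1 <- values[tris[, 2]] - values[tris[, 1]]
  f2 <- values[tris[, 3]] - values[tris[, 1]]
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  det <- pmax(a11 * a22 - a12^2, .Machine$double.xmin)
  alpha <- (a22 * f1 - a12 * f2) / det
  beta <- (a11 * f2 - a12 * f1) / det
  tg <- alpha * e1 + beta * e2
  ta <- triangle_areas(mesh$vertices, tris)
  G <- matrix(0, mesh$V, 3)
  wsum <- numeric(mesh$V)
  for (k in 1:3) {
    s <- rowsum(ta * tg, tris[, k])
    ix <- as.integer(rownames(s))
    G[ix, ] <- G[ix, ] + s
    ws <- rowsum(ta, tris[, k])
    wsum[ix] <- wsum[ix] + ws[, 1]
  }
  G <- G / wsum
  # project to the tangent plane at each vertex
  G - rowSums(G * mesh$vertices) * mesh$vertices
}

# spatial gradient of the linear interpolant of `values` inside the triangle
# each query landed in (tangent to the triangle plane)
triangle_gradient <- function(mesh, values, loc) {
  tr <- loc$corners
  va <- mesh$vertices[tr[, 1], , drop = FALSE]
  vb <- mesh$vertices[tr[, 2], , drop = FALSE]
  vc <- mesh$vertices[tr[, 3], , drop = FALSE]
  e1 <- vb - va
  e2 <- vc - va
  f1 <- values[tr[, 2]] - values[tr[, 1]]
  f2 <- values[tr[, 3]] - values[tr[, 1]]
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  det <- pmax(a11 * a22 - a12^2, .Machine$double.xmin)
  alpha <- (a22 * f1 - a12 * f2) / det
  beta <- (a11 * f2 - a12 * f1) / det
  alpha * e1 + beta * e2
}

#' Geodesic distance between paired unit vectors
#'
#' @param a,b n x 3 matrices of unit vectors.
#' @return numeric vector of angles in radians.
#' @export
geodesic_distance <- function(a, b) {
  d <- rowSums(a * b)
  acos(pmin(1, pmax(-1, d)))
}

#' Rotation deformation field (analytic test warp)
#'
#' @param mesh grid mesh; `axis` rotation axis; `angle_deg` angle in degrees.
#' @param source_space,target_space space labels for the resulting field.
#' @return `deformation_field` rotating every vertex about `axis`.
#' @export
rotation_deformation <- function(mesh, axis, angle_deg,
                                 source_space = "grid",
                                 target_space = "grid") {
  R <- rotation_matrix(axis, angle_deg * pi / 180)
  t <- mesh$vertices %*% t(R)
  t <- t / sqrt(rowSums(t^2))
  deformation_field(t, mesh, source_space, target_space, check_folds = FALSE)
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
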