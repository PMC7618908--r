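#' Spherical mesh with optional exact mirror symmetry
#'
#' A `spherical_mesh` is a closed triangulated 2-manifold whose vertices lie
#' on the unit sphere. It is the common coordinate system for all per-vertex
#' maps in the package. When the vertex set is exactly invariant under the
#' reflection `x -> -x` (as for octaspheres, see [make_octasphere()]), the
#' mesh carries `mirror_perm`, the vertex permutation realising that
#' reflection; this makes left-right mirroring an exact index operation.
#'
#' @param vertices numeric V x 3 matrix of unit-norm coordinates.
#' @param triangles integer F x 3 matrix of 1-based vertex indices with
#'   consistent outward winding.
#' @param mirror_perm optional integer vector: `mirror_perm[i]` is the vertex
#'   whose coordinates are `(-x, y, z)` of vertex `i`.
#' @param validate logical; skip invariant checks (internal use only).
#' @return object of class `spherical_mesh` with fields `vertices`,
#'   `triangles`, `mirror_perm`, `V`, `F`.
#' @export
spherical_mesh <- function(vertices, triangles, mirror_perm = NULL,
                           validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L)
  m <- structure(list(vertices = vertices, triangles = triangles,
                      mirror_perm = mirror_perm,
                      V = nrow(vertices), F = nrow(triangles)),
                 class = "spherical_mesh")
  if (validate) validate_spherical_mesh(m)
  m
}

validate_spherical_mesh <- function(m) {
  nrm <- sqrt(rowSums(m$vertices^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("spherical_mesh: vertex norms deviate from 1 by up to ",
         format(max(abs(nrm - 1))))
  E <- mesh_edges(m)
  euler <- m$V - nrow(E) + m$F
  if (euler != 2L)
    stop("spherical_mesh: Euler characteristic is ", euler, ", expected 2")
  check_winding(m$vertices, m$triangles)
  if (!is.null(m$mirror_perm)) {
    p <- m$mirror_perm
    if (length(p) != m$V || any(p[p] != seq_len(m$V)))
      stop("spherical_mesh: mirror_perm is not an involution")
    refl <- m$vertices
    refl[, 1] <- -refl[, 1]
    if (max(abs(m$vertices[p, ] - refl)) > 1e-12)
      stop("spherical_mesh: mirror_perm does not realise x -> -x")
  }
  invisible(m)
}

# Every undirected edge of a closed, consistently wound mesh appears exactly
# twice, once in each direction.
check_winding <- function(vertices, triangles) {
  he <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    stop("mesh winding inconsistent: a directed edge appears twice")
  rkey <- paste(he[, 2], he[, 1])
  if (!all(rkey %in% key))
    stop("mesh is not closed: boundary edge found")
  # outward orientation: signed volume of the star-shaped solid must be > 0
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
             v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
             v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  if (vol < 0) stop("mesh winding inconsistent: normals point inward")
  invisible(TRUE)
}

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# list: neighbours[[i]] = sorted vertex neighbours of i
mesh_neighbours <- function(mesh) {
  if (!is.null(mesh$.neighbours)) return(mesh$.neighbours)
  E <- mesh_edges(mesh)
  nb <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
  lapply(nb, function(x) sort(unique(x)))
}

# list: incident[[i]] = triangle indices containing vertex i
vertex_triangles <- function(mesh) {
  tr <- mesh$triangles
  idx <- rep(seq_len(nrow(tr)), 3)
  split(idx, c(tr[, 1], tr[, 2], tr[, 3]))
}

#' Anatomical surface sharing a spherical mesh's topology
#'
#' Vertex coordinates in mm (RAS-like axes) on the same triangulation as a
#' paired [spherical_mesh()]; the `role` tag distinguishes white, pial and
#' midthickness geometry.
#'
#' @param vertices numeric V x 3 coordinate matrix in mm.
#' @param mesh the paired `spherical_mesh` supplying the triangulation.
#' @param role one of `"white"`, `"pial"`, `"midthickness"`.
#' @return object of class `anatomical_surface`.
#' @export
anatomical_surface <- function(vertices, mesh, role = c("white", "pial",
                                                        "midthickness")) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) != mesh$V)
    stop("anatomical_surface: vertex count ", nrow(vertices),
         " does not match mesh vertex count ", mesh$V)
  a <- triangle_areas(vertices, mesh$triangles)
  if (any(a == 0)) warning("anatomical_surface: degenerate zero-area triangle")
  structure(list(vertices = vertices, mesh = mesh, role = role),
            class = "anatomical_surface")
}

#' Per-vertex scalar map
#'
#' @param values numeric vector, one value per mesh vertex. Non-finite input
#'   is rejected: missing vertices are represented by the value 0 plus an
#'   explicit `missing` flag, never by NaN.
#' @param hemisphere `"left"`, `"right"` or `"symmetric"`.
#' @param feature feature name, e.g. `"sulc"`, `"thickness"`.
#' @param missing optional logical vector flagging missing vertices.
#' @return object of class `metric_map`.
#' @export
metric_map <- function(values, hemisphere = c("left", "right", "symmetric"),
                       feature = "metric", missing = NULL) {
  hemisphere <- match.arg(hemisphere)
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("metric_map: non-finite values; flag missing vertices explicitly")
  if (!is.null(missing)) stopifnot(length(missing) == length(values))
  structure(list(values = values, hemisphere = hemisphere, feature = feature,
                 missing = missing),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s (%s), %d vertices, range [%.4g, %.4g]\n",
              x$feature, x$hemisphere, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

triangle_areas <- function(vertices, triangles) {
  u <- vertices[triangles[, 2], , drop = FALSE] -
       vertices[triangles[, 1], , drop = FALSE]
  v <- vertices[triangles[, 3], , drop = FALSE] -
       vertices[triangles[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Cortical thickness from paired white and pial surfaces
#'
#' Thickness at vertex i is the Euclidean distance between the white and pial
#' coordinates of that vertex, in mm.
#'
#' @param white,pial `anatomical_surface` objects on the same topology.
#' @param hemisphere hemisphere tag for the result.
#' @return `metric_map` of per-vertex thickness (mm, nonnegative).
#' @export
cortical_thickness <- function(white, pial, hemisphere = "left") {
  if (!identical(dim(white$vertices), dim(pial$vertices)) ||
      !identical(white$mesh$triangles, pial$mesh$triangles))
    stop("cortical_thickness: white and pial surfaces have mismatched topology")
  d <- sqrt(rowSums((pial$vertices - white$vertices)^2))
  metric_map(d, hemisphere, "thickness")
}

#' Per-vertex surface area
#'
#' Each vertex is assigned one third of the area of every triangle it belongs
#' to, so vertex areas sum exactly to the total mesh area.
#'
#' @param surface an `anatomical_surface` (or `spherical_mesh` for unit-sphere
#'   areas).
#' @param hemisphere hemisphere tag for the result.
#' @return `metric_map` of per-vertex area (mm^2).
#' @export
vertex_areas <- function(surface, hemisphere = "left") {
  if (inherits(surface, "spherical_mesh")) {
    verts <- surface$vertices; tris <- surface$triangles; V <- surface$V
  } else {
    verts <- surface$vertices; tris <- surface$mesh$triangles; V <- nrow(verts)
  }
  a <- triangle_areas(verts, tris)
  if (any(a == 0)) warning("vertex_areas: degenerate triangle contributes zero")
  va <- numeric(V)
  third <- a / 3
  for (k in 1:3) {
    s <- rowsum(third, tris[, k])
    ix <- as.integer(rownames(s))
    va[ix] <- va[ix] + s[, 1]
  }
  metric_map(va, hemisphere, "vertex_area")
}

# cotangent weight matrix (sparse, symmetric) with per-vertex clamp bookkeeping
cotan_weights <- function(verts, tris) {
  W <- NULL
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in 1:3) {
    a <- tris[, k]
    b <- tris[, (k %% 3) + 1]
    c <- tris[, ((k + 1) %% 3) + 1]
    # angle at c, opposite edge (a, b)
    u <- verts[a, , drop = FALSE] - verts[c, , drop = FALSE]
    v <- verts[b, , drop = FALSE] - verts[c, , drop = FALSE]
    dotuv <- rowSums(u * v)
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    crossn <- sqrt(cx^2 + cy^2 + cz^2)
    cot <- dotuv / pmax(crossn, .Machine$double.xmin)
    ii <- c(ii, a, b); jj <- c(jj, b, a); ww <- c(ww, cot / 2, cot / 2)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nrow(verts), nrow(verts)))
}

#' Discrete mean curvature
#'
#' Half the norm of the area-normalised cotangent Laplacian applied to the
#' vertex coordinates, signed positive where the surface bends towards the
#' outward normal (a sphere of radius r has mean curvature +1/r). Vertices in
#' obtuse-degenerate patches (non-positive total cotangent weight) fall back
#' to uniform weights and are flagged in the `fallback` attribute.
#'
#' @param surface an `anatomical_surface`.
#' @param hemisphere hemisphere tag.
#' @return `metric_map` of mean curvature (1/mm).
#' @export
mean_curvature <- function(surface, hemisphere = "left") {
  verts <- surface$vertices
  tris <- surface$mesh$triangles
  W <- cotan_weights(verts, tris)
  rs <- Matrix::rowSums(W)
  bad <- which(rs <= 0)
  if (length(bad)) {
    # uniform-weight fallback at degenerate vertices
    nb <- mesh_neighbours(surface$mesh)
    for (i in bad) {
      W[i, ] <- 0
      W[i, nb[[i]]] <- 1
    }
  }
  A <- vertex_areas(surface)$values
  lap <- (as.matrix(W %*% verts) - Matrix::rowSums(W) * verts) / A
  # outward vertex normals from area-weighted triangle normals
  nrm <- vertex_normals(verts, tris)
  mag <- sqrt(rowSums(lap^2)) / 2
  sgn <- ifelse(rowSums(lap * nrm) < 0, 1, -1)
  out <- metric_map(sgn * mag, hemisphere, "curvature")
  attr(out, "fallback") <- bad
  out
}

vertex_normals <- function(verts, tris) {
  u <- verts[tris[, 2], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  v <- verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- matrix(0, nrow(verts), 3)
  for (k in 1:3) {
    s <- rowsum(fn, tris[, k])
    ix <- as.integer(rownames(s))
    n[ix, ] <- n[ix, ] + s
  }
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Remove folding bias from a metric by regressing out curvature
#'
#' Ordinary least-squares fit of the metric on `[1, curvature]`; the returned
#' map is the residual plus the original global mean, so the output is
#' uncorrelated with curvature but keeps the input's absolute level (asymmetry
#' indices depend on it). Applying the operation twice equals applying it once.
#'
#' @param metric,curvature `metric_map`s on the same mesh and hemisphere.
#' @return corrected `metric_map`.
#' @export
regress_out_curvature <- function(metric, curvature) {
  if (length(metric$values) != length(curvature$values))
    stop("regress_out_curvature: maps live on different meshes")
  if (!identical(metric$hemisphere, curvature$hemisphere))
    stop("regress_out_curvature: hemisphere mismatch")
  x <- curvature$values
  y <- metric$values
  if (stats::sd(x) == 0) {
    warning("regress_out_curvature: constant curvature map, regression skipped")
    return(metric)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  metric_map(fit$residuals + mean(y), metric$hemisphere, metric$feature,
             metric$missing)
}

#' Surface-constrained Gaussian smoothing of a metric map
#'
#' Approximate geodesic Gaussian smoothing with kernel `sigma_mm`, realised as
#' heat diffusion for time t = sigma^2 / 2 using explicit area-weighted
#' cotangent-Laplacian steps. The step size is bounded by the stability limit
#' of the discrete Laplacian (with margin), so the iteration never diverges;
#' the area-weighted global mean is conserved and constant maps are invariant.
#'
#' @param metric `metric_map` to smooth.
#' @param surface `anatomical_surface` carrying the geometry (mm) on which
#'   distances are measured.
#' @param sigma_mm Gaussian kernel sigma in mm; 0 is the identity.
#' @return smoothed `metric_map`.
#' @export
smooth_metric <- function(metric, surface, sigma_mm) {
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0) return(metric)
  if (length(metric$values) != nrow(surface$vertices))
    stop("smooth_metric: metric has ", length(metric$values),
         " values but surface has ", nrow(surface$vertices), " vertices")
  op <- smoothing_operator(surface, sigma_mm)
  u <- metric$values
  for (s in seq_len(op$n_steps)) u <- u + op$dt * as.numeric(op$L %*% u)
  metric_map(u, metric$hemisphere, metric$feature, metric$missing)
}

# shared explicit heat-diffusion operator; negative cotangent weights are
# clamped to zero to keep the explicit scheme monotone (conservation holds
# because clamping preserves symmetry)
smoothing_operator <- function(surface, sigma_mm) {
  W <- cotan_weights(surface$vertices, surface$mesh$triangles)
  W@x[W@x < 0] <- 0
  A <- vertex_areas(surface)$values
  D <- Matrix::rowSums(W)
  L <- (W - Matrix::Diagonal(x = D)) / A   # row-scaled: A^{-1}(W - D)
  t_total <- sigma_mm^2 / 2
  dt_max <- 1 / max(D / A)
  n_steps <- max(1L, ceiling(t_total / (0.5 * dt_max)))
  list(L = methods::as(L, "CsparseMatrix"), dt = t_total / n_steps,
       n_steps = n_steps)
}
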