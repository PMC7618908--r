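#' Spherical deformation fields
#'
#' A `deformation_field` stores, for every vertex of a grid mesh, a target
#' position on the unit sphere. Fields follow the pull-back convention used
#' throughout the package: a field `d` whose grid is mesh `G` and whose
#' targets lie in space `S` is used to pull data defined on `S` onto `G`
#' ([resample_metric()] evaluates the metric at `d`'s targets). Composition,
#' inversion and averaging obey group-like laws for the small, smooth warps
#' produced by registration.
#'
#' @param targets V x 3 matrix of unit-norm target coordinates.
#' @param mesh the grid `spherical_mesh` the field is defined on.
#' @param source_space,target_space free-text space labels used for
#'   structural checks in [compose_deformations()].
#' @param check_folds verify that no spherical triangle flips orientation.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(targets, mesh, source_space = "grid",
                              target_space = "target", check_folds = TRUE) {
  targets <- as.matrix(targets)
  stopifnot(ncol(targets) == 3L, nrow(targets) == mesh$V)
  nrm <- sqrt(rowSums(targets^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("deformation_field: targets must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  d <- structure(list(targets = targets, mesh = mesh,
                      source_space = source_space,
                      target_space = target_space),
                 class = "deformation_field")
  if (check_folds && any(folded_triangles(d)))
    stop("deformation_field: folded spherical triangles present")
  d
}

#' @rdname deformation_field
#' @export
identity_deformation <- function(mesh, space = "grid") {
  deformation_field(mesh$vertices, mesh, source_space = space,
                    target_space = space, check_folds = FALSE)
}

# a spherical triangle is folded when the signed volume of its mapped corners
# changes sign relative to the source orientation (outward on both meshes)
folded_triangles <- function(d) {
  tr <- d$mesh$triangles
  t1 <- d$targets[tr[, 1], , drop = FALSE]
  t2 <- d$targets[tr[, 2], , drop = FALSE]
  t3 <- d$targets[tr[, 3], , drop = FALSE]
  det <- t1[, 1] * (t2[, 2] * t3[, 3] - t2[, 3] * t3[, 2]) -
         t1[, 2] * (t2[, 1] * t3[, 3] - t2[, 3] * t3[, 1]) +
         t1[, 3] * (t2[, 1] * t3[, 2] - t2[, 2] * t3[, 1])
  det <= 0
}

# barycentric evaluation machinery: locate points on `mesh` and return the
# sparse interpolation info
locate_on_mesh <- function(mesh, points) {
  loc <- .locate_points_cpp(mesh$vertices, mesh$triangles, as.matrix(points))
  loc$corners <- mesh$triangles[loc$triangle, , drop = FALSE]
  loc
}

interp_values <- function(values, loc) {
  if (is.matrix(values))
    loc$weights[, 1] * values[loc$corners[, 1], , drop = FALSE] +
    loc$weights[, 2] * values[loc$corners[, 2], , drop = FALSE] +
    loc$weights[, 3] * values[loc$corners[, 3], , drop = FALSE]
  else
    loc$weights[, 1] * values[loc$corners[, 1]] +
    loc$weights[, 2] * values[loc$corners[, 2]] +
    loc$weights[, 3] * values[loc$corners[, 3]]
}

#' Resample a metric map through a deformation field
#'
#' Each output vertex takes the barycentric interpolation of `metric` (which
#' lives on `mesh`, the space the deformation's targets point into) at the
#' vertex's mapped position. Barycentric weights are nonnegative and sum to
#' one; mapped points that fall outside all triangles after spherical point
#' location (a numerical corner case) use the nearest triangle and are
#' flagged in the `fallback` attribute.
#'
#' @param metric `metric_map` on `mesh`.
#' @param deformation `deformation_field` whose targets lie in `mesh`'s space.
#' @param mesh the `spherical_mesh` carrying `metric`.
#' @return `metric_map` on the deformation's grid mesh.
#' @export
resample_metric <- function(metric, deformation, mesh) {
  if (length(metric$values) != mesh$V)
    stop("resample_metric: metric has ", length(metric$values),
         " values but mesh has ", mesh$V, " vertices")
  loc <- locate_on_mesh(mesh, deformation$targets)
  out <- metric_map(interp_values(metric$values, loc), metric$hemisphere,
                    metric$feature)
  attr(out, "fallback") <- which(loc$fallback)
  out
}

#' Compose two deformation fields
#'
#' `compose_deformations(d1, d2)` maps `v` to `d2(d1(v))`: `d2` is evaluated
#' at `d1`'s targets by barycentric interpolation of its own targets (then
#' re-projected to the sphere). Under the pull-back convention this is the
#' field that pulls data through `d2` and then `d1` in one interpolation.
#'
#' @param d1,d2 `deformation_field`s with `d1$target_space == d2$source_space`.
#' @return composed `deformation_field` on `d1`'s grid.
#' @export
compose_deformations <- function(d1, d2) {
  if (!identical(d1$target_space, d2$source_space))
    stop("compose_deformations: d1 targets live in '", d1$target_space,
         "' but d2 is defined on '", d2$source_space, "'")
  loc <- locate_on_mesh(d2$mesh, d1$targets)
  # barycentric interpolation of the target positions with re-projection to
  # the sphere: radial projection makes this exact for the identity and for
  # rotations, the cases the algebraic laws are anchored on
  t2 <- interp_values(d2$targets, loc)
  t2 <- t2 / sqrt(rowSums(t2^2))
  deformation_field(t2, d1$mesh, d1$source_space, d2$target_space,
                    check_folds = FALSE)
}

#' Invert a deformation field
#'
#' Scattered-interpolation initial guess (locating each grid vertex in the
#' deformed mesh) refined by damped fixed-point iteration on the residual
#' `d(inv(u)) - u`. The composition of a field with its inverse stays within
#' `1e-3` radians of the identity for smooth, fold-free warps.
#'
#' @param d `deformation_field` without folded triangles.
#' @param max_iter,tol iteration controls for the fixed-point refinement.
#' @return inverse `deformation_field`.
#' @export
invert_deformation <- function(d, max_iter = 50, tol = 1e-10) {
  if (any(folded_triangles(d)))
    stop("invert_deformation: field has folded triangles")
  mesh <- d$mesh
  # deformed mesh: source triangulation carried to the target positions
  dmesh <- structure(list(vertices = d$targets, triangles = mesh$triangles,
                          mirror_perm = NULL, V = mesh$V, F = mesh$F),
                     class = "spherical_mesh")
  loc <- locate_on_mesh(dmesh, mesh$vertices)
  s <- interp_values(mesh$vertices, loc)
  s <- s / sqrt(rowSums(s^2))
  disp <- d$targets - mesh$vertices
  eval_d <- function(s) {
    locf <- locate_on_mesh(mesh, s)
    ds <- s + interp_values(disp, locf)
    ds / sqrt(rowSums(ds^2))
  }
  resid_of <- function(s) {
    err <- mesh$vertices - eval_d(s)
    list(err = err, resid = max(sqrt(rowSums(err^2))))
  }
  cur <- resid_of(s)
  for (it in seq_len(max_iter)) {
    if (cur$resid < tol) break
    # damped fixed point with backtracking on the residual
    alpha <- 1
    repeat {
      s2 <- s + alpha * cur$err
      s2 <- s2 / sqrt(rowSums(s2^2))
      nxt <- resid_of(s2)
      if (nxt$resid < cur$resid || alpha < 1e-3) break
      alpha <- alpha / 2
    }
    if (nxt$resid >= cur$resid) break
    s <- s2
    cur <- nxt
  }
  resid <- cur$resid
  if (resid > 1e-4)
    stop("invert_deformation: fixed-point iteration did not converge ",
         "(residual ", format(resid), " radians)")
  deformation_field(s, mesh, source_space = d$target_space,
                    target_space = d$source_space, check_folds = FALSE)
}

#' Average deformation fields
#'
#' Per-vertex weighted Euclidean mean of the target coordinates, projected
#' back onto the unit sphere. Valid for the small displacements produced by
#' within-week registrations; near-antipodal configurations are refused.
#'
#' @param fields list of `deformation_field`s sharing grid and spaces.
#' @param weights optional weights, default uniform; normalised internally.
#' @return `deformation_field`.
#' @export
average_deformations <- function(fields, weights = NULL) {
  stopifnot(length(fields) >= 1)
  if (is.null(weights)) weights <- rep(1, length(fields))
  stopifnot(length(weights) == length(fields))
  weights <- weights / sum(weights)
  acc <- matrix(0, fields[[1]]$mesh$V, 3)
  for (k in seq_along(fields)) acc <- acc + weights[k] * fields[[k]]$targets
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm < 0.5))
    stop("average_deformations: near-antipodal mean (norm < 0.5)")
  deformation_field(acc / nrm, fields[[1]]$mesh,
                    fields[[1]]$source_space, fields[[1]]$target_space,
                    check_folds = FALSE)
}

#' Mirror permutation and metric mirroring
#'
#' `mirror_map` returns the vertex permutation realising the reflection
#' `x -> -x`; `mirror_metric` applies it to a per-vertex map, carrying a map
#' between the left and right hemispheric frames of a shared symmetric mesh.
#' Applying `mirror_metric` twice is the identity.
#'
#' @param mesh `spherical_mesh` with `mirror_perm` present.
#' @return `mirror_map`: integer permutation; `mirror_metric`: `metric_map`.
#' @export
mirror_map <- function(mesh) {
  if (is.null(mesh$mirror_perm))
    stop("mirror_map: mesh has no mirror permutation; ",
         "use a symmetric mesh such as make_octasphere()")
  mesh$mirror_perm
}

#' @rdname mirror_map
#' @param metric `metric_map` on `mesh`.
#' @export
mirror_metric <- function(metric, mesh) {
  p <- mirror_map(mesh)
  hemi <- switch(metric$hemisphere, left = "right", right = "left",
                 "symmetric")
  metric_map(metric$values[p], hemi, metric$feature,
             if (!is.null(metric$missing)) metric$missing[p])
}

#' Serialise a deformation field as a 3-column metric file
#'
#' @param d `deformation_field`; `path` file path.
#' @rdname deformation_io
#' @export
write_deformation <- function(d, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  gifti_array(doc, "NIFTI_INTENT_VECTOR", "NIFTI_TYPE_FLOAT32",
              matrix(sprintf("%.17g", d$targets), nrow(d$targets), 3),
              list(source_space = d$source_space,
                   target_space = d$target_space))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname deformation_io
#' @param path file path; `mesh` the grid mesh.
#' @export
read_deformation <- function(path, mesh) {
  arrs <- gifti_read_arrays(path)
  a <- arrs[[1]]
  t <- a$data
  t <- t / sqrt(rowSums(t^2))
  deformation_field(t, mesh, a$meta$source_space %||% "grid",
                    a$meta$target_space %||% "target", check_folds = FALSE)
}
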