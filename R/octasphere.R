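#' Octasphere: subdivided-octahedron sphere mesh with exact mirror symmetry
#'
#' Recursive midpoint subdivision of the unit octahedron. Because the
#' octahedron's vertex set is exactly invariant under the reflection
#' `x -> -x`, and edge-midpoint subdivision preserves that invariance
#' bitwise in IEEE arithmetic, the mirror permutation is exact (not merely
#' approximate), which makes left-right metric mirroring an index operation.
#' Subdivision levels are nested: the first `4 * 4^l + 2` vertices of a
#' level-`l + 1` octasphere are exactly the level-`l` vertices.
#'
#' @param level subdivision level, 0 (octahedron, 6 vertices) to 7.
#' @return `spherical_mesh` with `mirror_perm` populated and an integer
#'   `level` attribute; `V = 4 * 4^level + 2`.
#' @export
make_octasphere <- function(level) {
  stopifnot(level >= 0)
  if (level > 7) stop("make_octasphere: level > 7 refused (size guard)")
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0),
                 c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  tris <- matrix(0L, 8, 3)
  r <- 0L
  for (sx in c(1L, 2L)) for (sy in c(3L, 4L)) for (sz in c(5L, 6L)) {
    r <- r + 1L
    flip <- (sx == 2L) + (sy == 4L) + (sz == 6L)
    tris[r, ] <- if (flip %% 2 == 0) c(sx, sy, sz) else c(sx, sz, sy)
  }
  for (l in seq_len(level)) {
    sub <- subdivide_once(verts, tris)
    verts <- sub$verts
    tris <- sub$tris
  }
  mp <- mirror_permutation(verts)
  m <- spherical_mesh(verts, tris, mirror_perm = mp)
  attr(m, "level") <- level
  m
}

subdivide_once <- function(verts, tris) {
  nv <- nrow(verts)
  ek <- new.env(hash = TRUE)
  newv <- list()
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- ek[[key]]
    if (!is.null(id)) return(id)
    p <- verts[i, ] + verts[j, ]
    p <- p / sqrt(sum(p^2))
    newv[[length(newv) + 1L]] <<- p
    id <- nv + length(newv)
    ek[[key]] <- id
    id
  }
  out <- matrix(0L, nrow(tris) * 4, 3)
  for (t in seq_len(nrow(tris))) {
    a <- tris[t, 1]; b <- tris[t, 2]; c <- tris[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    out[(t - 1) * 4 + 1, ] <- c(a, ab, ca)
    out[(t - 1) * 4 + 2, ] <- c(ab, b, bc)
    out[(t - 1) * 4 + 3, ] <- c(ca, bc, c)
    out[(t - 1) * 4 + 4, ] <- c(ab, bc, ca)
  }
  list(verts = rbind(verts, do.call(rbind, newv)), tris = out)
}

# exact lookup of the vertex at (-x, y, z) for every vertex
mirror_permutation <- function(verts) {
  key <- function(M) apply(M, 1, function(r) paste(sprintf("%.17g", r + 0),
                                                   collapse = ","))
  refl <- verts
  refl[, 1] <- -refl[, 1]
  p <- match(key(refl), key(verts))
  if (anyNA(p)) stop("mirror_permutation: vertex set not mirror-symmetric")
  as.integer(p)
}

#' Band-limited random smooth field on a spherical mesh
#'
#' Draws independent Gaussian coefficients for all real spherical harmonics
#' with degree inside `band` and returns their combination, scaled to zero
#' spherical mean and unit pointwise variance in expectation. Used as a
#' sulcal-depth-like template pattern by the synthetic cohort generator.
#'
#' @param mesh `spherical_mesh`.
#' @param seed integer seed (mandatory; same seed, same field).
#' @param band integer vector `c(lmin, lmax)`, default degrees 3 to 8.
#' @param hemisphere,feature metadata for the returned map.
#' @return `metric_map`.
#' @export
generate_template_pattern <- function(mesh, seed, band = c(3, 8),
                                      hemisphere = "left", feature = "sulc") {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  co <- stats::rnorm(n_band_coefs(band))
  vals <- band_limited_field(mesh$vertices, band, co)
  metric_map(vals, hemisphere, feature)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
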