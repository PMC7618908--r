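#' Asymmetry index maps
#'
#' The asymmetry index at a vertex is `AI = (L - R) / ((L + R) / 2)`:
#' positive values are leftward asymmetries. For nonnegative inputs the
#' index is bounded in `[-2, 2]`. Vertices whose mean `(L + R) / 2` falls
#' below `eps` are set to 0 and flagged missing rather than propagating
#' division blow-ups.
#'
#' @param left `metric_map` on the shared mesh (left hemisphere).
#' @param right `metric_map` already mirrored onto the left topology, so
#'   vertex i of both maps is the same anatomical location.
#' @param eps denominator guard in native metric units (default 1e-8).
#' @param subject_id optional id stored on the result.
#' @return `metric_map` of class `c("asymmetry_map", "metric_map")` with
#'   feature `"<feature>_ai"`.
#' @export
asymmetry_index <- function(left, right, eps = 1e-8, subject_id = NULL) {
  stopifnot(length(left$values) == length(right$values))
  L <- left$values
  R <- right$values
  if (any(L < 0) || any(R < 0))
    warning("asymmetry_index: negative input for a nonnegative feature; ",
            "AI is unbounded")
  denom <- (L + R) / 2
  bad <- abs(denom) < eps
  ai <- numeric(length(L))
  ai[!bad] <- (L[!bad] - R[!bad]) / denom[!bad]
  out <- metric_map(ai, "symmetric", paste0(left$feature, "_ai"),
                    missing = if (any(bad)) bad else NULL)
  out$subject_id <- subject_id
  class(out) <- c("asymmetry_map", class(out))
  out
}

#' Subject-specific symmetric midthickness surface
#'
#' Averages the left midthickness coordinates with the YZ-plane-flipped
#' right midthickness coordinates (indexed through the mesh's mirror
#' permutation), then applies iterative neighbourhood smoothing
#' `v <- (1 - s) v + s mean(neighbours)` so metric smoothing downstream is
#' not biased towards either hemisphere.
#'
#' @param left,right midthickness `anatomical_surface`s on the shared mesh.
#' @param iterations smoothing iterations (default 10).
#' @param strength smoothing strength `s` (default 0.75).
#' @return `anatomical_surface` with role `"midthickness"`.
#' @export
symmetric_midthickness <- function(left, right, iterations = 10,
                                   strength = 0.75) {
  mesh <- left$mesh
  p <- mirror_map(mesh)
  rv <- right$vertices[p, , drop = FALSE]
  rv[, 1] <- -rv[, 1]
  v <- (left$vertices + rv) / 2
  nb <- mesh_neighbours(mesh)
  nbr_idx <- unlist(nb)
  nbr_rep <- rep(seq_len(mesh$V), lengths(nb))
  for (i in seq_len(iterations)) {
    nm <- rowsum(v[nbr_idx, , drop = FALSE], nbr_rep) / lengths(nb)
    v <- (1 - strength) * v + strength * nm
  }
  anatomical_surface(v, mesh, "midthickness")
}

#' Smooth an asymmetry map on the symmetric midthickness surface
#'
#' Delegates to [smooth_metric()] on the subject's symmetric midthickness
#' geometry with the default kernel sigma of 2 mm used for structural
#' asymmetry maps.
#'
#' @param ai asymmetry `metric_map`; `sym_mid` the smoothing surface.
#' @param sym_mid symmetric midthickness `anatomical_surface`.
#' @param sigma_mm kernel sigma in mm (default 2).
#' @return smoothed asymmetry map.
#' @export
smooth_asymmetry <- function(ai, sym_mid, sigma_mm = 2.0) {
  out <- smooth_metric(ai, sym_mid, sigma_mm)
  out$subject_id <- ai$subject_id
  class(out) <- class(ai)
  out
}

#' Functional component mask from a symmetric group map
#'
#' Thresholds a mirror-symmetric group component Z map at `z_thresh`
#' (signed, `Z > 5.1` by default), producing the single mask applied to
#' every subject's asymmetry map for that component so all subjects share
#' one spatial extent.
#'
#' @param group_map_z `metric_map` of group component Z values; must be
#'   mirror-symmetric on `mesh`.
#' @param mesh shared `spherical_mesh` (for the mirror check).
#' @param z_thresh threshold (default 5.1).
#' @param component label used in error messages.
#' @return logical vertex mask (mirror-symmetric).
#' @export
functional_mask <- function(group_map_z, mesh = NULL, z_thresh = 5.1,
                            component = group_map_z$feature) {
  mask <- group_map_z$values > z_thresh
  if (!any(mask))
    stop("functional_mask: component '", component, "' has no vertex above Z = ",
         z_thresh, " (max Z = ", format(max(group_map_z$values)), ")")
  if (!is.null(mesh)) {
    p <- mirror_map(mesh)
    if (!identical(mask, mask[p]))
      warning("functional_mask: mask is not mirror-symmetric")
  }
  mask
}

#' @rdname functional_mask
#' @param ai asymmetry map to mask.
#' @param mask logical vertex mask.
#' @export
apply_mask <- function(ai, mask) {
  stopifnot(length(mask) == length(ai$values))
  vals <- ai$values
  vals[!mask] <- 0
  miss <- !mask
  if (!is.null(ai$missing)) miss <- miss | ai$missing
  out <- metric_map(vals, ai$hemisphere, ai$feature, missing = miss)
  out$subject_id <- ai$subject_id
  class(out) <- class(ai)
  out
}

#' Region-of-interest summary of an asymmetry map
#'
#' Area-weighted mean and weighted median of the asymmetry index per label,
#' excluding flagged-missing vertices. The weighted totals are conserved: the
#' sum of `area * mean` over ROIs equals the sum of `area * AI` over
#' analysed vertices.
#'
#' @param ai asymmetry `metric_map`.
#' @param labels integer or character per-vertex ROI labels.
#' @param areas `metric_map` of per-vertex areas (mm^2).
#' @return data.frame with columns `roi`, `n_vertices`, `area_mm2`,
#'   `mean_ai`, `median_ai`.
#' @export
roi_summary <- function(ai, labels, areas) {
  if (length(labels) != length(ai$values) ||
      length(areas$values) != length(ai$values))
    stop("roi_summary: labels/areas length does not match the map")
  keep <- if (is.null(ai$missing)) rep(TRUE, length(labels)) else !ai$missing
  v <- ai$values[keep]
  a <- areas$values[keep]
  l <- labels[keep]
  rois <- sort(unique(l))
  res <- lapply(rois, function(r) {
    i <- l == r
    data.frame(roi = r, n_vertices = sum(i), area_mm2 = sum(a[i]),
               mean_ai = sum(a[i] * v[i]) / sum(a[i]),
               median_ai = weighted_median(v[i], a[i]))
  })
  do.call(rbind, res)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
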