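#' Timeseries container
#'
#' Frames-by-vertices matrix for one hemisphere of one subject. Columns are
#' demeaned on construction (per-vertex mean removed); no other temporal
#' filtering is applied.
#'
#' @param data numeric frames x vertices matrix.
#' @param hemisphere `"left"` or `"right"`.
#' @param subject_id optional id.
#' @return object of class `timeseries_matrix`.
#' @export
timeseries_matrix <- function(data, hemisphere = c("left", "right"),
                              subject_id = NULL) {
  hemisphere <- match.arg(hemisphere)
  data <- as.matrix(data)
  data <- sweep(data, 2, colMeans(data))
  structure(list(data = data, hemisphere = hemisphere,
                 subject_id = subject_id, n_frames = nrow(data)),
            class = "timeseries_matrix")
}

#' Smooth every frame of a timeseries on a surface
#'
#' Frame-by-frame application of [smooth_metric()] with the default
#' functional kernel sigma of 4 mm. All frames share one smoothing operator,
#' so this is a single sparse-matrix power iteration applied to the whole
#' frames-by-vertices block.
#'
#' @param ts `timeseries_matrix`.
#' @param surface `anatomical_surface` carrying the smoothing geometry.
#' @param sigma_mm kernel sigma in mm (default 4).
#' @return smoothed `timeseries_matrix`.
#' @export
smooth_timeseries <- function(ts, surface, sigma_mm = 4.0) {
  if (sigma_mm == 0) return(ts)
  op <- smoothing_operator(surface, sigma_mm)
  U <- t(ts$data)                       # vertices x frames
  for (s in seq_len(op$n_steps)) U <- U + op$dt * as.matrix(op$L %*% U)
  timeseries_matrix(t(U), ts$hemisphere, ts$subject_id)
}

#' Incremental group PCA (MIGP)
#'
#' Streaming concatenate-then-truncate SVD over subjects in a seeded random
#' order: subject blocks are stacked and, whenever the working matrix
#' exceeds `d_internal` rows, reduced to its top `d_internal` left-singular
#' rows. The row space approximates the leading eigenspace of the full
#' temporal concatenation at a fraction of the memory.
#'
#' @param subjects list of `timeseries_matrix` (same hemisphere/vertices).
#' @param d_internal internal dimensionality (rows retained).
#' @param seed integer seed for the subject order (mandatory).
#' @return `d_internal` x vertices matrix.
#' @export
migp <- function(subjects, d_internal, seed) {
  total <- sum(vapply(subjects, function(s) nrow(s$data), 0L))
  if (d_internal > total)
    stop("migp: d_internal = ", d_internal, " exceeds total frames ", total)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  ord <- sample(seq_along(subjects))
  W <- NULL
  for (s in ord) {
    W <- rbind(W, subjects[[s]]$data)
    if (nrow(W) > d_internal) {
      sv <- svd(W, nu = d_internal, nv = 0)
      W <- t(sv$u) %*% W                # top-d left-singular rows: U^T W
    }
  }
  if (nrow(W) < d_internal)
    W <- rbind(W, matrix(0, d_internal - nrow(W), ncol(W)))
  W
}

#' Mirror-concatenate hemispheric blocks
#'
#' Stacks the left block, the mirrored right block, the mirrored left block
#' and the right block, so the resulting row multiset is exactly invariant
#' both under the mirror permutation and under exchanging the hemisphere
#' inputs. Group decompositions of this matrix are mirror-symmetric by
#' construction, which is what removes hemispheric bias from dual-regressed
#' subject maps.
#'
#' @param left_block,right_block rows x vertices matrices (e.g. MIGP
#'   outputs), columns indexed on each hemisphere's own frame.
#' @param mirror_perm the shared mesh's mirror vertex permutation.
#' @return matrix with `2 * (nrow(left) + nrow(right))` rows.
#' @export
mirror_concatenate <- function(left_block, right_block, mirror_perm) {
  if (is.null(mirror_perm))
    stop("mirror_concatenate: mirror permutation absent")
  stopifnot(ncol(left_block) == ncol(right_block),
            ncol(left_block) == length(mirror_perm))
  rbind(left_block, right_block[, mirror_perm, drop = FALSE],
        left_block[, mirror_perm, drop = FALSE], right_block)
}

#' Group spatial ICA
#'
#' Fixed-point (FastICA) spatial ICA with the logcosh contrast and
#' deflation, run on the PCA-whitened reduced matrix with vertices as
#' samples. Component sign is fixed so every map has nonnegative skewness,
#' maps are Z-scored (zero mean, unit variance over vertices), and the
#' result is deterministic for a fixed seed.
#'
#' @param reduced rows x vertices matrix (e.g. mirror-concatenated MIGP).
#' @param d number of components (default 8 at desk scale; the full-scale
#'   analysis value is 25).
#' @param seed integer seed (mandatory).
#' @param max_restarts restarts with incremented seed on non-convergence.
#' @return list with `spatial_maps` (d x vertices, Z-scored), `mixing`
#'   (rows x d), `d`, `seed`.
#' @export
group_ica <- function(reduced, d = 8, seed, max_restarts = 5) {
  stopifnot(d <= nrow(reduced))
  X <- sweep(reduced, 1, rowMeans(reduced))
  # PCA whitening over vertices
  sv <- svd(X, nu = d, nv = 0)
  if (sv$d[d] < 1e-12 * sv$d[1])
    stop("group_ica: reduced matrix is rank-deficient below d = ", d)
  K <- t(sv$u[, seq_len(d), drop = FALSE]) / sv$d[seq_len(d)] *
    sqrt(ncol(X))
  Z <- K %*% X                          # d x V, rows white
  for (r in seq_len(max_restarts)) {
    Wu <- fastica_deflate(Z, d, seed + r - 1L)
    if (!is.null(Wu)) break
  }
  if (is.null(Wu))
    stop("group_ica: fixed-point iteration failed after ", max_restarts,
         " restarts")
  S <- Wu %*% Z                         # d x V
  # deterministic orientation and order: nonnegative skewness, then by
  # explained variance of the back-projection
  sk <- apply(S, 1, function(x) mean((x - mean(x))^3))
  S <- S * ifelse(sk >= 0, 1, -1)
  A <- MASS_ginv(K) %*% t(Wu * ifelse(sk >= 0, 1, -1))  # rows x d mixing
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  S <- t(scale(t(S)))                   # Z-score each map
  list(spatial_maps = S, mixing = A, d = d, seed = seed)
}

fastica_deflate <- function(Z, d, seed, max_iter = 500, tol = 1e-9) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- ncol(Z)
  W <- matrix(0, d, nrow(Z))
  for (k in seq_len(d)) {
    w <- stats::rnorm(nrow(Z))
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      wx <- as.numeric(w %*% Z)
      g <- tanh(wx)
      gp <- 1 - g^2
      w1 <- as.numeric(Z %*% g) / n - mean(gp) * w
      if (k > 1) {
        Wp <- W[seq_len(k - 1), , drop = FALSE]
        w1 <- w1 - as.numeric(t(Wp) %*% (Wp %*% w1))
      }
      nw <- sqrt(sum(w1^2))
      if (nw < 1e-12) break
      w1 <- w1 / nw
      conv <- abs(abs(sum(w1 * w)) - 1)
      w <- w1
      if (conv < tol) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    W[k, ] <- w
  }
  W
}

# small Moore-Penrose pseudoinverse (avoids a MASS dependency)
MASS_ginv <- function(M, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Dual regression
#'
#' Stage 1 regresses every frame of the subject timeseries on the group
#' spatial maps, giving per-component timecourses; stage 2 regresses every
#' vertex's timeseries on the (variance-normalised) timecourses, giving the
#' subject's spatial maps.
#'
#' @param group_maps d x vertices matrix of group spatial maps.
#' @param subject_ts `timeseries_matrix` (or frames x vertices matrix) on
#'   the same vertex space.
#' @param normalise_timecourses scale stage-1 timecourses to unit variance
#'   before stage 2 (default TRUE).
#' @return list with `timecourses` (frames x d) and `maps` (d x vertices).
#' @export
dual_regression <- function(group_maps, subject_ts,
                            normalise_timecourses = TRUE) {
  Y <- if (inherits(subject_ts, "timeseries_matrix")) subject_ts$data
       else as.matrix(subject_ts)
  S <- group_maps
  stopifnot(ncol(Y) == ncol(S))
  G <- S %*% t(S)
  cn <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(cn)) {
    cc <- suppressWarnings(stats::cor(t(S)))
    cc[!is.finite(cc)] <- 1
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("dual_regression: group maps are rank deficient (components ",
         worst[1], " and ", worst[2], " are collinear)")
  }
  tc <- Y %*% t(S) %*% cn               # frames x d
  tcs <- tc
  if (normalise_timecourses) {
    sd_tc <- apply(tc, 2, stats::sd)
    sd_tc[sd_tc == 0] <- 1
    tcs <- sweep(tc, 2, sd_tc, "/")
  }
  maps <- solve(crossprod(tcs), t(tcs) %*% Y)   # d x vertices
  list(timecourses = tc, maps = maps)
}
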