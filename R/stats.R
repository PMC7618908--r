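#' Vertex-wise GLM t statistics
#'
#' Ordinary least squares fit of every vertex column of `Y` on the design
#' `X`, returning the t statistic for the contrast `c` at each vertex.
#' Vertices with zero residual variance receive the capped sentinel 1e6
#' (signed by the contrast estimate) and are reported in the `flagged`
#' attribute.
#'
#' @param Y subjects x vertices matrix of response maps.
#' @param X design matrix (full column rank, rows = subjects).
#' @param contrast numeric contrast vector over design columns.
#' @return numeric t-statistic vector (length = vertices).
#' @export
fit_glm <- function(Y, X, contrast) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(nrow(Y) == n, length(contrast) == p, n > p)
  XtXi <- solve(crossprod(X))
  if (!is.finite(sum(XtXi)))
    stop("fit_glm: design matrix is rank deficient")
  B <- XtXi %*% crossprod(X, Y)                    # p x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  cb <- as.numeric(contrast %*% B)
  se <- sqrt(pmax(sigma2, 0) * as.numeric(t(contrast) %*% XtXi %*% contrast))
  t <- ifelse(se > 0, cb / se, sign(cb) * 1e6)
  attr(t, "flagged") <- which(se == 0)
  t
}

#' Build a design matrix from a covariate table
#'
#' Intercept plus the standard explanatory variables (GA at birth, PMA at
#' scan, sex, birthweight Z, total brain volume, hemispheric volume
#' asymmetry). Nuisance columns are mean-centred by default so the
#' intercept contrast tests the cohort mean of the response, as in
#' PALM-style one-sample designs.
#'
#' @param covariates data.frame in the [read_covariates()] layout.
#' @param columns covariate columns to include (default all six).
#' @param center mean-centre the covariate columns (default TRUE).
#' @return numeric design matrix with an `intercept` first column.
#' @export
make_design <- function(covariates,
                        columns = c("ga_weeks", "pma_weeks", "sex", "bwz",
                                    "tbv_cm3", "hemi_vol_asym_cm3"),
                        center = TRUE) {
  M <- as.matrix(covariates[, columns, drop = FALSE])
  if (center) M <- sweep(M, 2, colMeans(M))
  cbind(intercept = 1, M)
}

#' TFCE parameter bundle
#'
#' @param H height exponent (default 2.0).
#' @param E extent exponent (default 0.6).
#' @param dh threshold step; `NULL` means `max(stat) / 100`, fixed across
#'   the permutations of one analysis.
#' @param areas per-vertex areas in mm^2 (group-average midthickness vertex
#'   areas), as a `metric_map` or numeric vector.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2.0, E = 0.6, dh = NULL, areas = NULL) {
  stopifnot(H > 0, E > 0, is.null(dh) || dh > 0)
  structure(list(H = H, E = E, dh = dh, areas = areas),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement on a mesh
#'
#' For thresholds `h = dh, 2 dh, ..., max(stat)`, vertices with
#' `stat >= h` are grouped into connected components of the mesh vertex
#' adjacency, and every member vertex accumulates
#' `area(component)^E * h^H * dh`, where the component area is the sum of
#' its vertices' areas. Output is 0 wherever `stat <= 0`; raising any input
#' value never lowers any output value.
#'
#' @param stat `metric_map` or numeric vector of statistics.
#' @param mesh `spherical_mesh` supplying the adjacency.
#' @param params `tfce_params`; `params$areas` defaults to unit-sphere
#'   vertex areas of `mesh`.
#' @return numeric TFCE vector.
#' @export
tfce <- function(stat, mesh, params = tfce_params()) {
  v <- if (inherits(stat, "metric_map")) stat$values else as.numeric(stat)
  areas <- params$areas %||% vertex_areas(mesh)$values
  if (inherits(areas, "metric_map")) areas <- areas$values
  dh <- params$dh %||% (max(v) / 100)
  if (!is.null(params$dh) && params$dh <= 0) stop("tfce: dh must be > 0")
  if (dh <= 0) return(numeric(length(v)))
  E <- mesh_edges(mesh)
  .tfce_cpp(v, E, areas, params$H, params$E, dh)
}

#' Reference TFCE implementation (independent threshold sweep)
#'
#' Direct per-threshold connected-component sweep written in plain R with
#' the same accumulation order as the production kernel; used as the
#' independent oracle for bit-for-bit equivalence tests on small meshes.
#'
#' @inheritParams tfce
#' @export
tfce_reference <- function(stat, mesh, params = tfce_params()) {
  v <- if (inherits(stat, "metric_map")) stat$values else as.numeric(stat)
  areas <- params$areas %||% vertex_areas(mesh)$values
  if (inherits(areas, "metric_map")) areas <- areas$values
  dh <- params$dh %||% (max(v) / 100)
  out <- numeric(length(v))
  if (dh <= 0 || max(v) <= 0) return(out)
  E <- mesh_edges(mesh)
  nh <- floor(max(v) / dh + 1e-12)
  nb <- mesh_neighbours(mesh)
  for (k in seq_len(nh)) {
    h <- k * dh
    supra <- which(v >= h)
    lab <- integer(length(v))
    nxt <- 0L
    for (s in supra) {
      if (lab[s] != 0L) next
      nxt <- nxt + 1L
      queue <- s
      lab[s] <- nxt
      while (length(queue)) {
        x <- queue[[1]]
        queue <- queue[-1]
        for (y in nb[[x]]) {
          if (v[y] >= h && lab[y] == 0L) {
            lab[y] <- nxt
            queue <- c(queue, y)
          }
        }
      }
    }
    # component areas accumulated in ascending vertex order (as the C++
    # kernel does) so the floating-point sums agree bitwise
    carea <- numeric(nxt)
    for (s in supra) carea[lab[s]] <- carea[lab[s]] + areas[s]
    hh <- h^params$H
    for (s in supra) out[s] <- out[s] + carea[lab[s]]^params$E * hh * dh
  }
  out
}

#' Permutation inference with TFCE and joint FWE correction
#'
#' Computes observed t and TFCE maps for every feature and contrast, then
#' builds the null distribution of the maximum TFCE statistic over
#' vertices, features and contrasts under a shared permutation schedule:
#' sign flipping of (nuisance-residualised) data for one-sample designs, or
#' Freedman-Lane residual permutation for general designs. FWE-corrected
#' p-values use the `(1 + #{null >= observed}) / (1 + n_perm)` convention,
#' so p is never below `1 / (n_perm + 1)`.
#'
#' @param features named list of subjects x vertices matrices (one per
#'   image feature), all sharing the subject order of `X`.
#' @param X design matrix.
#' @param contrasts named list of contrast vectors; one-sided, applied to
#'   the signed t statistic (pair `c` with `-c` for the two directions).
#' @param mesh `spherical_mesh` for the TFCE adjacency.
#' @param params `tfce_params`; `dh` fixed per feature x contrast at
#'   `max(observed)/100` and reused across permutations.
#' @param n_perm number of random shuffles (default 500 at desk scale; the
#'   full-scale analysis value is 10000).
#' @param seed integer seed (mandatory).
#' @param scheme `"sign_flip"` or `"freedman_lane"`.
#' @return list of class `stat_result`: per feature x contrast `t`, `tfce`,
#'   `neg_log10_p` maps, plus `null_max`, `n_perm`, `seed`, `dh`.
#' @export
permutation_test <- function(features, X, contrasts, mesh,
                             params = tfce_params(), n_perm = 500, seed,
                             scheme = c("sign_flip", "freedman_lane")) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("permutation_test: seed is mandatory")
  if (n_perm < 100) warning("permutation_test: n_perm < 100")
  X <- as.matrix(X)
  n <- nrow(X)
  if (scheme == "sign_flip") {
    for (cn in names(contrasts)) {
      cv <- contrasts[[cn]]
      nz <- which(cv != 0)
      if (length(nz) != 1 || !all(X[, nz] == 1))
        stop("permutation_test: sign_flip requires intercept-only contrasts",
             " (contrast '", cn, "' is not)")
    }
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  E <- mesh_edges(mesh)
  areas <- params$areas %||% vertex_areas(mesh)$values
  if (inherits(areas, "metric_map")) areas <- areas$values

  # residualise on nuisance once per contrast (Freedman-Lane / sign-flip of
  # residualised data); the reduced model excludes the contrast columns
  setup <- list()
  for (fn in names(features)) for (cn in names(contrasts)) {
    Y <- as.matrix(features[[fn]])
    cv <- contrasts[[cn]]
    nz <- which(cv != 0)
    Z <- X[, -nz, drop = FALSE]
    if (ncol(Z) > 0) {
      Hz <- Z %*% solve(crossprod(Z), t(Z))
      Rz <- Y - Hz %*% Y
    } else {
      Hz <- matrix(0, n, n)
      Rz <- Y
    }
    t_obs <- fit_glm(Y, X, cv)
    dh <- params$dh %||% (max(c(t_obs, 0)) / 100)
    tf_obs <- if (dh > 0) .tfce_cpp(t_obs, E, areas, params$H, params$E, dh)
              else numeric(length(t_obs))
    setup[[paste(fn, cn, sep = ":")]] <-
      list(feature = fn, contrast = cn, Y = Y, cv = cv, Z = Z, Hz = Hz,
           Rz = Rz, t = t_obs, tfce = tf_obs, dh = dh)
  }
  # contrasts that differ only in sign share one GLM fit per permutation
  XtXi <- solve(crossprod(X))
  base_of <- list()
  for (key in names(setup)) {
    s <- setup[[key]]
    k1 <- paste(format(s$cv, digits = 15), collapse = ",")
    k2 <- paste(format(-s$cv, digits = 15), collapse = ",")
    canon <- min(k1, k2)
    setup[[key]]$sign <- if (k1 == canon) 1 else -1
    setup[[key]]$gkey <- paste(s$feature, canon)
    if (is.null(base_of[[setup[[key]]$gkey]]))
      base_of[[setup[[key]]$gkey]] <-
        list(cv = s$cv * setup[[key]]$sign, Rz = s$Rz, Hz = s$Hz, Y = s$Y)
  }
  np <- ncol(X)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    if (scheme == "sign_flip") {
      flip <- sample(c(-1, 1), n, replace = TRUE)
    } else {
      perm <- sample(n)
    }
    tcache <- list()
    for (g in names(base_of)) {
      b <- base_of[[g]]
      Yp <- if (scheme == "sign_flip") flip * b$Rz
            else b$Hz %*% b$Y + b$Rz[perm, , drop = FALSE]
      B <- XtXi %*% crossprod(X, Yp)
      resid <- Yp - X %*% B
      sigma2 <- colSums(resid^2) / (n - np)
      cb <- as.numeric(b$cv %*% B)
      se <- sqrt(pmax(sigma2, 0) *
                 as.numeric(t(b$cv) %*% XtXi %*% b$cv))
      tcache[[g]] <- ifelse(se > 0, cb / se, sign(cb) * 1e6)
    }
    mx <- 0
    for (s in setup) {
      if (s$dh > 0) {
        tf <- .tfce_cpp(s$sign * tcache[[s$gkey]], E, areas, params$H,
                        params$E, s$dh)
        m1 <- max(tf)
        if (m1 > mx) mx <- m1
      }
    }
    null_max[p] <- mx
  }
  out <- list()
  for (key in names(setup)) {
    s <- setup[[key]]
    cnt <- 1 + vapply(s$tfce, function(o) sum(null_max >= o), 0)
    pmap <- cnt / (1 + n_perm)
    out[[key]] <- list(feature = s$feature, contrast = s$contrast,
                       t = s$t, tfce = s$tfce,
                       neg_log10_p = -log10(pmap), p = pmap, dh = s$dh)
  }
  structure(list(results = out, null_max = null_max, n_perm = n_perm,
                 seed = seed, scheme = scheme,
                 H = params$H, E = params$E),
            class = "stat_result")
}

#' Significance mask from FWE-corrected p-values
#'
#' Strict threshold on the corrected map: a vertex is significant when
#' `-log10(p) > -log10(alpha)` (1.301 for alpha = 0.05, the conventional
#' 1.3 cut-off).
#'
#' @param result single entry of a `stat_result` (or any list with a
#'   `neg_log10_p` field), or a numeric `-log10(p)` vector.
#' @param alpha significance level (default 0.05).
#' @return logical vertex mask.
#' @export
significance_mask <- function(result, alpha = 0.05) {
  v <- if (is.numeric(result)) result else result$neg_log10_p
  v > -log10(alpha)
}

#' Cohort demographic tests
#'
#' One-sample t-test on hemispheric volume asymmetry within each group,
#' two-sample Welch t-tests on continuous covariates between groups, and a
#' chi-squared independence test on sex by group, with medians and
#' interquartile ranges per group.
#'
#' @param covariates data.frame in the [read_covariates()] layout.
#' @param group factor or column name (`"group"`) splitting the cohort.
#' @return list with `asymmetry` (per-group one-sample t), `continuous`
#'   (per-variable two-sample tests), `sex` (chi-squared), `summary`
#'   (median/IQR table).
#' @export
cohort_stats <- function(covariates, group = "group") {
  g <- if (is.character(group) && length(group) == 1)
         factor(covariates[[group]]) else factor(group)
  if (nlevels(g) < 1 || any(table(g) < 2))
    stop("cohort_stats: every group needs at least 2 subjects")
  one_sample <- lapply(split(covariates$hemi_vol_asym_cm3, g), function(x) {
    if (stats::sd(x) == 0) {
      list(t = 0, p = 1, mean = mean(x))
    } else {
      tt <- stats::t.test(x)
      list(t = unname(tt$statistic), p = tt$p.value, mean = mean(x))
    }
  })
  cont_vars <- intersect(c("ga_weeks", "pma_weeks", "bwz", "tbv_cm3",
                           "hemi_vol_asym_cm3"), names(covariates))
  continuous <- NULL
  sexres <- NULL
  if (nlevels(g) == 2) {
    continuous <- lapply(cont_vars, function(v) {
      a <- covariates[[v]][g == levels(g)[1]]
      b <- covariates[[v]][g == levels(g)[2]]
      if (stats::sd(c(a, b)) == 0)
        return(list(variable = v, t = 0, p = 1))
      tt <- stats::t.test(a, b)
      list(variable = v, t = unname(tt$statistic), p = tt$p.value)
    })
    names(continuous) <- cont_vars
    tab <- table(g, covariates$sex)
    sx <- suppressWarnings(stats::chisq.test(tab))
    sexres <- list(statistic = unname(sx$statistic), p = sx$p.value,
                   table = tab)
  }
  summ <- do.call(rbind, lapply(levels(g), function(l) {
    d <- covariates[g == l, cont_vars, drop = FALSE]
    data.frame(group = l, variable = cont_vars,
               median = vapply(d, stats::median, 0),
               iqr_lo = vapply(d, function(x) stats::quantile(x, 0.25), 0),
               iqr_hi = vapply(d, function(x) stats::quantile(x, 0.75), 0))
  }))
  list(asymmetry = one_sample, continuous = continuous, sex = sexres,
       summary = summ)
}
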