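#' Real spherical harmonics evaluated at unit vectors
#'
#' Orthonormal real spherical harmonics Y_lm on the unit sphere
#' (\eqn{\int Y_{lm}^2 d\Omega = 1}), used by the synthetic-field generator
#' and by the closed-form heat-kernel attenuation checks: Y_lm is an
#' eigenfunction of the Laplace-Beltrami operator with eigenvalue
#' \eqn{-l(l+1)}.
#'
#' @param l degree (0 <= l).
#' @param m order (-l <= m <= l); negative orders are the sine harmonics.
#' @param xyz n x 3 matrix of unit vectors.
#' @return numeric vector of length n.
#' @export
real_sph_harm <- function(l, m, xyz) {
  stopifnot(l >= 0, abs(m) <= l)
  xyz <- as.matrix(xyz)
  z <- xyz[, 3]
  phi <- atan2(xyz[, 2], xyz[, 1])
  am <- abs(m)
  P <- assoc_legendre(l, am, z)
  K <- sqrt((2 * l + 1) / (4 * pi) *
            exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  if (m > 0) sqrt(2) * K * cos(am * phi) * P
  else if (m < 0) sqrt(2) * K * sin(am * phi) * P
  else K * P
}

# P_l^m(x) by the standard upward recurrence in l (stable for l <= ~30)
assoc_legendre <- function(l, m, x) {
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# band-limited field: sum over degrees in band of random harmonics, scaled so
# the field has zero spherical mean and unit pointwise variance in expectation
band_limited_field <- function(xyz, band, rng_coefs) {
  stopifnot(band[1] >= 1)
  f <- numeric(nrow(xyz))
  k <- 0L
  for (l in band[1]:band[2]) for (m in (-l):l) {
    k <- k + 1L
    f <- f + rng_coefs[k] * real_sph_harm(l, m, xyz)
  }
  f * sqrt(4 * pi) / sqrt(sum(rng_coefs[seq_len(k)]^2))
}

n_band_coefs <- function(band) {
  sum(2 * (band[1]:band[2]) + 1)
}
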