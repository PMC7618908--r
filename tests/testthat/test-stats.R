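test_that("GLM t statistics match closed forms", {
  set.seed(1)
  n <- 18
  Y <- matrix(rnorm(n * 40), n)
  # intercept-only equals the classic one-sample t
  t1 <- fit_glm(Y, matrix(1, n, 1), 1)
  classic <- apply(Y, 2, function(y) mean(y) / (sd(y) / sqrt(n)))
  expect_equal(as.numeric(t1), classic, tolerance = 1e-10)
  # group indicator equals the pooled-variance two-sample t
  g <- rep(c(0, 1), each = n / 2)
  X2 <- cbind(1, g)
  t2 <- fit_glm(Y, X2, c(0, 1))
  pooled <- apply(Y, 2, function(y) {
    a <- y[g == 1]; b <- y[g == 0]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (n - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  })
  expect_equal(as.numeric(t2), pooled, tolerance = 1e-10)
  # adding a column orthogonal to the design leaves the contrast estimate
  # untouched; the t statistic rescales only through the residual df
  z <- rnorm(n)
  z <- z - X2 %*% solve(crossprod(X2), crossprod(X2, z))
  t3 <- fit_glm(Y, cbind(X2, as.numeric(z)), c(0, 1, 0))
  b2 <- solve(crossprod(X2), crossprod(X2, Y))[2, ]
  b3 <- solve(crossprod(cbind(X2, as.numeric(z))),
              crossprod(cbind(X2, as.numeric(z)), Y))[2, ]
  expect_equal(b3, b2, tolerance = 1e-10)
  expect_equal(sign(as.numeric(t3)), sign(as.numeric(t2)))
  # zero-variance vertex gets the capped sentinel
  Yc <- Y
  Yc[, 1] <- 2
  tc <- fit_glm(Yc, matrix(1, n, 1), 1)
  expect_equal(as.numeric(tc[1]), 1e6)
  expect_identical(attr(tc, "flagged"), 1L)
})

test_that("TFCE matches the single-vertex closed form and brute force", {
  m <- oct2
  areas <- vertex_areas(sphere_surface(m, 1))$values
  # single isolated suprathreshold vertex
  v <- numeric(m$V)
  v[5] <- 1.7
  dh <- 0.05
  got <- tfce(v, m, tfce_params(dh = dh, areas = areas))
  ks <- seq_len(ceiling(v[5] / dh))
  ks <- ks[ks * dh <= v[5]]          # thresholds k dh <= s, float-exact
  closed <- sum(areas[5]^0.6 * (ks * dh)^2 * dh)
  expect_equal(got[5], closed, tolerance = 1e-12)
  expect_true(all(got[-5] == 0))
  # all-zero map
  expect_identical(tfce(numeric(m$V), m, tfce_params(dh = 1)), numeric(m$V))
  # negative statistics contribute nothing
  vn <- v
  vn[10] <- -3
  expect_identical(tfce(vn, m, tfce_params(dh = dh, areas = areas))[10], 0)
  expect_error(tfce(v, m, tfce_params(dh = -1)), "dh")
})

test_that("TFCE is monotone and splitting components never raises values", {
  m <- oct2
  areas <- vertex_areas(sphere_surface(m, 1))$values
  set.seed(2)
  v <- pmax(rnorm(m$V), 0)
  pr <- tfce_params(dh = max(v) / 40, areas = areas)
  base <- tfce(v, m, pr)
  # raising one value never lowers any output
  v2 <- v
  i <- sample(which(v > 0), 1)
  v2[i] <- v2[i] + 0.5
  up <- tfce(v2, m, pr)
  expect_true(all(up >= base - 1e-12))
  # zeroing a cut vertex: remaining vertices never increase
  cut <- which(v > 0)[3]
  v3 <- v
  v3[cut] <- 0
  down <- tfce(v3, m, pr)
  expect_true(all(down[-cut] <= base[-cut] + 1e-12))
})

test_that("permutation p-values respect the lower bound and saturate", {
  m <- oct2
  set.seed(3)
  n <- 30
  mask <- cap_mask(m, c(0, 0, 1), 30)
  Y <- matrix(rnorm(n * m$V, 0, 0.05), n)
  Y[, mask] <- Y[, mask] + 0.5           # effect 10x the noise sd
  res <- permutation_test(list(f = Y), matrix(1, n, 1), list(C1 = 1),
                          m, tfce_params(), n_perm = 500, seed = 4,
                          scheme = "sign_flip")
  r <- res$results[[1]]
  expect_true(all(r$p >= 1 / 501))
  expect_equal(min(r$p[mask]), 1 / 501)
  expect_true(all(significance_mask(r)[mask]))
  # sign_flip refuses non-intercept contrasts
  expect_error(permutation_test(list(f = Y), cbind(1, rnorm(n)),
                                list(C = c(0, 1)), m, tfce_params(),
                                n_perm = 100, seed = 1,
                                scheme = "sign_flip"),
               "intercept")
  expect_warning(permutation_test(list(f = Y), matrix(1, n, 1),
                                  list(C1 = 1), m, tfce_params(),
                                  n_perm = 50, seed = 1,
                                  scheme = "sign_flip"),
                 "n_perm")
})

test_that("Freedman-Lane detects a group difference and controls nulls", {
  m <- oct2
  set.seed(5)
  n <- 24
  g <- rep(c(0, 1), each = n / 2)
  z <- rnorm(n)
  mask <- cap_mask(m, c(1, 0, 0), 30)
  Y <- matrix(rnorm(n * m$V, 0, 0.1), n) + outer(0.3 * z, rep(1, m$V))
  Y[g == 1, mask] <- Y[g == 1, mask] + 0.6
  X <- cbind(1, g, z)
  res <- permutation_test(list(f = Y), X,
                          list(Cg = c(0, 1, 0)), m, tfce_params(),
                          n_perm = 300, seed = 6,
                          scheme = "freedman_lane")
  r <- res$results[[1]]
  expect_true(any(significance_mask(r)[mask]))
  expect_false(any(significance_mask(r)[!mask]))
})

test_that("joint FWE across more features never decreases p-values", {
  m <- oct2
  set.seed(7)
  n <- 16
  Y1 <- matrix(rnorm(n * m$V), n)
  Y2 <- matrix(rnorm(n * m$V), n)
  X <- matrix(1, n, 1)
  one <- permutation_test(list(a = Y1), X, list(C = 1), m, tfce_params(),
                          n_perm = 200, seed = 8, scheme = "sign_flip")
  both <- permutation_test(list(a = Y1, b = Y2), X, list(C = 1), m,
                           tfce_params(), n_perm = 200, seed = 8,
                           scheme = "sign_flip")
  expect_true(all(both$results[["a:C"]]$p >= one$results[["a:C"]]$p - 1e-12))
})

test_that("significance rule: strict 1.3-style threshold", {
  expect_false(significance_mask(-log10(0.05)))
  expect_true(significance_mask(-log10(0.049)))
  expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)
  expect_identical(significance_mask(c(1.2, 1.31)), c(FALSE, TRUE))
})

test_that("cohort demographic tests cover the degenerate cases", {
  set.seed(9)
  n <- 40
  cov <- data.frame(subject_id = seq_len(n), ga_weeks = rnorm(n, 40),
                    pma_weeks = rnorm(n, 41), sex = rep(c(0, 1), n / 2),
                    bwz = rnorm(n), tbv_cm3 = rnorm(n, 340, 30),
                    hemi_vol_asym_cm3 = rnorm(n, -1.8, 1.5),
                    group = rep(c("term", "preterm"), each = n / 2))
  out <- cohort_stats(cov)
  expect_named(out$asymmetry, c("preterm", "term"))
  expect_true(all(vapply(out$continuous, function(x) x$p, 0) >= 0))
  # all-zero asymmetry gives t = 0, p = 1
  cov0 <- cov
  cov0$hemi_vol_asym_cm3 <- 0
  out0 <- cohort_stats(cov0)
  expect_equal(out0$asymmetry$term$t, 0)
  expect_equal(out0$asymmetry$term$p, 1)
  # identical groups give two-sample t = 0
  cov1 <- cov
  cov1$tbv_cm3 <- rep(cov$tbv_cm3[1:(n / 2)], 2)
  o1 <- cohort_stats(cov1)
  expect_equal(o1$continuous$tbv_cm3$t, 0, tolerance = 1e-12)
  # balanced 2x2 sex table: chi-squared statistic 0, p 1
  expect_equal(out$sex$statistic,
               suppressWarnings(unname(chisq.test(table(cov$group,
                                                        cov$sex))$statistic)))
  tab <- matrix(c(10, 10, 10, 10), 2)
  ch <- suppressWarnings(chisq.test(tab))
  expect_equal(unname(ch$statistic), 0)
  expect_equal(ch$p.value, 1)
  expect_error(cohort_stats(cov[1, ]), "at least 2")
})

test_that("null p-values are super-uniform at a fixed vertex", {
  # small but real exchangeability check: empirical CDF at 0.05 of the
  # minimum-cost vertex p-value under pure noise
  m <- oct2
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    Y <- matrix(rnorm(12 * m$V), 12)
    res <- permutation_test(list(f = Y), matrix(1, 12, 1), list(C = 1),
                            m, tfce_params(), n_perm = 100,
                            seed = 200 + r, scheme = "sign_flip")
    hits <- hits + (res$results[[1]]$p[1] <= 0.05)
  }
  expect_lte(hits / reps, 0.12)   # 0.05 + binomial slack at 60 replicates
})
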