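test_that("perceptual distance reduces to Euclidean for the identity model", {
  idc <- lnl_cascade(lnl_layer(diag(3)))
  xA <- c(1, 2, 3); xB <- c(0, 4, 2)
  expect_equal(perceptual_distance(xA, xA, idc), 0)
  expect_equal(perceptual_distance(xA, xB, idc), sqrt(sum((xA - xB)^2)))
  expect_equal(unclass(perceptual_metric(xA, idc)), diag(3),
               ignore_attr = TRUE)
})

test_that("the metric is the symmetric PSD second-order model of the distance", {
  set.seed(2)
  m <- build_cartoon_model()
  xA <- c(30, 50, 40)
  M <- perceptual_metric(xA, m)
  expect_equal(unclass(M), t(unclass(M)))
  expect_true(all(eigen(unclass(M), symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # quadratic-form agreement improves as O(||dx||^3): log-log slope ~ 3
  dx <- rnorm(3); dx <- dx / sqrt(sum(dx^2))
  hs <- c(1, 0.5, 0.25, 0.125)
  errs <- vapply(hs, function(h) {
    d_true <- perceptual_distance(xA, xA + h * dx, m)
    d_quad <- sqrt(as.numeric(t(h * dx) %*% unclass(M) %*% (h * dx)))
    abs(d_true^2 - d_quad^2)
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(hs)))[2]
  expect_gt(slope, 2.5)
})

test_that("patch-wise metrics are the block-diagonal of per-patch metrics", {
  set.seed(12)
  d <- 4   # two patches of 2 pixels, model acts per patch
  casc <- random_cascade(c(2, 2), kinds = "dn")
  x <- random_drive(4, 0.3)
  patches <- list(1:2, 3:4)
  M <- perceptual_metric(x, casc, patches = patches)
  expect_equal(unclass(M)[1:2, 1:2],
               unclass(perceptual_metric(x[1:2], casc)), ignore_attr = TRUE)
  expect_true(all(unclass(M)[1:2, 3:4] == 0))
  # and the patch distance adds squared per-patch distances
  y <- x + 0.01 * rnorm(4)
  expect_equal(perceptual_distance(x, y, casc, patches = patches)^2,
               perceptual_distance(x[1:2], y[1:2], casc)^2 +
                 perceptual_distance(x[3:4], y[3:4], casc)^2)
})

test_that("sensitivity equals the squared Jacobian volume and its closed form", {
  idc <- lnl_cascade(lnl_layer(diag(3)))
  expect_equal(sensitivity(c(1, 1, 1), idc), 1)
  m <- build_cartoon_model()
  set.seed(22)
  for (i in 1:10) {
    x0 <- runif(3, 5, 120)
    s_gen <- sensitivity(x0, m)
    expect_equal(s_gen, cartoon_sensitivity(x0, m), tolerance = 1e-8)
    # internal consistency with singular values
    J <- jacobian_stimulus(m, x0)
    expect_equal(s_gen, prod(svd(J)$d^2), tolerance = 1e-8)
  }
  # rank deficiency reports 0 with a flag
  flat <- lnl_cascade(lnl_layer(matrix(c(1, 1, 0, 0), 2, 2)))
  s0 <- sensitivity(c(1, 2), flat)
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "rank_deficient"))
})

test_that("sensitivity decreases along a mean-luminance ladder", {
  m <- build_cartoon_model()   # gamma1 < 1
  set.seed(32)
  z <- rnorm(3); z <- (z - mean(z)) / sd(z)
  lums <- seq(20, 100, length.out = 8)
  sens <- vapply(lums, function(l) sensitivity(l * (1 + 0.3 * z), m),
                 numeric(1))
  expect_true(all(diff(sens) < 0))
})

test_that("delta-MI is exactly additive and matches the Gaussian closed form", {
  set.seed(42)
  S <- 0.9^abs(outer(0:2, 0:2, `-`))
  X <- matrix(rnorm(3 * 20000), 20000, 3) %*% chol(S)
  idc <- lnl_cascade(lnl_layer(diag(3)))
  r0 <- delta_multi_information(idc, X, jac_subsample = 10, seed = 1)
  expect_equal(r0$delta_mi, 0)   # identical marginals, unit Jacobian
  expect_equal(r0$delta_mi, r0$delta_h + r0$jac_term)
  A <- matrix(c(1, 0.5, 0.2, 0, 1, 0.3, 0.1, 0, 1), 3, byrow = TRUE)
  lc <- lnl_cascade(lnl_layer(A))
  r1 <- delta_multi_information(lc, X, jac_subsample = 10, seed = 1)
  mi_g <- function(Sig) 0.5 * log2(prod(diag(Sig)) / det(Sig))
  oracle <- mi_g(S) - mi_g(A %*% S %*% t(A))
  # 0.015 ~ 3 s.d. of the histogram estimator at n = 2e4 (measured a priori)
  expect_lt(abs(r1$delta_mi - oracle), 0.015)
  # non-square cascades are rejected
  rect <- lnl_cascade(lnl_layer(matrix(rnorm(6), 2, 3)))
  expect_error(delta_multi_information(rect, X), "square")
})

test_that("filter-uncertainty impacts match the cartoon closed form and trends", {
  m <- build_cartoon_model()
  set.seed(52)
  samples <- generate_three_pixel_ensemble(6, lum = 40, con = 0.4, seed = 3)
  # zero perturbation, zero impact
  imp0 <- filter_uncertainty_impact(m, layer = 2, filter_row = 2,
                                    perturbation = c(0, 0, 0), samples)
  expect_true(all(imp0$impact == 0))
  # generic machinery equals the closed form (identity kernel confines the
  # impact to the perturbed sensor); a perturbation dF of the analyzer row
  # reaches L2 = G F as G_kk * dF
  dF <- c(0.02, -0.01, 0.015)
  G <- attr(m, "cartoon")$G
  for (k in 1:3) {
    imp <- filter_uncertainty_impact(m, 2, k, G[k, k] * dF, samples)
    for (i in seq_len(nrow(samples))) {
      expect_equal(imp$impact[imp$sample == i & imp$sensor == k],
                   cartoon_filter_impact(samples[i, ], m, k, dF),
                   tolerance = 1e-8)
      expect_lt(max(abs(imp$impact[imp$sample == i & imp$sensor != k])),
                1e-12)
    }
  }
  # AC impact grows with luminance (sub-saturation, low-contrast regime),
  # DC impact shrinks; raising contrast suppresses the AC impact
  z <- c(-1, 0.2, 0.8); z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  lums <- seq(20, 100, length.out = 6)
  ladder <- t(vapply(lums, function(l) l * (1 + 0.02 * z), numeric(3)))
  imp_ac <- filter_uncertainty_impact(m, 2, 2, dF, ladder)
  ac <- abs(imp_ac$impact[imp_ac$sensor == 2])
  expect_true(all(diff(ac) > 0))
  imp_dc <- filter_uncertainty_impact(m, 2, 1, dF, ladder)
  dc <- abs(imp_dc$impact[imp_dc$sensor == 1])
  expect_true(all(diff(dc) < 0))
  cons <- c(0.05, 0.1, 0.2, 0.4)
  crow <- t(vapply(cons, function(cc) 60 * (1 + cc * z), numeric(3)))
  imp_c <- filter_uncertainty_impact(m, 2, 2, dF, crow)
  expect_true(all(diff(abs(imp_c$impact[imp_c$sensor == 2])) < 0))
})
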