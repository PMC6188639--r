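test_that("distance gradient matches FD and degenerates gracefully", {
  m <- build_cartoon_model()
  xA <- c(30, 50, 40); xB <- c(32, 48, 41)
  g <- perceptual_distance_gradient(xB, xA, m)
  gfd <- fd_jacobian(function(v) perceptual_distance(xA, v, m), xB)
  expect_lt(max_rel_err(g, as.numeric(gfd)), 1e-5)
  # identity model: unit direction
  idc <- lnl_cascade(lnl_layer(diag(3)))
  gi <- perceptual_distance_gradient(xB, xA, idc)
  expect_equal(gi, (xB - xA) / sqrt(sum((xB - xA)^2)))
  # zero distance flagged
  g0 <- perceptual_distance_gradient(xA, xA, m)
  expect_true(attr(g0, "zero_distance"))
  expect_true(all(g0 == 0))
  # operator-norm bound: |grad| <= largest singular value of J
  expect_lte(sqrt(sum(g^2)), max(svd(jacobian_stimulus(m, xB))$d) + 1e-12)
})

test_that("mad_step stays on the sphere and fixes identity-model iterates", {
  set.seed(4)
  m <- build_cartoon_model()
  xA <- c(30, 50, 40)
  prob <- mad_problem(xA, radius = 2, seed = 1)
  noise <- rnorm(3)
  x_m <- xA + 2 * noise / sqrt(sum(noise^2))
  for (dir in c("max", "min")) {
    xn <- mad_step(x_m, prob, m, dir)
    expect_lt(abs(sqrt(sum((xn - xA)^2)) - 2), 1e-8)
  }
  # lambda = 0 leaves the point unchanged
  expect_equal(mad_step(x_m, prob, m, "max", lambda = 0), x_m)
  # identity model: the gradient is radial, so the iterate is a fixed point
  idc <- lnl_cascade(lnl_layer(diag(3)))
  expect_equal(mad_step(x_m, prob, idc, "max"), x_m, tolerance = 1e-10)
})

test_that("mad_run produces monotone traces bracketing the initial distance", {
  set.seed(14)
  casc <- random_cascade(c(5, 5), kinds = "dn")
  xA <- random_drive(5, 0.5)
  prob <- mad_problem(xA, radius = 0.3, max_iter = 60, seed = 2)
  tr <- mad_run(prob, casc)
  expect_true(all(diff(tr$max$distances) >= -1e-12))
  expect_true(all(diff(tr$min$distances) <= 1e-12))
  expect_gte(max(tr$max$distances), tr$max$distances[1])
  expect_lte(min(tr$min$distances), tr$min$distances[1])
  expect_gte(max(tr$max$distances), min(tr$min$distances))
  # every stored distance corresponds to a point on the sphere
  expect_lt(abs(sqrt(sum((tr$max$final - xA)^2)) - 0.3), 1e-8)
  expect_lt(abs(sqrt(sum((tr$min$final - xA)^2)) - 0.3), 1e-8)
})

test_that("on a fixed-metric model the search attains the eigenvalue bounds", {
  set.seed(24)
  d <- 8
  A <- matrix(rnorm(d * d), d)
  M <- crossprod(A) / d
  eg <- eigen(M, symmetric = TRUE)
  Msqrt <- eg$vectors %*% (sqrt(eg$values) * t(eg$vectors))
  surro <- lnl_cascade(lnl_layer(Msqrt))
  xA <- rnorm(d)
  prob <- mad_problem(xA, radius = 0.5, max_iter = 400, seed = 3)
  tr <- mad_run(prob, surro)
  expect_equal(max(tr$max$distances), 0.5 * sqrt(eg$values[1]),
               tolerance = 0.01)
  expect_equal(min(tr$min$distances), 0.5 * sqrt(eg$values[d]),
               tolerance = 0.01)
  # second-order regime: eigen-MAD quadratic forms bound the achieved values
  em <- eigen_mad(xA, surro, 0.5)
  expect_equal(perceptual_distance(em$worst, xA, surro),
               max(tr$max$distances), tolerance = 0.01)
})

test_that("eigen-MAD beats random directions and ties are flagged", {
  set.seed(34)
  d <- 8
  A <- matrix(rnorm(d * d), d)
  surro <- lnl_cascade(lnl_layer(A))
  xA <- rnorm(d)
  em <- eigen_mad(xA, surro, radius = 1)
  M <- unclass(perceptual_metric(xA, surro))
  qf_max <- as.numeric(t(em$v_max) %*% M %*% em$v_max)
  qf_min <- as.numeric(t(em$v_min) %*% M %*% em$v_min)
  V <- matrix(rnorm(d * 10000), d)
  V <- V / rep(sqrt(colSums(V^2)), each = d)
  qf_rand <- colSums(V * (M %*% V))
  expect_gte(qf_max, max(qf_rand))
  expect_lte(qf_min, min(qf_rand))
  # isotropic metric: every direction ties
  idc <- lnl_cascade(lnl_layer(diag(3)))
  em_id <- eigen_mad(c(1, 2, 3), idc, radius = 1)
  expect_true(attr(em_id, "tie"))
  # diagonal metric diag(4, 1): max along axis 1, distance 2 * radius
  dg <- lnl_cascade(lnl_layer(diag(c(2, 1))))
  em_dg <- eigen_mad(c(0, 0), dg, radius = 1.5)
  expect_equal(abs(em_dg$v_max), c(1, 0))
  expect_equal(perceptual_distance(em_dg$worst, c(0, 0), dg), 3)
})

test_that("patch-block eigen solution equals the dense one for separable models", {
  set.seed(44)
  casc <- random_cascade(c(3, 3), kinds = "dn")  # acts on each 3-pixel patch
  x <- random_drive(6, 0.4)
  patches <- list(1:3, 4:6)
  em_patch <- eigen_mad(x, casc, radius = 0.2, patches = patches)
  # dense equivalent: block-diagonal metric assembled by the patch machinery
  M <- unclass(perceptual_metric(x, casc, patches = patches))
  eg <- eigen(M, symmetric = TRUE)
  expect_equal(em_patch$lambda_max, eg$values[1], tolerance = 1e-10)
  expect_equal(em_patch$lambda_min, eg$values[6], tolerance = 1e-10)
  expect_equal(abs(em_patch$v_max), abs(eg$vectors[, 1]), tolerance = 1e-8)
})
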