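test_that("finite-difference oracle behaves as a second-order scheme", {
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  expect_lt(max(abs(fd_jacobian(function(x) A %*% x, c(1, -2)) - A)), 1e-9)
  expect_equal(as.numeric(fd_jacobian(function(x) x^2, 3)), 6,
               tolerance = 1e-6)
  # halving the step shrinks the error ~4x for smooth curvature
  f <- function(x) exp(x)
  e1 <- abs(fd_jacobian(f, 1, step = 1e-3) - exp(1))
  e2 <- abs(fd_jacobian(f, 1, step = 5e-4) - exp(1))
  expect_gt(e1 / e2, 2.5)
  expect_lt(e1 / e2, 6)
})

test_that("stimulus Jacobian of a cascade is the ordered layer product", {
  set.seed(3)
  # all-linear cascade: product of the L matrices
  L1 <- matrix(rnorm(6), 3, 2); L2 <- matrix(rnorm(12), 4, 3)
  lin <- lnl_cascade(lnl_layer(L1), lnl_layer(L2))
  expect_equal(jacobian_stimulus(lin, c(1, 2)), L2 %*% L1)
  # commuting diagonal layers: order does not matter
  d1 <- diag(c(1, 2, 3)); d2 <- diag(c(0.5, 4, 1))
  expect_equal(jacobian_stimulus(lnl_cascade(lnl_layer(d1), lnl_layer(d2)),
                                 rnorm(3)),
               jacobian_stimulus(lnl_cascade(lnl_layer(d2), lnl_layer(d1)),
                                 rnorm(3)))
})

test_that("cascade Jacobians match finite differences across mixed nonlinearities", {
  set.seed(13)
  for (i in 1:15) {
    nlay <- sample(2:3, 1)
    dims <- sample(3:6, nlay + 1, replace = TRUE)
    casc <- random_cascade(dims)
    x0 <- random_drive(dims[1], min_abs = 0.3)
    J <- jacobian_stimulus(casc, x0)
    Jfd <- fd_jacobian(function(v) respond(v, casc), x0)
    expect_lt(max_rel_err(J, Jfd), 1e-5)
  }
})

test_that("block replication converts row-wise vectorized perturbations", {
  set.seed(23)
  for (i in 1:10) {
    m <- sample(2:5, 1); d <- sample(2:5, 1)
    v <- rnorm(m)
    dL <- matrix(rnorm(d * m), d, m)
    expect_equal(as.numeric(block_replicate(v, d) %*% as.vector(t(dL))),
                 as.numeric(dL %*% v))
  }
})

test_that("parameter Jacobian matches finite differences including L blocks", {
  set.seed(33)
  for (i in 1:8) {
    dims <- sample(3:5, 3, replace = TRUE)
    casc <- random_cascade(dims, kinds = c("dn", "dn"))
    x0 <- random_drive(dims[1], min_abs = 0.3)
    pk <- pack_params(casc)
    J <- jacobian_params(casc, x0, pk$layout)
    # step 1e-5: balances truncation and roundoff through the whole cascade
    Jfd <- fd_jacobian(function(th) respond(x0, unpack_params(casc, th,
                                                              pk$layout)),
                       pk$theta, step = 1e-5)
    expect_lt(max_rel_err(J, Jfd, floor = 1e-5), 1e-5)
  }
  # the last layer's block needs no propagation: identical for a 1-layer model
  d <- 4
  casc1 <- lnl_cascade(lnl_layer(diag(d), random_dn(d)))
  x0 <- random_drive(d)
  pk1 <- pack_params(casc1, free = list(c("gamma", "b", "H")))
  y1 <- forward_cascade(x0, casc1)[[1]]$y
  expect_equal(jacobian_params(casc1, x0, pk1$layout),
               dn_jacobian_params(y1, casc1$layers[[1]]$nonlin),
               ignore_attr = TRUE)
})

test_that("inverse parameter Jacobian follows from the forward Jacobians", {
  # identity cascade: no parameters influence the inverse through theta = L
  idc <- lnl_cascade(lnl_layer(diag(2)))
  x0 <- c(1, -1)
  pk <- pack_params(idc)
  expect_equal(inverse_param_jacobian(idc, x0, pk$layout),
               -solve(diag(2), jacobian_params(idc, x0, pk$layout)))
  # scalar DN layer: matches FD of the analytic inverse w.r.t. b
  nl <- dn_nonlin(gamma = 1, b = 1.2, H = matrix(0.4, 1, 1))
  casc <- lnl_cascade(lnl_layer(diag(1), nl))
  x0 <- 0.8
  r <- respond(x0, casc)
  pk <- pack_params(casc, free = list("b"))
  Ji <- inverse_param_jacobian(casc, x0, pk$layout)
  fd <- fd_jacobian(function(b) {
    dn_inverse(r, dn_nonlin(1, b, matrix(0.4, 1, 1)))
  }, 1.2, step = 1e-7)
  expect_lt(max_rel_err(Ji, fd), 1e-5)
  # consistency on a random square cascade: d/dtheta S^-1(r) from the
  # identity equals brute-force FD through cascade_inverse
  set.seed(43)
  casc2 <- random_cascade(c(3, 3), kinds = "dn")
  x0 <- random_drive(3, 0.3)
  r2 <- respond(x0, casc2)
  pk2 <- pack_params(casc2, free = list(c("gamma", "b")))
  Ji2 <- inverse_param_jacobian(casc2, x0, pk2$layout)
  fd2 <- fd_jacobian(function(th) {
    cascade_inverse(r2, unpack_params(casc2, th, pk2$layout))
  }, pk2$theta, step = 1e-6)
  expect_lt(max_rel_err(Ji2, fd2, floor = 1e-4), 1e-4)
})
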