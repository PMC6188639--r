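test_that("dn_forward matches scalar evaluations and degenerate limits", {
  p <- dn_nonlin(gamma = 1, b = 1, H = matrix(1, 1, 1))
  expect_equal(dn_forward(0, p), 0)            # sign(0) = 0
  expect_equal(dn_forward(2, p), 2 / 3)
  p0 <- dn_nonlin(gamma = 1, b = 1, d = 3)     # H = 0, unit denominator
  y <- c(-2.5, 0.3, 7)
  expect_equal(dn_forward(y, p0), y)
  expect_error(dn_nonlin(gamma = 1, b = c(1, 0), d = 2), "positive")
})

test_that("dn_forward is sign-equivariant and |x| bounded by e/b", {
  set.seed(11)
  for (i in 1:20) {
    d <- sample(2:8, 1)
    p <- random_dn(d)
    y <- rnorm(d)
    x <- dn_forward(y, p)
    expect_equal(dn_forward(-y, p), -x)
    expect_true(all(abs(x) <= abs(y)^p$gamma / p$b + 1e-12))
  }
})

test_that("stimulus Jacobian matches scalar closed forms and is diagonal for H = 0", {
  p <- dn_nonlin(gamma = 1, b = 1, H = matrix(1, 1, 1))
  expect_equal(as.numeric(dn_jacobian_stimulus(2, p)), 1 / 9)  # d/dy y/(1+y)
  b <- c(0.7, 1.2, 2)
  y <- c(1.5, -0.8, 3)
  # no interaction, unit pool on self (H = I): strictly diagonal slope
  pI <- dn_nonlin(gamma = 1, b = b, H = diag(3))
  expect_equal(dn_jacobian_stimulus(y, pI), diag(b / (b + abs(y))^2))
  # H = 0: the pure power/semisaturation scaling
  p0 <- dn_nonlin(gamma = 1, b = b, d = 3)
  expect_equal(dn_jacobian_stimulus(y, p0), diag(1 / b))
})

test_that("stimulus Jacobian matches finite differences on random configurations", {
  set.seed(21)
  for (i in 1:40) {
    d <- sample(2:6, 1)
    p <- random_dn(d)
    y <- random_drive(d)
    J <- dn_jacobian_stimulus(y, p)
    Jfd <- fd_jacobian(function(v) dn_forward(v, p), y)
    expect_lt(max_rel_err(J, Jfd), 1e-5)
  }
})

test_that("parameter Jacobians match scalar closed forms", {
  p <- dn_nonlin(gamma = 1, b = 1, H = matrix(1, 1, 1))
  Jp <- dn_jacobian_params(2, p)   # columns: gamma | b | H
  expect_equal(as.numeric(Jp[1, 1]), 2 * log(2) / 9)  # d 2^g/(1+2^g) /dg, g=1
  expect_equal(as.numeric(Jp[1, 2]), -2 / 9)          # d/db
  expect_equal(as.numeric(Jp[1, 3]), -4 / 9)          # d/dH = -e^2/D^2
})

test_that("parameter Jacobians match finite differences", {
  set.seed(31)
  for (i in 1:25) {
    d <- sample(2:5, 1)
    p <- random_dn(d)
    y <- random_drive(d)
    Jp <- dn_jacobian_params(y, p)
    fg <- function(g) dn_forward(y, dn_nonlin(g, p$b, p$H))
    expect_lt(max_rel_err(Jp[, 1, drop = FALSE], fd_jacobian(fg, p$gamma)),
              1e-5)
    fb <- function(b) dn_forward(y, dn_nonlin(p$gamma, b, p$H))
    expect_lt(max_rel_err(Jp[, 2:(d + 1)], fd_jacobian(fb, p$b)), 1e-5)
    fH <- function(h) dn_forward(y, dn_nonlin(p$gamma, p$b,
                                              matrix(h, d, d, byrow = TRUE)))
    expect_lt(max_rel_err(Jp[, (d + 2):(d + 1 + d^2)],
                          fd_jacobian(fH, as.vector(t(p$H)))), 1e-5)
  }
  expect_error(dn_jacobian_params(0, dn_nonlin(1, 1, d = 1)), "log")
})

test_that("Gaussian kernels have the stated structure", {
  # single sensor per subband: diagonal with c * dp / (2 pi sigma^2)
  spec1 <- gaussian_kernel_spec(cbind(c(0, 1), c(0, 0)), sigma = 0.3,
                                c = 0.5, dp = 0.01, subband = c(1, 2))
  H1 <- build_gaussian_H(spec1)
  expect_equal(H1, diag(rep(0.5 * 0.01 / (2 * pi * 0.3^2), 2)))
  # fine grid: row pools approach c within 1%
  n <- 41
  g <- expand.grid(x = seq_len(n), y = seq_len(n)) / 100  # dp far below sigma
  spec2 <- gaussian_kernel_spec(as.matrix(g), sigma = 0.05, c = 0.4,
                                dp = 0.01^2)
  H2 <- build_gaussian_H(spec2)
  interior <- which(g$x > 0.15 & g$x < 0.26 & g$y > 0.15 & g$y < 0.26)
  expect_lt(max(abs(rowSums(H2)[interior] - 0.4) / 0.4), 0.01)
  # cross-subband entries exactly zero
  spec3 <- gaussian_kernel_spec(cbind(1:4 / 10, 0), sigma = 0.2, c = 0.5,
                                dp = 0.01, subband = c(1, 1, 2, 2))
  H3 <- build_gaussian_H(spec3)
  expect_true(all(H3[1:2, 3:4] == 0) && all(H3[3:4, 1:2] == 0))
})

test_that("kernel-parameter Jacobians match finite differences and linearity", {
  set.seed(41)
  d <- 6
  spec <- gaussian_kernel_spec(cbind(runif(d), runif(d)),
                               sigma = runif(d, 0.15, 0.3),
                               c = runif(d, 0.3, 0.6), dp = 0.02,
                               subband = c(1, 1, 1, 2, 2, 2))
  p <- dn_nonlin(gamma = 0.9, b = runif(d, 0.5, 1), kernel = spec)
  y <- random_drive(d)
  kp <- dn_jacobian_kernel_params(y, p)
  fsig <- function(s) {
    sp <- spec; sp$sigma <- s
    nl_forward(dn_nonlin(0.9, p$b, kernel = sp), y)
  }
  expect_lt(max_rel_err(kp$sigma, fd_jacobian(fsig, spec$sigma, 1e-7)), 1e-5)
  # amplitude derivative is H/c exactly (linearity in c)
  fc <- function(cc) {
    sp <- spec; sp$c <- cc
    nl_forward(dn_nonlin(0.9, p$b, kernel = sp), y)
  }
  expect_lt(max_rel_err(kp$c, fd_jacobian(fc, spec$c, 1e-7)), 1e-5)
  # structured version: shared sigma per subband sums the per-sensor columns
  struct <- cbind(rep(c(1, 0), each = 3), rep(c(0, 1), each = 3))
  spec_s <- gaussian_kernel_spec(spec$positions, sigma = spec$sigma,
                                 c = spec$c, dp = 0.02,
                                 subband = spec$subband,
                                 sigma_struct = struct)
  p_s <- dn_nonlin(gamma = 0.9, b = p$b, kernel = spec_s)
  kp_s <- dn_jacobian_kernel_params(y, p_s)
  expect_equal(kp_s$sigma, kp$sigma %*% struct)
})

test_that("analytic inverse round-trips and reports invertibility", {
  p <- dn_nonlin(gamma = 1, b = 1, H = matrix(1, 1, 1))
  expect_equal(dn_inverse(2 / 3, p), 2)
  # H = 0: closed form sign(x) (b |x|)^(1/gamma)
  p0 <- dn_nonlin(gamma = 0.7, b = c(1.5, 2), d = 2)
  x <- c(0.4, -0.9)
  expect_equal(dn_inverse(x, p0), sign(x) * (p0$b * abs(x))^(1 / 0.7))
  set.seed(51)
  for (i in 1:20) {
    d <- sample(2:6, 1)
    p <- random_dn(d, h_scale = 0.1)
    y <- random_drive(d)
    x <- dn_forward(y, p)
    if (dn_invertibility_margin(x, p) < 0.95) {
      expect_lt(max(abs(dn_inverse(x, p) - y)), 1e-9)
    }
  }
  # margins
  expect_equal(dn_invertibility_margin(c(1, 2), dn_nonlin(1, 1, d = 2)), 0)
  expect_equal(dn_invertibility_margin(0.5, dn_nonlin(1, 1, matrix(1, 1, 1))),
               0.5)
  expect_error(dn_inverse(1.2, dn_nonlin(1, 1, matrix(1, 1, 1))),
               "not invertible")
})

test_that("series inverse converges to the direct inverse as order grows", {
  set.seed(61)
  d <- 5
  p <- random_dn(d, h_scale = 0.12)
  y <- random_drive(d)
  x <- dn_forward(y, p)
  direct <- dn_inverse(x, p)
  errs <- vapply(c(1, 3, 6, 12, 24), function(k) {
    max(abs(suppressWarnings(dn_inverse(x, p, method = "series", order = k)) -
              direct))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-8)
})
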