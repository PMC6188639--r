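make_affine_dataset <- function(a, b, N = 8, seed = 1) {
  # identity model: distances are ||dx||; set them to a * mos + b exactly
  set.seed(seed)
  mos <- sort(runif(N, 10, 90))
  d0 <- 3
  X <- matrix(runif(N * d0, 20, 60), N, d0)
  u <- c(1, 0, 0)
  Z <- X + (a * mos + b) %o% u
  quality_dataset(X, Z, mos)
}

test_that("pearson objective matches cor() and affine invariance", {
  idc <- lnl_cascade(lnl_layer(diag(3)))
  ds <- make_affine_dataset(a = 0.2, b = 1)
  expect_equal(pearson_objective(idc, ds), 1)
  ds_neg <- make_affine_dataset(a = -0.1, b = 20)
  expect_equal(pearson_objective(idc, ds_neg), -1)
  # against the textbook formula on a generic dataset
  set.seed(3)
  m <- build_cartoon_model()
  ds2 <- generate_mos_dataset(m, n_items = 20, seed = 5)
  D <- vapply(1:20, function(c) {
    perceptual_distance(ds2$originals[c, ], ds2$distorted[c, ], m)
  }, numeric(1))
  expect_equal(pearson_objective(m, ds2), cor(ds2$mos, D), tolerance = 1e-12)
  # degenerate variance is flagged
  ds_flat <- quality_dataset(ds2$originals, ds2$distorted,
                             rep(5, 20))
  expect_error(pearson_objective(m, ds_flat), "variance")
})

test_that("pearson gradient matches FD and respects scale invariance", {
  set.seed(13)
  nl <- dn_nonlin(gamma = 1, b = 1.5, H = matrix(0.3, 1, 1))
  casc <- lnl_cascade(lnl_layer(matrix(1), nl))
  N <- 6
  X <- matrix(runif(N, 0.5, 2), N, 1)
  Z <- X + matrix(runif(N, 0.05, 0.4), N, 1)
  ds <- quality_dataset(X, Z, mos = runif(N, 10, 90))
  pk <- pack_params(casc, free = list(c("gamma", "b", "H")))
  g <- pearson_gradient(casc, ds, pk$layout)
  gfd <- fd_jacobian(function(th) {
    pearson_objective(unpack_params(casc, th, pk$layout), ds)
  }, pk$theta, step = 1e-6)
  expect_lt(max_rel_err(g, as.numeric(gfd), floor = 1e-4), 1e-5)
  # rescaling all responses (theta direction = L itself) leaves rho unchanged
  casc_lin <- lnl_cascade(lnl_layer(matrix(2)))
  pk_lin <- pack_params(casc_lin, free = list("L"))
  g_lin <- pearson_gradient(casc_lin, ds, pk_lin$layout)
  expect_lt(abs(sum(g_lin * pk_lin$theta)), 1e-10)
  # identity cascade with no parameters: empty gradient
  idc <- lnl_cascade(lnl_layer(diag(1)))
  pk0 <- pack_params(idc, free = list(character(0)))
  expect_length(pearson_gradient(idc, ds, pk0$layout), 0)
})

test_that("quadratic cost gradient vanishes at the truth and matches FD", {
  set.seed(23)
  d <- 3
  nl <- random_dn(d)
  casc <- lnl_cascade(lnl_layer(diag(d), nl))
  Y <- matrix(random_drive(d * 10, 0.3), 10, d)
  X <- t(respond(t(Y), casc))
  pk <- pack_params(casc, free = list(c("gamma", "b")))
  at_truth <- quadratic_cost_gradient(casc, Y, X, pk$layout)
  expect_lt(max(abs(at_truth$gradient)), 1e-10)
  expect_equal(at_truth$value, 0)
  # away from the truth: FD agreement
  th <- pk$theta * 1.2
  casc2 <- unpack_params(casc, th, pk$layout)
  g <- quadratic_cost_gradient(casc2, Y, X, pk$layout)$gradient
  gfd <- fd_jacobian(function(t2) {
    quadratic_cost_gradient(unpack_params(casc, t2, pk$layout), Y, X,
                            pk$layout)$value
  }, th, step = 1e-6)
  expect_lt(max_rel_err(g, as.numeric(gfd), floor = 1e-4), 1e-5)
})

test_that("inverse-consistency cost is zero at the truth and FD-consistent", {
  set.seed(33)
  nl <- dn_nonlin(gamma = 1, b = 1.2, H = matrix(0.4, 1, 1))
  casc <- lnl_cascade(lnl_layer(matrix(1.5), nl))
  Y <- matrix(runif(6, 0.3, 1.5), 6, 1)
  R <- t(respond(t(Y), casc))
  pk <- pack_params(casc, free = list(c("gamma", "b")))
  at_truth <- inverse_consistency_gradient(casc, Y, R, pk$layout)
  expect_lt(at_truth$value, 1e-20)
  expect_lt(max(abs(at_truth$gradient)), 1e-8)
  th <- pk$theta * 1.15
  casc2 <- unpack_params(casc, th, pk$layout)
  g <- inverse_consistency_gradient(casc2, Y, R, pk$layout)$gradient
  gfd <- fd_jacobian(function(t2) {
    inverse_consistency_gradient(unpack_params(casc, t2, pk$layout), Y, R,
                                 pk$layout)$value
  }, th, step = 1e-6)
  expect_lt(max_rel_err(g, as.numeric(gfd), floor = 1e-4), 1e-4)
})

test_that("deterministic ascent reaches the grid-search optimum on 1 parameter", {
  set.seed(43)
  nl_true <- dn_nonlin(gamma = 1, b = 0.9, H = matrix(0.2, 1, 1))
  casc_true <- lnl_cascade(lnl_layer(matrix(1), nl_true))
  Y <- matrix(runif(40, 0.2, 2), 40, 1)
  X <- t(respond(t(Y), casc_true))
  start <- lnl_cascade(lnl_layer(matrix(1),
                                 dn_nonlin(1, 1.6, matrix(0.2, 1, 1))))
  ft <- fit_cascade(start, list(inputs = Y, targets = X),
                    objective = "quadratic", free = list("b"),
                    max_iter = 200, method = "lbfgs")
  # brute-force oracle over a fine b grid
  bs <- seq(0.5, 2, by = 1e-4)
  costs <- vapply(bs, function(b) {
    c2 <- lnl_cascade(lnl_layer(matrix(1), dn_nonlin(1, b, matrix(0.2, 1, 1))))
    sum((X - t(respond(t(Y), c2)))^2)
  }, numeric(1))
  b_grid <- bs[which.min(costs)]
  expect_lt(abs(ft$cascade$layers[[1]]$nonlin$b - b_grid), 1e-3)
})

test_that("fits are reproducible and improve held-out correlation", {
  set.seed(53)
  m_true <- build_cartoon_model(gamma1 = 0.65, b = 0.8)
  ds <- generate_mos_dataset(m_true, n_items = 40, observer_sd = 2, seed = 7)
  start <- build_cartoon_model(gamma1 = 0.65, b = 2.5)
  run <- function() {
    fit_cascade(start, ds, objective = "pearson",
                free = list(character(0), "b"), max_iter = 15, step = 0.15,
                holdout = 0.3, seed = 11)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$trace, f2$trace)          # determinism contract
  tr <- f1$trace
  expect_true(all(diff(tr$train) >= -1e-12))    # monotone accepted steps
  # the early-stopped model improves on the initialization out of sample
  expect_gt(pearson_objective(f1$cascade, ds, f1$test_items),
            pearson_objective(start, ds, f1$test_items))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$objective, "pearson")
})
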