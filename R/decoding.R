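#' Analytic inversion of a cascade
#'
#' Decodes a response by inverting each layer in turn, last layer first:
#' `x^{i-1} = L_i^dagger N_i^-1(x^i)`.  Nonlinearities use their analytic
#' (or root-found) inverses; linear stages use a ridge-regularized
#' pseudoinverse, so rectangular stages recover the projection of the input
#' onto the row space of `L` (metamerism: what the responses do not encode
#' cannot be decoded).
#'
#' Divisive-normalization layers are invertible only while the spectral
#' radius of `D_|x| H` stays below 1; a violation raises an error naming the
#' layer.  Ill-conditioned linear stages trigger a warning with the
#' condition number.
#'
#' @param responses final response vector `x^n`.
#' @param cascade an [lnl_cascade()].
#' @export
cascade_inverse <- function(responses, cascade) {
  xi <- as.numeric(responses)
  for (i in rev(seq_len(cascade$n))) {
    lay <- cascade$layers[[i]]
    y <- tryCatch(nl_inverse(lay$nonlin, xi),
      error = function(e) {
        stop(sprintf("layer %d not invertible: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    P <- pinv_ridge(lay$L, ridge = lay$pinv_ridge)
    if (is.finite(attr(P, "condition")) && attr(P, "condition") > 1e8) {
      warning(sprintf("layer %d linear stage ill-conditioned (cond %.3g)",
                      i, attr(P, "condition")))
    }
    xi <- as.numeric(P %*% y)
  }
  xi
}

#' Measurement noise model
#'
#' Distortions between the stimulus and the recorded neural signal: Gaussian
#' photon-like noise at the input (s.d. `input_sigma`, cd/m^2), Gaussian
#' blur of the responses in each subband's spatial domain (`blur_deg`,
#' visual degrees), and response noise with variance `fano * |response|`
#' per coefficient.  Responses can be negative, so a true Poisson draw is
#' undefined; the variance-to-mean-magnitude ratio (the Fano factor) is the
#' operative property and is realized with additive Gaussian noise.
#'
#' @param input_sigma input noise s.d. (cd/m^2).
#' @param fano Fano factor of the response noise.
#' @param blur_deg Gaussian blur width applied per subband (deg).
#' @export
noise_model <- function(input_sigma = 3, fano = 0.02, blur_deg = 0.05) {
  stopifnot(input_sigma >= 0, fano >= 0, blur_deg >= 0)
  structure(list(input_sigma = input_sigma, fano = fano,
                 blur_deg = blur_deg),
            class = "noise_model")
}

#' Simulate a recorded neural response
#'
#' Forward response to a noisy input, blurred per subband and corrupted with
#' Fano-scaled noise (see [noise_model()]).  Subband geometry and the
#' sampling density come from the cascade's `geometry`; without geometry the
#' blur must be 0.
#'
#' @param x0 stimulus vector.
#' @param cascade an [lnl_cascade()].
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @export
simulate_measurement <- function(x0, cascade, noise, seed = NULL) {
  with_seed(seed, {
    x_noisy <- x0 + stats::rnorm(length(x0), sd = noise$input_sigma)
    r <- respond(x_noisy, cascade)
    r <- blur_subbands(r, cascade$geometry, noise$blur_deg)
    if (noise$fano > 0) {
      r <- r + stats::rnorm(length(r), sd = sqrt(noise$fano * abs(r)))
    }
    r
  })
}

blur_subbands <- function(r, geometry, blur_deg) {
  if (blur_deg == 0) return(r)
  if (is.null(geometry)) {
    stop("blur requested but the cascade has no response geometry")
  }
  spd <- geometry$samples_per_deg
  for (sb in geometry$subbands) {
    # subbands at deeper scales sample space more coarsely (their own spd)
    sigma_px <- blur_deg * (sb$spd %||% spd)
    if (sigma_px <= 0) next
    K <- gauss_conv_matrix(sb$h, sb$w, sigma_px)
    r[sb$idx] <- as.numeric(K %*% r[sb$idx])
  }
  r
}

#' Regression decoders as baselines
#'
#' Conventional learning-based decoding: multivariate ridge regression and
#' RBF kernel ridge regression from responses to stimuli, with the ridge
#' strength selected by the closed-form leave-one-out shortcut.
#'
#' @param responses `n x dn` training responses (rows = samples).
#' @param stimuli `n x d0` matching stimuli.
#' @param lambdas ridge grid (scaled by the mean feature variance / kernel
#'   diagonal).
#' @return list of decoders `linear`, `kernel`; each predicts with
#'   `predict(dec, new_responses)`.
#' @export
train_baselines <- function(responses, stimuli,
                            lambdas = 10^seq(-8, 2, by = 1)) {
  R <- as.matrix(responses); X <- as.matrix(stimuli)
  stopifnot(nrow(R) == nrow(X), nrow(R) >= 2)
  list(linear = ridge_decoder(R, X, lambdas),
       kernel = kernel_ridge_decoder(R, X, lambdas))
}

ridge_decoder <- function(R, X, lambdas) {
  mu_r <- colMeans(R); mu_x <- colMeans(X)
  Rc <- sweep(R, 2L, mu_r); Xc <- sweep(X, 2L, mu_x)
  G <- crossprod(Rc)
  scale <- mean(diag(G)) / nrow(G)
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors; ev <- pmax(eg$values, 0)
  RtX <- crossprod(Rc, Xc)
  best <- NULL
  for (lam in lambdas * scale) {
    B <- U %*% ((t(U) %*% RtX) / (ev + lam))
    # LOO residuals via the hat matrix H = Rc (G + lam)^-1 Rc^T
    Hdiag <- rowSums((Rc %*% U)^2 / rep(ev + lam, each = nrow(Rc)))
    res <- (Xc - Rc %*% B) / pmax(1 - Hdiag, 1e-6)
    err <- mean(res^2)
    if (is.null(best) || err < best$err) best <- list(B = B, err = err,
                                                      lambda = lam)
  }
  structure(list(B = best$B, mu_r = mu_r, mu_x = mu_x,
                 lambda = best$lambda, loo = best$err),
            class = "ridge_decoder")
}

#' @export
predict.ridge_decoder <- function(object, newdata, ...) {
  Rn <- sweep(as.matrix(newdata), 2L, object$mu_r)
  sweep(Rn %*% object$B, 2L, object$mu_x, `+`)
}

kernel_ridge_decoder <- function(R, X, lambdas) {
  n <- nrow(R)
  D2 <- as.matrix(stats::dist(R))^2
  h2 <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(h2) || h2 <= 0) h2 <- 1
  K <- exp(-D2 / (2 * h2))
  mu_x <- colMeans(X)
  Xc <- sweep(X, 2L, mu_x)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; ev <- pmax(eg$values, 0)
  UtX <- t(U) %*% Xc
  best <- NULL
  for (lam in lambdas) {
    A <- U %*% (UtX / (ev + lam))
    Hdiag <- rowSums(col_scale(U^2, ev / (ev + lam)))
    res <- (Xc - K %*% A) / pmax(1 - Hdiag, 1e-6)
    err <- mean(res^2)
    if (is.null(best) || err < best$err) best <- list(A = A, err = err,
                                                      lambda = lam)
  }
  structure(list(A = best$A, train_R = R, h2 = h2, mu_x = mu_x,
                 lambda = best$lambda, loo = best$err),
            class = "kernel_ridge_decoder")
}

#' @export
predict.kernel_ridge_decoder <- function(object, newdata, ...) {
  Rn <- as.matrix(newdata)
  D2 <- outer(rowSums(Rn^2), rowSums(object$train_R^2), `+`) -
    2 * Rn %*% t(object$train_R)
  Kn <- exp(-pmax(D2, 0) / (2 * object$h2))
  sweep(Kn %*% object$A, 2L, object$mu_x, `+`)
}

#' Decoding error over a luminance x contrast grid
#'
#' Scaled-down in-silico decoding comparison: natural-like images are
#' generated on a luminance/contrast grid, measurements are simulated under
#' a noise model, the learned decoders are trained on pairs from the central
#' grid cell only, and every decoder (linear, kernel ridge, analytic
#' inverse) is evaluated on held-out images of every cell.  The error is the
#' mean absolute error in the input domain (cd/m^2).
#'
#' @param cascade an [lnl_cascade()] matching the grid image size.
#' @param noise a [noise_model()].
#' @param grid an [image_grid_spec()].
#' @param n_train training pairs drawn from the central cell.
#' @param n_test test images per cell.
#' @param seed RNG seed.
#' @return a `decode_report` tibble: columns `lum`, `con`, `decoder`, `mae`,
#'   plus attributes recording the setup.
#' @export
evaluate_decoding_grid <- function(cascade, noise, grid, n_train = 500,
                                   n_test = 1, seed = 1) {
  with_seed(seed, {
    central <- list(lum = stats::median(grid$lum_values),
                    con = stats::median(grid$con_values))
    # training set: fresh draws at the central condition
    train_x <- replicate(n_train,
      as.numeric(generate_grid_image(grid, central$lum, central$con)))
    train_r <- vapply(seq_len(n_train), function(j) {
      simulate_measurement(train_x[, j], cascade, noise)
    }, numeric(cascade$dims[cascade$n + 1L]))
    decoders <- train_baselines(t(train_r), t(train_x))
    rows <- list()
    for (lum in grid$lum_values) {
      for (con in grid$con_values) {
        for (t in seq_len(n_test)) {
          x <- as.numeric(generate_grid_image(grid, lum, con))
          r <- simulate_measurement(x, cascade, noise)
          est <- list(
            linear = as.numeric(predict(decoders$linear, matrix(r, 1))),
            kernel = as.numeric(predict(decoders$kernel, matrix(r, 1))),
            analytic = tryCatch(cascade_inverse(r, cascade),
                                error = function(e) rep(NA_real_, length(x))))
          for (nm in names(est)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              lum = lum, con = con, rep = t, decoder = nm,
              mae = mean(abs(est[[nm]] - x)))
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    structure(out, central = central, n_train = n_train, seed = seed,
              class = c("decode_report", class(out)))
  })
}
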