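#' Canonical divisive normalization
#'
#' The canonical saturating interaction of neural populations.  In matrix
#' form the response to a vector of linear drives `y` is
#' \deqn{x = D_{sign(y)} \, D_{b + H e}^{-1} \, e, \qquad e = |y|^\gamma,}
#' i.e. component-wise `x_k = sign(y_k) |y_k|^gamma / (b_k + sum_k' H_kk'
#' |y_k'|^gamma)`.  `gamma` is the excitation/inhibition exponent, `b` the
#' (strictly positive) semisaturation vector and `H` the nonnegative
#' interaction kernel describing how neighboring activity masks each unit.
#'
#' `H` can be given explicitly, or parameterized through a
#' [gaussian_kernel_spec()], in which case the kernel-level parameters
#' (per-sensor widths `sigma` and pooling amplitudes `c`, optionally shared
#' through binary structure matrices) become the free parameters instead of
#' the raw entries of `H`.
#'
#' @param gamma positive scalar exponent.
#' @param b strictly positive semisaturation vector (length `d`; a scalar is
#'   recycled once `d` is known from `H` or `kernel`).
#' @param H nonnegative `d x d` interaction kernel; defaults to no
#'   interaction (zero matrix).
#' @param kernel optional [gaussian_kernel_spec()]; overrides `H`.
#' @param d dimension, needed only when it cannot be inferred.
#' @return an object of class `dn_nonlin`.
#' @examples
#' p <- dn_nonlin(gamma = 1, b = 1, H = matrix(1, 1, 1))
#' nl_forward(p, 2)      # 2/3
#' nl_inverse(p, 2 / 3)  # 2
#' @export
dn_nonlin <- function(gamma, b, H = NULL, kernel = NULL, d = NULL) {
  if (!is.null(kernel)) {
    H <- build_gaussian_H(kernel)
  }
  d <- d %||% (if (!is.null(H)) nrow(H) else length(b))
  b <- rep_len(as.numeric(b), d)
  if (is.null(H)) H <- matrix(0, d, d)
  stopifnot(nrow(H) == d, ncol(H) == d)
  if (any(b <= 0)) stop("semisaturation b must be strictly positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (any(H < 0)) stop("interaction kernel H must be nonnegative")
  stopifnot_finite(H, "H")
  structure(list(gamma = as.numeric(gamma), b = b, H = H, kernel = kernel,
                 d = d, eta = 1e-6),
            class = c("dn_nonlin", "nonlinearity"))
}

dn_intermediates <- function(nl, y) {
  y <- as.matrix(y)
  e <- abs(y)^nl$gamma
  D <- nl$b + nl$H %*% e
  list(e = e, D = D, s = sign(y))
}

#' @export
nl_forward.dn_nonlin <- function(nl, y) {
  was_vec <- is.null(dim(y))
  im <- dn_intermediates(nl, y)
  x <- im$s * im$e / im$D
  if (was_vec) as.numeric(x) else x
}

#' Divisive normalization: forward, Jacobians, inverse, margin
#'
#' Free-standing wrappers over the [dn_nonlin()] bundle, named by operation.
#'
#' `dn_forward()` evaluates the response.  `dn_jacobian_stimulus()` returns
#' the `d x d` Jacobian w.r.t. the drive `y`,
#' \deqn{\nabla_y N = D_s D_D^{-1} [I - D_{e/D} H] D_{\gamma |y|^{\gamma-1}} D_s,}
#' which is the subtraction of a diagonal matrix and an `H`-coupling term.
#' For `gamma < 1` the factor `|y|^(gamma-1)` diverges at 0; `|y|` is clamped
#' to `nl$eta` (default `1e-6`) inside that factor only.
#'
#' `dn_jacobian_params()` concatenates the derivatives w.r.t. `gamma`
#' (one column), `b` (diagonal, `d` columns) and the raw kernel `H`
#' (`d^2` columns, row-wise vectorization: column `(k-1)*d + l` is
#' `dH[k, l]`).  `dn_jacobian_kernel_params()` gives the columns for the
#' Gaussian-kernel widths and amplitudes instead (see
#' [gaussian_kernel_spec()]).
#'
#' `dn_inverse()` applies the analytic inverse
#' \deqn{y = D_{sign(x)} [(I - D_{|x|} H)^{-1} b \odot |x|]^{1/\gamma},}
#' which exists when the spectral radius of `D_|x| H` is below 1;
#' `dn_invertibility_margin()` returns that radius.  With
#' `method = "series"` the matrix inverse is replaced by a truncated Neumann
#' series of matrix-on-vector products, checked a posteriori against the
#' residual tolerance.
#'
#' @param y,x numeric vectors (matrix columns allowed for the forward map).
#' @param nl a [dn_nonlin()] bundle.
#' @export
dn_forward <- function(y, nl) nl_forward(nl, y)

#' @export
nl_jacobian.dn_nonlin <- function(nl, y) {
  y <- as.numeric(y)
  im <- dn_intermediates(nl, y)
  e <- as.numeric(im$e); D <- as.numeric(im$D); s <- as.numeric(im$s)
  ay <- abs(y)
  if (nl$gamma < 1) ay <- pmax(ay, nl$eta)
  g <- nl$gamma * ay^(nl$gamma - 1)
  A <- diag(length(y)) - row_scale(e / D, nl$H)
  J <- col_scale(row_scale(s / D, A), g * s)
  J
}

#' @rdname dn_forward
#' @export
dn_jacobian_stimulus <- function(y, nl) nl_jacobian(nl, y)

dn_grad_gamma <- function(nl, y) {
  im <- dn_intermediates(nl, y)
  e <- as.numeric(im$e); D <- as.numeric(im$D); s <- as.numeric(im$s)
  if (any(y == 0)) {
    stop("gamma derivative undefined at y = 0 (log|y| singularity)")
  }
  ep <- e * log(abs(y))
  s * (ep / D - e * as.numeric(nl$H %*% ep) / D^2)
}

dn_grad_b_diag <- function(nl, y) {
  im <- dn_intermediates(nl, y)
  -as.numeric(im$s) * as.numeric(im$e) / as.numeric(im$D)^2
}

dn_grad_H <- function(nl, y) {
  im <- dn_intermediates(nl, y)
  e <- as.numeric(im$e); D <- as.numeric(im$D); s <- as.numeric(im$s)
  d <- nl$d
  J <- matrix(0, d, d * d)
  coef <- -s * e / D^2
  for (k in seq_len(d)) {
    J[k, ((k - 1L) * d + 1L):(k * d)] <- coef[k] * e
  }
  J
}

#' @rdname dn_forward
#' @export
dn_jacobian_params <- function(y, nl) {
  cbind(gamma = dn_grad_gamma(nl, y),
        diag(dn_grad_b_diag(nl, y), nrow = nl$d),
        dn_grad_H(nl, y))
}

#' @export
nl_param_jacobian.dn_nonlin <- function(nl, y) {
  if (is.null(nl$kernel)) {
    dn_jacobian_params(y, nl)
  } else {
    kp <- dn_jacobian_kernel_params(y, nl)
    cbind(gamma = dn_grad_gamma(nl, y),
          diag(dn_grad_b_diag(nl, y), nrow = nl$d),
          kp$sigma, kp$c)
  }
}

#' @rdname dn_forward
#' @export
dn_jacobian_kernel_params <- function(y, nl) {
  spec <- nl$kernel
  if (is.null(spec)) stop("nonlinearity has no Gaussian kernel spec")
  im <- dn_intermediates(nl, y)
  e <- as.numeric(im$e); D <- as.numeric(im$D); s <- as.numeric(im$s)
  coef <- -s * e / D^2
  Fk <- gaussian_kernel_matrix(spec, deriv = "sigma")
  Gk <- gaussian_kernel_matrix(spec, deriv = "c")
  v_sigma <- coef * as.numeric(Fk %*% e)   # d/d sigma_k, nonzero in row k only
  v_c <- coef * as.numeric(Gk %*% e)
  Ms <- spec$sigma_struct %||% diag(nl$d)
  Mc <- spec$c_struct %||% diag(nl$d)
  list(sigma = col_from_diag(v_sigma, Ms),
       c = col_from_diag(v_c, Mc))
}

# diag(v) %*% M without forming diag(v)
col_from_diag <- function(v, M) row_scale(v, M)

#' @rdname dn_forward
#' @param method `"direct"` (matrix solve) or `"series"` (truncated Neumann
#'   expansion).
#' @param order series truncation order.
#' @param tol residual tolerance for the series method.
#' @export
dn_inverse <- function(x, nl, method = c("direct", "series"), order = 10,
                       tol = 1e-8) {
  method <- match.arg(method)
  x <- as.numeric(x)
  ax <- abs(x)
  rad <- spectral_radius(row_scale(ax, nl$H))
  if (rad >= 1) {
    stop(sprintf(
      "divisive normalization not invertible here: spectral radius of D_|x|H is %.4f >= 1",
      rad))
  }
  A <- diag(length(x)) - row_scale(ax, nl$H)
  rhs <- nl$b * ax
  if (method == "direct") {
    elin <- solve(A, rhs)
  } else {
    # Neumann series: sum_j (D_|x| H)^j rhs, matrix-on-vector only
    elin <- rhs
    term <- rhs
    for (j in seq_len(order)) {
      term <- ax * as.numeric(nl$H %*% term)
      elin <- elin + term
    }
    resid <- sqrt(sum((as.numeric(A %*% elin) - rhs)^2))
    if (resid > tol) {
      warning(sprintf(
        "series inverse residual %.3g above tol %.3g at order %d; increase `order`",
        resid, tol, order))
    }
  }
  sign(x) * pmax(elin, 0)^(1 / nl$gamma)
}

#' @export
nl_inverse.dn_nonlin <- function(nl, x, ...) {
  if (is.null(dim(x))) return(dn_inverse(x, nl, ...))
  apply(x, 2L, dn_inverse, nl = nl, ...)
}

#' @rdname dn_forward
#' @export
dn_invertibility_margin <- function(x, nl) {
  spectral_radius(row_scale(abs(as.numeric(x)), nl$H))
}

#' @export
nl_theta_layout.dn_nonlin <- function(nl) {
  if (is.null(nl$kernel)) {
    data.frame(param = c("gamma", "b", "H"),
               length = c(1L, nl$d, nl$d^2),
               positive = c(TRUE, TRUE, FALSE),
               stringsAsFactors = FALSE)
  } else {
    gs <- ncol(nl$kernel$sigma_struct %||% diag(nl$d))
    gc <- ncol(nl$kernel$c_struct %||% diag(nl$d))
    data.frame(param = c("gamma", "b", "sigma", "c"),
               length = c(1L, nl$d, gs, gc),
               positive = c(TRUE, TRUE, TRUE, TRUE),
               stringsAsFactors = FALSE)
  }
}

#' @export
nl_get_theta.dn_nonlin <- function(nl) {
  if (is.null(nl$kernel)) {
    # H vectorized row-wise, matching the parameter-Jacobian convention
    c(nl$gamma, nl$b, as.vector(t(nl$H)))
  } else {
    c(nl$gamma, nl$b, kernel_group_values(nl$kernel, "sigma"),
      kernel_group_values(nl$kernel, "c"))
  }
}

#' @export
nl_set_theta.dn_nonlin <- function(nl, theta) {
  lay <- nl_theta_layout(nl)
  stopifnot(length(theta) == sum(lay$length))
  pos <- 0L
  take <- function(n) {
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  nl$gamma <- take(1L)
  nl$b <- take(nl$d)
  if (is.null(nl$kernel)) {
    nl$H <- matrix(take(nl$d^2), nl$d, nl$d, byrow = TRUE)
  } else {
    nl$kernel <- kernel_set_group_values(nl$kernel, "sigma", take(lay$length[3]))
    nl$kernel <- kernel_set_group_values(nl$kernel, "c", take(lay$length[4]))
    nl$H <- build_gaussian_H(nl$kernel)
  }
  if (any(nl$b <= 0) || nl$gamma <= 0) {
    stop("theta update violates positivity of gamma/b")
  }
  nl
}
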