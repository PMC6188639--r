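#' Global Jacobians of a cascade
#'
#' The Jacobian of the full response w.r.t. the stimulus is the ordered
#' product of per-layer Jacobians (last layer left-most),
#' \deqn{\nabla_{x^0} S = \prod_{i=n}^{1} \nabla_{x^{i-1}} S^{(i)}, \qquad
#'       \nabla_{x^{i-1}} S^{(i)} = \nabla_{y^i} N^{(i)} \cdot L^i.}
#' The Jacobian w.r.t. the parameters concatenates per-layer blocks: a
#' perturbation of layer `i` changes that layer's output (through
#' `grad_theta N` and, for the linear weights, `grad_y N . B(x^{i-1}T)`) and
#' then propagates through the remaining layers.
#'
#' @param cascade an [lnl_cascade()].
#' @param x0 stimulus vector.
#' @return `jacobian_stimulus()`: `d_n x d_0` matrix.
#' @export
jacobian_stimulus <- function(cascade, x0) {
  st <- forward_cascade(x0, cascade)
  J <- NULL
  for (i in seq_len(cascade$n)) {
    Ji <- layer_jacobian(cascade$layers[[i]], st[[i]]$y, i)
    J <- if (is.null(J)) Ji else Ji %*% J
  }
  J
}

layer_jacobian <- function(layer, y, i) {
  tryCatch(nl_jacobian(layer$nonlin, y) %*% layer$L,
    error = function(e) {
      stop(sprintf("layer %d Jacobian: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
}

#' Block replication of a row vector
#'
#' `block_replicate(v, d)` builds the block-diagonal matrix with `d` copies
#' of the row vector `t(v)`; it converts row-wise-vectorized perturbations of
#' a matrix into matrix-on-vector products:
#' `block_replicate(v, d) %*% as.vector(t(dL)) == dL %*% v`.
#'
#' @param v numeric vector.
#' @param d replication count.
#' @export
block_replicate <- function(v, d) {
  m <- length(v)
  B <- matrix(0, d, d * m)
  for (k in seq_len(d)) B[k, ((k - 1L) * m + 1L):(k * m)] <- v
  B
}

#' @rdname jacobian_stimulus
#' @param layout layout from [pack_params()] selecting the free parameters;
#'   defaults to all parameters of all layers.
#' @return `jacobian_params()`: `d_n x d_Theta` matrix with columns ordered
#'   as in the layout (matrix parameters row-wise).
#' @export
jacobian_params <- function(cascade, x0, layout = NULL) {
  layout <- layout %||% pack_params(cascade)$layout
  st <- forward_cascade(x0, cascade)
  n <- cascade$n
  dn <- cascade$dims[n + 1L]
  # propagation products P[[i]] = prod_{l=n}^{i+1} grad S^(l)  (identity for i=n)
  P <- vector("list", n)
  P[[n]] <- diag(dn)
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      P[[i]] <- P[[i + 1L]] %*%
        layer_jacobian(cascade$layers[[i + 1L]], st[[i + 1L]]$y, i + 1L)
    }
  }
  J <- matrix(0, dn, sum(layout$length))
  for (r in seq_len(nrow(layout))) {
    i <- layout$layer[r]
    lay <- cascade$layers[[i]]
    x_prev <- if (i == 1L) as.numeric(x0) else st[[i - 1L]]$x
    block <- if (layout$param[r] == "L") {
      nl_jacobian(lay$nonlin, st[[i]]$y) %*%
        block_replicate(x_prev, nrow(lay$L))
    } else {
      Jth <- nl_param_jacobian(lay$nonlin, st[[i]]$y)
      sub_param_columns(lay$nonlin, Jth, layout$param[r])
    }
    J[, layout$offset[r] + seq_len(layout$length[r])] <- P[[i]] %*% block
  }
  J
}

# columns of the nonlinearity parameter Jacobian belonging to one parameter
sub_param_columns <- function(nl, Jth, param) {
  lay <- nl_theta_layout(nl)
  pos <- c(0L, cumsum(lay$length))
  r <- match(param, lay$param)
  if (is.na(r)) stop(sprintf("no parameter '%s'", param))
  Jth[, (pos[r] + 1L):pos[r + 1L], drop = FALSE]
}

#' Central finite-difference Jacobian
#'
#' Independent numerical oracle used to validate every analytic Jacobian in
#' the package: central differences with per-coordinate step
#' `step * max(1, |x_j|)`.
#'
#' @param func vector-valued function of a vector.
#' @param point evaluation point.
#' @param step base relative step (default `1e-6`).
#' @export
fd_jacobian <- function(func, point, step = 1e-6) {
  f0 <- func(point)
  J <- matrix(0, length(f0), length(point))
  for (j in seq_along(point)) {
    h <- step * max(1, abs(point[j]))
    if (h == 0) stop("finite-difference step underflow")
    xp <- point; xp[j] <- xp[j] + h
    xm <- point; xm[j] <- xm[j] - h
    J[, j] <- (func(xp) - func(xm)) / (2 * h)
  }
  J
}

#' Jacobian of the cascade inverse w.r.t. the parameters
#'
#' For square invertible cascades the inverse map's parameter sensitivity
#' follows from the forward Jacobians alone:
#' `grad_Theta S^-1 = -(grad_x0 S)^-1 grad_Theta S`, both evaluated at the
#' stimulus `x0` (i.e. at the response `S(x0)` of the inverse's argument).
#'
#' @inheritParams jacobian_params
#' @export
inverse_param_jacobian <- function(cascade, x0, layout = NULL) {
  J <- jacobian_stimulus(cascade, x0)
  if (nrow(J) != ncol(J)) stop("stimulus Jacobian is not square")
  -solve(J, jacobian_params(cascade, x0, layout))
}
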