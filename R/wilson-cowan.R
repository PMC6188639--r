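#' Wilson-Cowan steady-state nonlinearity
#'
#' The mean activity of a coupled population evolving as
#' `dx/dt = -alpha x + mu W f(x) + lambda y` is used, at its steady state, as
#' a layer nonlinearity: `x = N(y)` solves `0 = -alpha x + mu W f(x) +
#' lambda y`.  The inverse is closed form,
#' `y = (alpha x - mu W f(x)) / lambda`, and the forward Jacobian is the
#' matrix inverse of the (analytic) Jacobian of the inverse,
#' `grad N^-1 = (alpha I - mu W D_f'(x)) / lambda`.
#'
#' Existence/uniqueness of the steady state is assumed; at construction we
#' check the sufficient contraction condition
#' `alpha > |mu| * max_row_sum(|W|) * sup|f'|`, which also guarantees the
#' damped fixed-point iteration converges.
#'
#' @param alpha,mu,lam coupling coefficients (`alpha`, `lam` positive).
#' @param W `d x d` interaction kernel, typically decaying with `|k - k'|`.
#' @param f sigmoid name; currently `"tanh"`.
#' @param slope sigmoid slope.
#' @param tol,max_iter,damping fixed-point solver controls.
#' @param check enforce the contraction condition at construction.
#' @return an object of class `wc_nonlin`.
#' @examples
#' p <- wc_nonlin(alpha = 1, mu = 0.5, lam = 1, W = matrix(1, 1, 1))
#' nl_inverse(p, 1)                  # 1 - 0.5 * tanh(1)
#' nl_forward(p, nl_inverse(p, 1))   # back to 1
#' @export
wc_nonlin <- function(alpha, mu, lam, W, f = "tanh", slope = 1,
                      tol = 1e-10, max_iter = 10000, damping = 0.8,
                      check = TRUE) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), alpha > 0, lam > 0)
  sig <- make_sigmoid(f, slope)
  margin <- alpha - abs(mu) * max(rowSums(abs(W))) * sig$sup_grad
  if (check && margin <= 0) {
    stop(sprintf(
      "contraction condition violated (margin %.3g <= 0): need alpha > |mu| ||W||_inf sup|f'|",
      margin))
  }
  structure(list(alpha = alpha, mu = mu, lam = lam, W = W, f = sig,
                 d = nrow(W), tol = tol, max_iter = max_iter,
                 damping = damping, margin = margin),
            class = c("wc_nonlin", "nonlinearity"))
}

make_sigmoid <- function(name, slope = 1) {
  switch(name,
    tanh = list(name = "tanh", slope = slope,
                fn = function(x) tanh(slope * x),
                grad = function(x) slope * (1 - tanh(slope * x)^2),
                sup_grad = slope),
    stop(sprintf("unknown sigmoid '%s'", name)))
}

#' Wilson-Cowan operations
#'
#' Named wrappers over the [wc_nonlin()] bundle: `wc_forward()` solves the
#' steady state by damped fixed-point iteration (with a Newton polish),
#' `wc_inverse()` is the closed form, and `wc_jacobian_stimulus()` inverts
#' the analytic Jacobian of the inverse.
#'
#' @param y,x numeric vectors.
#' @param nl a [wc_nonlin()] bundle.
#' @export
wc_inverse <- function(x, nl) {
  x <- as.matrix(x)
  out <- (nl$alpha * x - nl$mu * nl$W %*% nl$f$fn(x)) / nl$lam
  if (ncol(out) == 1L) as.numeric(out) else out
}

#' @export
nl_inverse.wc_nonlin <- function(nl, x, ...) wc_inverse(x, nl)

wc_solve_one <- function(y, nl) {
  a <- nl$alpha; mu <- nl$mu; lam <- nl$lam
  x <- lam * y / a
  kap <- nl$damping
  resid <- function(x) -a * x + mu * as.numeric(nl$W %*% nl$f$fn(x)) + lam * y
  for (it in seq_len(nl$max_iter)) {
    xn <- (1 - kap) * x + kap * (mu * as.numeric(nl$W %*% nl$f$fn(x)) + lam * y) / a
    if (max(abs(xn - x)) < nl$tol) { x <- xn; break }
    x <- xn
  }
  # Newton polish on the steady-state residual (to near machine precision,
  # so finite differences of the forward map stay clean)
  for (it in 1:6) {
    r <- resid(x)
    if (max(abs(r)) < 1e-14 * max(1, abs(a))) break
    Jr <- -a * diag(length(x)) + mu * col_scale(nl$W, nl$f$grad(x))
    x <- x - solve(Jr, r)
  }
  r <- resid(x)
  if (max(abs(r)) > 1e3 * nl$tol) {
    stop(sprintf("Wilson-Cowan steady state did not converge (residual %.3g)",
                 max(abs(r))))
  }
  x
}

#' @rdname wc_inverse
#' @export
wc_forward <- function(y, nl) nl_forward(nl, y)

#' @export
nl_forward.wc_nonlin <- function(nl, y) {
  if (is.null(dim(y))) return(wc_solve_one(as.numeric(y), nl))
  apply(y, 2L, wc_solve_one, nl = nl)
}

#' @rdname wc_inverse
#' @export
wc_jacobian_stimulus <- function(y, nl) {
  x <- nl_forward(nl, y)
  Jinv <- (nl$alpha * diag(length(x)) -
             nl$mu * col_scale(nl$W, nl$f$grad(x))) / nl$lam
  solve(Jinv)
}

#' @export
nl_jacobian.wc_nonlin <- function(nl, y) wc_jacobian_stimulus(y, nl)
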