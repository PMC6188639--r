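#' Two-gamma tone-mapping nonlinearity
#'
#' A point-wise brightness-from-luminance curve `x = sign(y) |y|^gamma(|y|)`
#' whose exponent transitions smoothly between a low-input value `gamma_l`
#' and a high-input value `gamma_h`:
#' \deqn{\gamma(a) = \gamma_H - (\gamma_H - \gamma_L)
#'       \frac{\mu_1^m}{\mu_1^m + a^m}.}
#' The transition happens around `a = mu1` (where the exponent is exactly
#' half-way) with sharpness `m`.  Because the derivative of `a^gamma(a)`
#' involves `log a` and `1/a`, it is singular at 0; below a patch radius
#' `eps` the curve is replaced by the quadratic `sign(y)(a1 |y|^2 + a2 |y|)`
#' with `a1`, `a2` chosen so value and slope match at `|y| = eps` (the curve
#' is C1 everywhere).
#'
#' There is no closed-form inverse (the exponent depends on the input);
#' `nl_inverse()` root-finds each component of the monotone scalar map.
#' Monotonicity for the given parameters is checked on a grid at
#' construction.
#'
#' With `gamma_l == gamma_h` this is the plain power law `sign(y)|y|^gamma`
#' (used e.g. for brightness stages), with exact closed-form inverse.
#'
#' @param gamma_l,gamma_h exponents for low / high inputs.
#' @param mu1 transition point, in the units of `|y|`.
#' @param m transition sharpness.
#' @param eps patch radius (default `1e-3`, normalized input units).
#' @return an object of class `tg_nonlin`.
#' @examples
#' p <- tg_nonlin(0.9, 0.5, mu1 = 1, m = 2)
#' nl_forward(p, 1)        # exponent is (0.9 + 0.5)/2 at |y| = mu1
#' nl_inverse(p, nl_forward(p, 2))
#' @export
tg_nonlin <- function(gamma_l, gamma_h, mu1 = 1, m = 2, eps = 1e-3) {
  stopifnot(gamma_l > 0, gamma_h > 0, mu1 > 0, m > 0, eps > 0, eps < 1)
  nl <- structure(list(gamma_l = gamma_l, gamma_h = gamma_h, mu1 = mu1,
                       m = m, eps = eps),
                  class = c("tg_nonlin", "nonlinearity"))
  d <- tg_gprime(nl, eps)
  g <- tg_g(nl, eps)
  nl$a1 <- (eps * d - g) / eps^2
  nl$a2 <- (2 * g - eps * d) / eps
  # monotonicity of the patched curve, checked numerically on a grid
  grid <- c(seq(0, eps, length.out = 32)[-1],
            exp(seq(log(eps), log(1e3 * mu1), length.out = 256)))
  if (any(tg_slope(nl, grid) <= 0)) {
    stop("two-gamma parameters give a non-monotone curve; not invertible")
  }
  nl
}

tg_exponent <- function(nl, a) {
  nl$gamma_h - (nl$gamma_h - nl$gamma_l) * nl$mu1^nl$m / (nl$mu1^nl$m + a^nl$m)
}

tg_exponent_grad <- function(nl, a) {
  (nl$gamma_h - nl$gamma_l) * nl$m * a^(nl$m - 1) * nl$mu1^nl$m /
    (nl$mu1^nl$m + a^nl$m)^2
}

tg_g <- function(nl, a) a^tg_exponent(nl, a)          # a > 0

tg_gprime <- function(nl, a) {
  tg_g(nl, a) * (tg_exponent_grad(nl, a) * log(a) + tg_exponent(nl, a) / a)
}

# derivative of the patched curve w.r.t. a = |y| (valid for a >= 0)
tg_slope <- function(nl, a) {
  out <- numeric(length(a))
  lo <- a <= nl$eps
  out[lo] <- 2 * nl$a1 * a[lo] + nl$a2
  if (any(!lo)) out[!lo] <- tg_gprime(nl, a[!lo])
  out
}

#' Two-gamma operations
#'
#' `tg_forward()` evaluates the patched curve, `tg_jacobian_stimulus()` its
#' (diagonal) Jacobian, `tg_inverse()` the per-component scalar inverse.
#'
#' @param y,x numeric vectors (matrix columns allowed for the forward map).
#' @param nl a [tg_nonlin()] bundle.
#' @export
tg_forward <- function(y, nl) nl_forward(nl, y)

#' @export
nl_forward.tg_nonlin <- function(nl, y) {
  a <- abs(y)
  out <- y
  lo <- a <= nl$eps
  out[lo] <- sign(y[lo]) * (nl$a1 * a[lo]^2 + nl$a2 * a[lo])
  out[!lo] <- sign(y[!lo]) * tg_g(nl, a[!lo])
  out
}

#' @rdname tg_forward
#' @export
tg_jacobian_stimulus <- function(y, nl) {
  diag(tg_slope(nl, abs(as.numeric(y))), nrow = length(y))
}

#' @export
nl_jacobian.tg_nonlin <- function(nl, y) tg_jacobian_stimulus(y, nl)

tg_invert_one <- function(ax, nl) {
  if (ax == 0) return(0)
  g_eps <- nl$a1 * nl$eps^2 + nl$a2 * nl$eps
  if (ax <= g_eps) {
    # quadratic branch: a1 a^2 + a2 a = ax, positive root
    if (abs(nl$a1) < 1e-14) return(ax / nl$a2)
    a <- (-nl$a2 + sqrt(nl$a2^2 + 4 * nl$a1 * ax)) / (2 * nl$a1)
    return(a)
  }
  if (nl$gamma_l == nl$gamma_h) return(ax^(1 / nl$gamma_l))
  upper <- max(1, ax)^(1 / min(nl$gamma_l, nl$gamma_h)) + 1
  while (tg_g(nl, upper) < ax) upper <- upper * 2
  stats::uniroot(function(a) tg_g(nl, a) - ax, c(nl$eps, upper),
                 tol = 1e-13)$root
}

#' @rdname tg_forward
#' @export
tg_inverse <- function(x, nl) {
  sign(x) * vapply(abs(as.numeric(x)), tg_invert_one, numeric(1), nl = nl)
}

#' @export
nl_inverse.tg_nonlin <- function(nl, x, ...) {
  if (is.null(dim(x))) return(tg_inverse(x, nl))
  apply(x, 2L, tg_inverse, nl = nl)
}
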