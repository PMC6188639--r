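# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# diagonal-scaling products without forming diagonal matrices:
# row_scale(v, M) = D_v %*% M ; col_scale(M, v) = M %*% D_v
row_scale <- function(v, M) M * v
col_scale <- function(M, v) sweep(M, 2L, v, `*`)

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# ridge-regularized Moore-Penrose pseudoinverse via SVD.
# `ridge` is added to the squared singular values, so ridge = 0 gives the
# plain pseudoinverse (with small-singular-value truncation at tol).
pinv_ridge <- function(L, ridge = 0, tol = 1e-12) {
  sv <- svd(L)
  s <- sv$d
  smax <- if (length(s)) s[1] else 0
  keep <- s > tol * max(smax, 1)
  if (ridge > 0) {
    g <- s[keep] / (s[keep]^2 + ridge)
  } else {
    g <- 1 / s[keep]
  }
  P <- sv$v[, keep, drop = FALSE] %*% (g * t(sv$u[, keep, drop = FALSE]))
  attr(P, "condition") <- if (any(keep)) smax / min(s[keep]) else Inf
  P
}

spectral_radius <- function(M) {
  if (!nrow(M)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# circulant 1-d Gaussian smoothing matrix (unit row sums); sigma in samples
gauss_circulant <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- 0:(n - 1)
  # wrap-around distance on the circle
  d <- pmin(i, n - i)
  k <- exp(-d^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (r in seq_len(n)) K[r, ] <- k[((i - (r - 1)) %% n) + 1]
  K
}

# 2-d separable circular Gaussian smoothing matrix acting on vectorized
# h x w single-band images in the package scan order (row index slowest).
gauss_conv_matrix <- function(h, w, sigma) {
  kronecker(gauss_circulant(h, sigma), gauss_circulant(w, sigma))
}

# seeded evaluation: runs expr under set.seed(seed) when seed is not NULL
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
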