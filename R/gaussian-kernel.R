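#' Gaussian interaction kernels
#'
#' Interaction between normalization units is stronger for closer neurons,
#' which suggests Gaussian rows for the kernel `H`: within each subband
#' \deqn{H_{kk'} = c_k \frac{dp_k}{2\pi\sigma_k^2}
#'       e^{-\Delta_{kk'}^2 / 2\sigma_k^2},}
#' and exactly 0 across subbands.  `Delta` is the spatial distance between
#' the sensors (deg), `dp_k` the grid cell area (deg^2) of the subband's
#' sampling grid, `c_k` the total interaction pool (on a grid fine relative
#' to `sigma_k`, the row sum of `H` approaches `c_k`) and `sigma_k` the
#' interaction width (deg).
#'
#' Parameters may be shared across sensors through binary structure matrices
#' (`d x g`, one 1 per row): e.g. one width per subband.  Shared values are
#' stored per-sensor and packed/optimized per group.
#'
#' @param positions `d x 2` matrix of sensor centers (deg).
#' @param sigma widths (deg); scalar, per-sensor vector, or per-group vector
#'   when `sigma_struct` is given.
#' @param c pooling amplitudes; same recycling rules as `sigma`.
#' @param dp grid cell area (deg^2); scalar or per-sensor.
#' @param subband integer/factor subband id per sensor.
#' @param sigma_struct,c_struct optional binary `d x g` sharing matrices.
#' @return a `gaussian_kernel_spec`.
#' @examples
#' spec <- gaussian_kernel_spec(cbind(1:4 / 10, 0), sigma = 0.2, c = 0.5,
#'                              dp = 0.01)
#' rowSums(build_gaussian_H(spec))
#' @export
gaussian_kernel_spec <- function(positions, sigma, c, dp, subband = 1L,
                                 sigma_struct = NULL, c_struct = NULL) {
  positions <- as.matrix(positions)
  d <- nrow(positions)
  stopifnot(ncol(positions) == 2L)
  subband <- rep_len(as.integer(as.factor(subband)), d)
  expand <- function(v, struct, what) {
    if (!is.null(struct)) {
      stopifnot(nrow(struct) == d, all(rowSums(struct) == 1))
      if (length(v) == ncol(struct)) v <- as.numeric(struct %*% v)
    }
    rep_len(as.numeric(v), d)
  }
  sigma <- expand(sigma, sigma_struct, "sigma")
  c <- expand(c, c_struct, "c")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(c <= 0)) stop("c must be positive")
  dp <- rep_len(as.numeric(dp), d)
  if (any(dp <= 0)) stop("dp must be positive")
  structure(list(positions = positions, sigma = sigma, c = c, dp = dp,
                 subband = subband, sigma_struct = sigma_struct,
                 c_struct = c_struct, d = d),
            class = "gaussian_kernel_spec")
}

# squared distances and subband mask, shared by H and its derivatives
kernel_geometry <- function(spec) {
  P <- spec$positions
  d2 <- outer(P[, 1], P[, 1], `-`)^2 + outer(P[, 2], P[, 2], `-`)^2
  mask <- outer(spec$subband, spec$subband, `==`)
  list(d2 = d2, mask = mask)
}

gaussian_kernel_matrix <- function(spec, deriv = c("none", "sigma", "c")) {
  deriv <- match.arg(deriv)
  geo <- kernel_geometry(spec)
  s <- spec$sigma
  base <- exp(-geo$d2 / (2 * s^2))          # sigma_k applies to row k
  amp <- switch(deriv,
    none  = spec$c * spec$dp / (2 * pi * s^2),
    # d/d sigma_k of row k: c dp/(2 pi sigma^5) (Delta^2 - 2 sigma^2) exp(.)
    sigma = spec$c * spec$dp / (2 * pi * s^5),
    c     = spec$dp / (2 * pi * s^2))
  M <- row_scale(amp, base)
  if (deriv == "sigma") M <- M * (geo$d2 - 2 * s^2)
  M[!geo$mask] <- 0
  M
}

#' @rdname gaussian_kernel_spec
#' @param spec a `gaussian_kernel_spec`.
#' @export
build_gaussian_H <- function(spec) {
  stopifnot(inherits(spec, "gaussian_kernel_spec"))
  gaussian_kernel_matrix(spec, deriv = "none")
}

# group-level parameter values (first sensor of each group) and expansion
kernel_group_values <- function(spec, what = c("sigma", "c")) {
  what <- match.arg(what)
  v <- spec[[what]]
  struct <- spec[[paste0(what, "_struct")]]
  if (is.null(struct)) return(v)
  idx <- apply(struct, 2L, function(col) which(col == 1)[1])
  v[idx]
}

kernel_set_group_values <- function(spec, what, values) {
  struct <- spec[[paste0(what, "_struct")]]
  if (is.null(struct)) {
    stopifnot(length(values) == spec$d)
    spec[[what]] <- as.numeric(values)
  } else {
    stopifnot(length(values) == ncol(struct))
    spec[[what]] <- as.numeric(struct %*% values)
  }
  if (any(spec[[what]] <= 0)) stop(sprintf("%s must stay positive", what))
  spec
}
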