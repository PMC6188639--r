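#' The 3-pixel cartoon model
#'
#' A two-layer L+NL system on three-pixel images, small enough that every
#' analytic quantity has a readable closed form.  Layer 1 is brightness from
#' luminance: spectral integration is the identity on luminance triplets and
#' the nonlinearity is the power law `x1 = (y1)^gamma1`.  Layer 2 applies
#' frequency-selective analyzers (rows of `F`: DC, low-frequency AC,
#' high-frequency AC) with CSF-like band-pass gains `G = diag(0.8, 1, 0.2)`,
#' followed by the saturating contrast response
#' `x2 = sign(y2) |y2| / (b + |y2|)` (divisive normalization with
#' `gamma = 1` and identity interaction kernel: interactions between
#' coefficients are neglected).
#'
#' The analyzer matrix is orthonormal to the printed 3-decimal precision
#' (`|det F| = 0.99945`).
#'
#' @param gamma1 brightness exponent in `(0, 1]` (default 0.65).
#' @param b semisaturation of the contrast response (scalar or length 3).
#' @return an [lnl_cascade()] carrying attribute `cartoon` with the pieces
#'   (`gamma1`, `b`, `F`, `G`) used by the closed forms.
#' @export
build_cartoon_model <- function(gamma1 = 0.65, b = 1) {
  stopifnot(gamma1 > 0, gamma1 <= 1, all(b > 0))
  F <- rbind(c(0.577,  0.577,  0.577),
             c(0.707,  0.000, -0.707),
             c(0.408, -0.817,  0.408))
  G <- diag(c(0.8, 1, 0.2))
  b <- rep_len(b, 3)
  casc <- lnl_cascade(
    lnl_layer(diag(3), tg_nonlin(gamma1, gamma1), name = "brightness"),
    lnl_layer(G %*% F, dn_nonlin(gamma = 1, b = b, H = diag(3)),
              name = "contrast"))
  attr(casc, "cartoon") <- list(gamma1 = gamma1, b = b, F = F, G = G)
  casc
}

#' Closed forms of the cartoon model
#'
#' `cartoon_sensitivity()` evaluates the three-bracket closed form of the
#' sensitivity `|grad S|^2` (brightness factor, contrast-saturation factor,
#' CSF-gain factor, times `det(F)^2`); `cartoon_filter_impact()` evaluates
#' the closed-form impact of a perturbation `dF_k` of the `k`-th frequency
#' analyzer,
#' `dx_k2 = (1 - |x_k2|)/(b_k + |y_k2|) * G_kk * (dF_k . x1)`.
#' Both must agree with the generic chain-rule machinery
#' ([sensitivity()], [filter_uncertainty_impact()]) to numerical precision;
#' that equality is part of the test suite.
#'
#' @param x0 three-pixel stimulus (positive luminances).
#' @param model a [build_cartoon_model()] cascade.
#' @export
cartoon_sensitivity <- function(x0, model) {
  p <- attr(model, "cartoon")
  st <- forward_cascade(x0, model)
  y1 <- st[[1]]$y
  y2 <- st[[2]]$y
  x2 <- st[[2]]$x
  d <- 3
  bright <- p$gamma1^(2 * d) * prod(y1^(2 * (p$gamma1 - 1)))
  sat <- prod((p$b + abs(y2))^-2) * prod((1 - abs(x2))^2)
  gains <- prod(diag(p$G)^2)
  bright * sat * gains * det(p$F)^2
}

#' @rdname cartoon_sensitivity
#' @param filter_row which analyzer row of `F` is perturbed.
#' @param dF perturbation row vector (length 3).
#' @return `cartoon_filter_impact()`: the response change of sensor
#'   `filter_row` (the identity interaction kernel confines the impact to
#'   that sensor).
#' @export
cartoon_filter_impact <- function(x0, model, filter_row, dF) {
  p <- attr(model, "cartoon")
  st <- forward_cascade(x0, model)
  x1 <- st[[1]]$x
  y2 <- st[[2]]$y
  x2 <- st[[2]]$x
  k <- filter_row
  (1 - abs(x2[k])) / (p$b[k] + abs(y2[k])) * p$G[k, k] * sum(dF * x1)
}

# ---- orthonormal Haar wavelet -----------------------------------------

# multi-level 1-d orthonormal Haar transform with coefficient bookkeeping
haar_1d <- function(n, levels) {
  stopifnot(n %% 2^levels == 0)
  W <- diag(n)
  # after all levels, rows 1:(n/2^levels) are the approximation
  for (lev in seq_len(levels)) {
    m <- n / 2^(lev - 1)
    A <- matrix(0, m / 2, m)
    D <- matrix(0, m / 2, m)
    for (j in seq_len(m / 2)) {
      A[j, c(2 * j - 1, 2 * j)] <- 1 / sqrt(2)
      D[j, 2 * j - 1] <- 1 / sqrt(2)
      D[j, 2 * j] <- -1 / sqrt(2)
    }
    S <- diag(n)
    S[1:m, 1:m] <- rbind(A, D)
    W <- S %*% W
  }
  # spacing (in samples) and center position of each coefficient
  spacing <- integer(n)
  pos <- numeric(n)
  na <- n / 2^levels
  spacing[1:na] <- 2^levels
  pos[1:na] <- (seq_len(na) - 0.5) * 2^levels
  off <- na
  for (lev in levels:1) {
    nd <- n / 2^lev
    spacing[off + seq_len(nd)] <- 2^lev
    pos[off + seq_len(nd)] <- (seq_len(nd) - 0.5) * 2^lev
    off <- off + nd
  }
  band <- integer(n)
  band[1:na] <- 0L                      # approximation
  off <- na
  for (lev in levels:1) {
    nd <- n / 2^lev
    band[off + seq_len(nd)] <- lev      # detail level (coarsest = levels)
    off <- off + nd
  }
  list(W = W, spacing = spacing, pos = pos, band = band)
}

#' Separable 2-d orthonormal Haar transform
#'
#' Tensor product of two multi-level 1-d Haar transforms, acting on
#' vectorized `size x size` single-band images in the package scan order.
#' Returns the orthonormal matrix plus per-coefficient subband bookkeeping
#' (subband id, spatial center in deg, grid cell area in deg^2) used to
#' build intra-subband Gaussian interaction kernels and per-subband blurs.
#'
#' @param size image side (divisible by `2^levels`).
#' @param levels number of scales.
#' @param samples_per_deg retinal sampling density.
#' @export
haar_2d <- function(size, levels = 2, samples_per_deg = 80) {
  h1 <- haar_1d(size, levels)
  W <- kronecker(h1$W, h1$W)  # rows index (row-coef, col-coef), row-major
  idx_r <- rep(seq_len(size), each = size)
  idx_c <- rep(seq_len(size), times = size)
  band <- interaction(h1$band[idx_r], h1$band[idx_c], drop = TRUE)
  pos <- cbind(h1$pos[idx_r], h1$pos[idx_c]) / samples_per_deg
  dp <- h1$spacing[idx_r] * h1$spacing[idx_c] / samples_per_deg^2
  spacing <- pmax(h1$spacing[idx_r], h1$spacing[idx_c])
  list(W = W, subband = as.integer(band), positions = pos, dp = dp,
       spacing = spacing, samples_per_deg = samples_per_deg)
}

# subband geometry (index set + spatial grid) for the measurement simulator;
# each subband is a (possibly anisotropic) grid of row-coef x col-coef pairs
# and its linear indices, sorted, traverse that grid row-major
haar_geometry <- function(hw, size) {
  idx_r <- rep(seq_len(size), each = size)
  idx_c <- rep(seq_len(size), times = size)
  bands <- sort(unique(hw$subband))
  subbands <- lapply(bands, function(bid) {
    idx <- which(hw$subband == bid)
    list(idx = idx,
         h = length(unique(idx_r[idx])),
         w = length(unique(idx_c[idx])),
         spd = hw$samples_per_deg / max(hw$spacing[idx]))
  })
  list(subbands = subbands, samples_per_deg = hw$samples_per_deg)
}

#' Reduced four-layer cascade
#'
#' A desk-scale analog of the full psychophysical program -- brightness,
#' local contrast, CSF-filtered contrast with spatial masking, and wavelet
#' decomposition with intra-subband masking -- on `size x size` luminance
#' images.  All four stages are square and invertible by construction
#' (interaction pools `c` and semisaturations `b` are sized so the
#' divisive-normalization invertibility condition, spectral radius of
#' `D_|x| H` below 1, holds with slack on the synthetic fixture grid; see
#' [invertibility_sweep()]).
#'
#' The exact psychophysically calibrated parameters of the full-scale model
#' are out of scope; the defaults here are documented package choices, with
#' the masking exponent `gamma = 0.65` as the one experimentally anchored
#' value.
#'
#' `variant = "alt"` swaps the brightness stage for a two-gamma tone mapping
#' and the wavelet masking for a Wilson-Cowan steady state, exercising the
#' modularity of the cascade calculus.
#'
#' @param size image side in pixels (divisible by 4).
#' @param samples_per_deg sampling density; the default makes the image
#'   subtend 1 degree of visual angle, the natural desk-scale reduction of a
#'   foveal patch.
#' @param gamma masking excitation exponent.
#' @param variant `"dn"` (all divisive normalization) or `"alt"`.
#' @export
build_reduced_fourlayer <- function(size = 16, samples_per_deg = size,
                                    gamma = 0.65, variant = c("dn", "alt")) {
  variant <- match.arg(variant)
  stopifnot(size %% 4 == 0, size <= 64)
  d <- size^2
  spd <- samples_per_deg
  px <- 1 / spd  # deg per pixel

  # pixel-grid kernel spec helper (single subband over the image);
  # interaction scales are tied to the pixel grid so the model behaves the
  # same at any sampling density
  pix_pos <- cbind(rep(seq_len(size) - 0.5, each = size),
                   rep(seq_len(size) - 0.5, times = size)) * px
  pix_kernel <- function(sigma_px, c_pool) {
    gaussian_kernel_spec(pix_pos, sigma = sigma_px * px, c = c_pool,
                         dp = px^2, subband = 1L)
  }

  # 1: brightness -- pointwise saturating power of luminance
  lay1 <- if (variant == "dn") {
    lnl_layer(diag(d), dn_nonlin(gamma = 0.65, b = 30, d = d),
              name = "brightness")
  } else {
    # luminance scaled to O(1) units, then a two-gamma tone curve
    lnl_layer(diag(d) / 100, tg_nonlin(gamma_l = 0.6, gamma_h = 0.9,
                                       mu1 = 1, m = 2),
              name = "brightness-tg")
  }

  # 2: local contrast -- deviation from (90% of) the local mean, normalized
  # by pooled local activity
  B2 <- gauss_conv_matrix(size, size, 2)
  lay2 <- lnl_layer(diag(d) - 0.9 * B2,
                    dn_nonlin(gamma = 1, b = 0.5,
                              kernel = pix_kernel(2, 0.5)),
                    name = "contrast")

  # 3: CSF-like filtering (high-frequency emphasis) + spatial masking
  B3 <- gauss_conv_matrix(size, size, 1)
  lay3 <- lnl_layer(1.5 * diag(d) - 0.5 * B3,
                    dn_nonlin(gamma = gamma, b = 0.7,
                              kernel = pix_kernel(1.5, 0.4)),
                    name = "csf-masking")

  # 4: orthonormal wavelet + intra-subband masking
  hw <- haar_2d(size, levels = 2, samples_per_deg = spd)
  # semisaturations sized so wavelet responses reach O(1) magnitudes: with
  # Fano-scaled response noise (var = F |r|) the relative noise falls as
  # 1/sqrt(|r|), as in psychophysically calibrated models; pools c keep the
  # invertibility radius |x| * c well below 1
  b4 <- ifelse(hw$subband == hw$subband[1], 1.5, 0.25)
  nl4 <- if (variant == "dn") {
    # interaction width of one coefficient spacing in each subband
    spec4 <- gaussian_kernel_spec(hw$positions,
                                  sigma = hw$spacing * px, c = 0.08,
                                  dp = hw$dp, subband = hw$subband)
    dn_nonlin(gamma = gamma, b = b4, kernel = spec4)
  } else {
    W4 <- exp(-abs(outer(seq_len(d), seq_len(d), `-`)) / 4)
    W4 <- W4 / rowSums(W4)
    wc_nonlin(alpha = 1, mu = 0.3, lam = 1, W = W4)
  }
  lay4 <- lnl_layer(hw$W, nl4, name = "wavelet-masking")

  lnl_cascade(list(lay1, lay2, lay3, lay4),
              geometry = haar_geometry(hw, size))
}

#' Invertibility margins of divisive-normalization layers
#'
#' Runs the forward pass on a set of stimuli and returns, per image and per
#' divisive-normalization layer, the spectral radius of `D_|x| H` at the
#' layer's response -- the quantity that must stay below 1 for the analytic
#' inverse to exist.
#'
#' @param cascade an [lnl_cascade()].
#' @param images list of stimulus vectors (or a matrix with one column per
#'   image).
#' @return tibble with columns `image`, `layer`, `radius`.
#' @export
invertibility_sweep <- function(cascade, images) {
  if (is.matrix(images)) images <- asplit(images, 2L)
  rows <- list()
  for (im in seq_along(images)) {
    st <- forward_cascade(as.numeric(images[[im]]), cascade)
    for (i in seq_len(cascade$n)) {
      nl <- cascade$layers[[i]]$nonlin
      if (inherits(nl, "dn_nonlin")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image = im, layer = i,
          radius = dn_invertibility_margin(st[[i]]$x, nl))
      }
    }
  }
  do.call(rbind, rows)
}
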