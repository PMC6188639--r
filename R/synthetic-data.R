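#' Luminance x contrast grid of natural-like images
#'
#' Seeded generator of 1/f Gaussian-field images rescaled to target mean
#' luminance and RMS contrast, covering the illumination range of a
#' conventional display.  Defaults: a 7 x 9 grid with average luminances in
#' \[25, 80\] cd/m^2, RMS contrasts in \[0.1, 0.9\], display range
#' \[0, 160\] cd/m^2 and spectral slope 1 (amplitude falling as `1/f`),
#' which preserves the spectral falloff and local correlation of natural
#' scenes without requiring any external image database.
#'
#' Contrast here is RMS contrast, `sd(x)/mean(x)`.  A Gaussian field cannot
#' reach high RMS contrast inside a bounded positive display range, so the
#' standardized field is iteratively clamped to the per-cell feasible bound
#' and re-standardized; the mean/contrast targets are then met affinely
#' (exactly), at the cost of an increasingly bimodal pixel distribution at
#' high contrast (as in natural high-contrast scenes).  Cells whose bound is
#' infeasible (`< 1` in standardized units) are flagged.
#'
#' @param size image side in pixels.
#' @param n_lum,n_con grid dimensions.
#' @param lum_range,con_range target ranges.
#' @param display_range luminance range of the display (cd/m^2).
#' @param spectral_slope exponent of the `1/f^slope` amplitude spectrum.
#' @export
image_grid_spec <- function(size = 16, n_lum = 7, n_con = 9,
                            lum_range = c(25, 80), con_range = c(0.1, 0.9),
                            display_range = c(0, 160), spectral_slope = 1) {
  structure(list(size = size,
                 lum_values = seq(lum_range[1], lum_range[2],
                                  length.out = n_lum),
                 con_values = seq(con_range[1], con_range[2],
                                  length.out = n_con),
                 display_range = display_range,
                 spectral_slope = spectral_slope),
            class = "image_grid_spec")
}

# one standardized 1/f field (mean 0, sd 1), row-major h x w
one_over_f_field <- function(size, slope) {
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  f2 <- outer(fr^2, fr^2, `+`)
  amp <- 1 / sqrt(f2)^slope
  amp[1, 1] <- 0
  ph <- matrix(stats::rnorm(size^2), size) +
    1i * matrix(stats::rnorm(size^2), size)
  z <- Re(stats::fft(amp * ph, inverse = TRUE)) / size^2
  z <- (z - mean(z)) / stats::sd(z)
  z
}

# clamp-and-restandardize until the standardized field fits the bound;
# the effective clamp level shrinks until mean 0 / sd 1 and |z| <= bound
# hold together (guaranteed for bound >= 1: the limit is a two-point field)
bound_field <- function(z, bound, iters = 200) {
  zs <- (z - mean(z)) / stats::sd(z)
  if (max(abs(zs)) <= bound) return(zs)
  b_eff <- bound
  for (i in seq_len(iters)) {
    zc <- pmin(pmax(z, -b_eff), b_eff)
    zs <- (zc - mean(zc)) / stats::sd(zc)
    if (max(abs(zs)) <= bound) return(zs)
    b_eff <- b_eff * 0.97
  }
  zs
}

generate_grid_image <- function(spec, lum, con) {
  z <- one_over_f_field(spec$size, spec$spectral_slope)
  lo <- lum - spec$display_range[1]
  hi <- spec$display_range[2] - lum
  bound <- min(lo, hi) / (lum * con)
  if (bound < 1) {
    attr(z, "infeasible") <- TRUE
    z <- (z - mean(z)) / stats::sd(z)
  } else {
    z <- bound_field(z, bound)
  }
  img <- lum * (1 + con * z)
  st <- vectorize(matrix(img, spec$size, spec$size))
  attr(st, "infeasible") <- isTRUE(attr(z, "infeasible"))
  st
}

#' @rdname image_grid_spec
#' @param spec an `image_grid_spec`.
#' @param seed RNG seed; same seed, bit-identical images.
#' @return `generate_image_grid()`: list with `images` (list of
#'   [stimulus][vectorize] vectors) and `manifest` (tibble: cell, lum, con,
#'   achieved mean/contrast, clipping flag).
#' @export
generate_image_grid <- function(spec, seed = 1) {
  with_seed(seed, {
    images <- list()
    rows <- list()
    cell <- 0L
    for (lum in spec$lum_values) {
      for (con in spec$con_values) {
        cell <- cell + 1L
        img <- generate_grid_image(spec, lum, con)
        images[[cell]] <- img
        rows[[cell]] <- tibble::tibble(
          cell = cell, lum = lum, con = con,
          mean_achieved = mean(img),
          con_achieved = stats::sd(img) / mean(img),
          clipped = min(img) < spec$display_range[1] ||
            max(img) > spec$display_range[2],
          infeasible = isTRUE(attr(img, "infeasible")))
      }
    }
    list(images = images, manifest = do.call(rbind, rows))
  })
}

#' Ensembles of natural-like 3-pixel stimuli
#'
#' Correlated Gaussian triplets (neighboring-pixel correlation `rho`,
#' AR(1)-style covariance) standardized per sample and rescaled so every
#' sample has exactly the requested average luminance and RMS contrast --
#' the stimulus sets used for sensitivity and efficiency sweeps over the
#' luminance/contrast plane.
#'
#' @param n number of samples.
#' @param lum average luminance (cd/m^2).
#' @param con RMS contrast (`con = 0` gives constant triplets).
#' @param rho neighboring-pixel correlation of the underlying field.
#' @param seed RNG seed.
#' @return `n x 3` matrix, one stimulus per row.
#' @export
generate_three_pixel_ensemble <- function(n, lum, con, rho = 0.9, seed = 1) {
  stopifnot(n >= 1, lum > 0, con >= 0)
  with_seed(seed, {
    if (con == 0) return(matrix(lum, n, 3))
    S <- rho^abs(outer(0:2, 0:2, `-`))
    Z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(S)
    m <- rowMeans(Z)
    # RMS contrast convention: population sd over the 3 pixels
    s <- sqrt(rowSums((Z - m)^2) / 3)
    s[s < 1e-12] <- 1e-12
    lum * (1 + con * (Z - m) / s)
  })
}

#' Synthetic mean-opinion-score dataset
#'
#' Stand-in for subjective quality databases: originals drawn from the
#' 3-pixel (or image) ensemble, distorted by white noise / smoothing /
#' contrast change with random amplitudes, and scored by a monotone
#' saturating link of the generating model's perceptual distance plus
#' observer noise.  The generating cascade and true distances are kept so
#' fitting can be validated against ground truth.
#'
#' @param cascade generating [lnl_cascade()].
#' @param n_items number of (original, distorted) pairs.
#' @param lum,con luminance/contrast of the originals.
#' @param observer_sd s.d. of the additive MOS noise (score units, 0-100).
#' @param seed RNG seed.
#' @return a [quality_dataset()] with `truth = list(cascade, distances)`.
#' @export
generate_mos_dataset <- function(cascade, n_items = 60, lum = 50, con = 0.4,
                                 observer_sd = 3, seed = 1) {
  d0 <- cascade$dims[1]
  with_seed(seed, {
    if (d0 == 3) {
      X <- generate_three_pixel_ensemble(n_items, lum, con, seed = NULL)
    } else {
      X <- t(replicate(n_items, lum * (1 + con * stats::rnorm(d0))))
    }
    fam <- sample(c("noise", "smooth", "contrast"), n_items, replace = TRUE)
    amp <- stats::runif(n_items, 0.02, 0.5)
    Z <- X
    for (c in seq_len(n_items)) {
      x <- X[c, ]
      Z[c, ] <- switch(fam[c],
        noise = x + amp[c] * lum * stats::rnorm(d0),
        smooth = (1 - amp[c]) * x + amp[c] * mean(x),
        contrast = mean(x) + (1 + amp[c]) * (x - mean(x)))
    }
    dist <- vapply(seq_len(n_items), function(c) {
      perceptual_distance(X[c, ], Z[c, ], cascade)
    }, numeric(1))
    half <- stats::median(dist)
    mos <- 100 * dist / (dist + half) + stats::rnorm(n_items, sd = observer_sd)
    quality_dataset(X, Z, mos,
                    truth = list(cascade = cascade, distances = dist,
                                 family = fam, amplitude = amp))
  })
}

#' Radially averaged spectral slope
#'
#' Amplitudes are averaged in radial frequency annuli (optionally across
#' several images to tame single-draw noise), then the least-squares slope
#' of `log mean amplitude` vs `log frequency` is fit over the band
#' `[2/size, 0.25]` cycles/pixel, where the 1/f behavior of natural-like
#' fields lives.
#'
#' @param imgs a square matrix / vectorized [stimulus][vectorize], or a list
#'   of them.
#' @export
estimate_spectral_slope <- function(imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  size <- NULL
  acc <- NULL
  for (img in imgs) {
    if (inherits(img, "stimulus") || is.null(dim(img))) img <- devectorize(img)
    size <- nrow(img)
    A <- Mod(stats::fft(img - mean(img)))
    acc <- if (is.null(acc)) A else acc + A
  }
  A <- acc / length(imgs)
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  f <- sqrt(outer(fr^2, fr^2, `+`))
  band <- f >= 2 / size & f <= 0.25
  bins <- cut(f[band], breaks = exp(seq(log(2 / size * 0.999),
                                        log(0.2501), length.out = 13)))
  mean_amp <- tapply(A[band], bins, mean)
  mid <- tapply(f[band], bins, mean)
  ok <- is.finite(mean_amp) & mean_amp > 0
  fit <- stats::lm(log(mean_amp[ok]) ~ log(mid[ok]))
  unname(stats::coef(fit)[2])
}
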