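#' Perceptual distance and second-order metric
#'
#' Perceptual distance between two stimuli is the Euclidean distance between
#' their responses, `D_P(xA, xB) = ||S(xB) - S(xA)||_2`.  For small
#' distortions it is approximated to second order by the quadratic form of
#' the metric matrix `M(xA) = J^T J` with `J = grad_x S(xA)`: the
#' discrimination regions become ellipsoids oriented by the eigenvectors of
#' `M`.
#'
#' In patch mode (`patches` = list of index vectors partitioning the
#' stimulus) the model is applied independently per patch, the squared
#' distances add, and the metric is block-diagonal with one block per patch.
#'
#' @param xA,xB stimulus vectors.
#' @param cascade an [lnl_cascade()] whose input dimension matches the
#'   stimulus (or the patch length in patch mode).
#' @param patches optional list of index vectors (see [patch_indices()]).
#' @export
perceptual_distance <- function(xA, xB, cascade, patches = NULL) {
  if (is.null(patches)) {
    return(sqrt(sum((respond(xB, cascade) - respond(xA, cascade))^2)))
  }
  sq <- vapply(patches, function(idx) {
    sum((respond(xB[idx], cascade) - respond(xA[idx], cascade))^2)
  }, numeric(1))
  sqrt(sum(sq))
}

#' @rdname perceptual_distance
#' @return `perceptual_metric()`: a `metric_matrix` -- the symmetric PSD
#'   `d0 x d0` matrix with attributes `anchor` and (in patch mode) `blocks`.
#' @export
perceptual_metric <- function(xA, cascade, patches = NULL) {
  if (is.null(patches)) {
    J <- jacobian_stimulus(cascade, xA)
    M <- crossprod(J)
    blocks <- NULL
  } else {
    d0 <- length(xA)
    M <- matrix(0, d0, d0)
    blocks <- vector("list", length(patches))
    for (p in seq_along(patches)) {
      idx <- patches[[p]]
      J <- jacobian_stimulus(cascade, xA[idx])
      blocks[[p]] <- crossprod(J)
      M[idx, idx] <- blocks[[p]]
    }
  }
  structure((M + t(M)) / 2, anchor = as.numeric(xA), blocks = blocks,
            patches = patches, class = "metric_matrix")
}

#' Non-overlapping square patches of a single-band image
#'
#' Index vectors (in the package scan order) of `patch_px x patch_px`
#' regions tiling an `h x w` image; used for block-structured metrics and
#' patch-wise MAD.
#'
#' @param h,w image size in pixels.
#' @param patch_px patch side; must divide `h` and `w`.
#' @export
patch_indices <- function(h, w, patch_px) {
  stopifnot(h %% patch_px == 0, w %% patch_px == 0)
  idx_of <- function(r, c) (r - 1L) * w + c   # band-col-row order, 1 band
  out <- list()
  for (pr in seq_len(h / patch_px)) {
    for (pc in seq_len(w / patch_px)) {
      rows <- (pr - 1L) * patch_px + seq_len(patch_px)
      cols <- (pc - 1L) * patch_px + seq_len(patch_px)
      out[[length(out) + 1L]] <-
        as.integer(outer(rows, cols, idx_of))
    }
  }
  out
}

#' Sensitivity: inverse volume of the discrimination region
#'
#' The volume of the just-noticeable-difference region around a stimulus is
#' inversely proportional to `det M(x) = |grad_x S|^2`; this determinant is
#' used as the (scalar) sensitivity of the model at `x`.  For non-square
#' Jacobians the Gram determinant `det(J^T J)` is used.  A rank-deficient
#' Jacobian gives 0 with attribute `rank_deficient = TRUE`.
#'
#' @param xA stimulus vector.
#' @param cascade an [lnl_cascade()].
#' @export
sensitivity <- function(xA, cascade) {
  J <- jacobian_stimulus(cascade, xA)
  s <- svd(J, nu = 0, nv = 0)$d
  if (length(s) && min(s) < 1e-12 * max(s)) {
    return(structure(0, rank_deficient = TRUE))
  }
  prod(s^2)
}

#' Multi-information reduction of a transform
#'
#' How much redundancy (shared bits) between coefficients a transform
#' removes:
#' \deqn{\Delta MI = \sum_k h(x^0_k) - \sum_k h(x^n_k)
#'       + E[\log_2 |\nabla_{x^0} S|].}
#' Marginal entropies are estimated with equal-width histograms
#' (`ceiling(n^(1/3))` bins, Miller-Madow bias correction, plus the
#' `log2(bin width)` differential term); the Jacobian term averages
#' `log2 |det J|` over the samples (optionally a seeded subsample, since the
#' entropies are cheap but the per-sample Jacobians are not).
#'
#' @param cascade a square [lnl_cascade()] (`d_n == d_0`).
#' @param samples `n x d0` matrix, one sample per row.
#' @param bins histogram bin count (default `ceiling(n^(1/3))`).
#' @param jac_subsample optional number of samples used for the Jacobian
#'   term.
#' @param seed seed for the subsample draw.
#' @return an `info_report` list: `delta_h`, `jac_term`, `delta_mi`
#'   (`= delta_h + jac_term` by construction), `n_samples`, `bins`,
#'   `n_dropped` (singular-Jacobian samples).
#' @export
delta_multi_information <- function(cascade, samples, bins = NULL,
                                    jac_subsample = NULL, seed = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  d0 <- ncol(samples)
  if (cascade$dims[1] != d0 || cascade$dims[cascade$n + 1L] != d0) {
    stop("delta_multi_information requires a square cascade (d_n == d_0)")
  }
  bins <- bins %||% ceiling(n^(1 / 3))
  resp <- t(respond(t(samples), cascade))
  delta_h <- sum(apply(samples, 2L, marginal_entropy, bins = bins)) -
    sum(apply(resp, 2L, marginal_entropy, bins = bins))
  idx <- seq_len(n)
  if (!is.null(jac_subsample) && jac_subsample < n) {
    idx <- with_seed(seed, sample.int(n, jac_subsample))
  }
  logdets <- vapply(idx, function(i) {
    dt <- det(jacobian_stimulus(cascade, samples[i, ]))
    if (is.finite(dt) && dt != 0) log2(abs(dt)) else NA_real_
  }, numeric(1))
  dropped <- sum(is.na(logdets))
  jac_term <- mean(logdets, na.rm = TRUE)
  structure(list(delta_h = delta_h, jac_term = jac_term,
                 delta_mi = delta_h + jac_term,
                 n_samples = n, bins = bins, n_dropped = dropped),
            class = "info_report")
}

#' @export
print.info_report <- function(x, ...) {
  cat(sprintf(
    "<info_report: delta_h %.3f + jac_term %.3f = delta_MI %.3f bits (n=%d%s)>\n",
    x$delta_h, x$jac_term, x$delta_mi, x$n_samples,
    if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

# equal-width histogram entropy (bits) with Miller-Madow correction and the
# differential log2(width) term
marginal_entropy <- function(x, bins) {
  r <- range(x)
  if (diff(r) == 0) return(-Inf)
  width <- diff(r) / bins
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts / length(x)
  p <- p[p > 0]
  -sum(p * log2(p)) + (length(p) - 1) / (2 * length(x) * log(2)) + log2(width)
}

#' Impact of filter uncertainty on the responses
#'
#' Sensitivity of the final response to a perturbation of one row of a
#' layer's linear filter bank, evaluated through the generic parameter
#' Jacobian at each sample: the response change is
#' `grad_L S . vect(dL^T)` with `dL` zero except for `perturbation` in row
#' `filter_row`.
#'
#' @param cascade an [lnl_cascade()].
#' @param layer layer index.
#' @param filter_row row of that layer's `L` being perturbed.
#' @param perturbation numeric vector, the row perturbation `dF_k`.
#' @param samples `n x d0` matrix of stimuli.
#' @return tibble with columns `sample`, `sensor`, `impact` (signed response
#'   change per output sensor).
#' @export
filter_uncertainty_impact <- function(cascade, layer, filter_row,
                                      perturbation, samples) {
  if (layer < 1 || layer > cascade$n) stop("invalid layer index")
  L <- cascade$layers[[layer]]$L
  stopifnot(filter_row >= 1, filter_row <= nrow(L),
            length(perturbation) == ncol(L))
  dL <- matrix(0, nrow(L), ncol(L))
  dL[filter_row, ] <- perturbation
  dvec <- as.vector(t(dL))
  free <- rep(list(character(0)), cascade$n)
  free[[layer]] <- "L"
  layout <- pack_params(cascade, free = free)$layout
  samples <- as.matrix(samples)
  out <- lapply(seq_len(nrow(samples)), function(i) {
    JL <- jacobian_params(cascade, samples[i, ], layout)
    dx <- as.numeric(JL %*% dvec)
    tibble::tibble(sample = i, sensor = seq_along(dx), impact = dx)
  })
  do.call(rbind, out)
}
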