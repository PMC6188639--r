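#' Stimuli as column vectors
#'
#' Vision models in this package act on stimuli rearranged as column vectors.
#' `vectorize()` turns an `h x w x b` luminance/radiance array (or an `h x w`
#' matrix, taken as a single band) into a `stimulus` object: a numeric vector
#' of length `h*w*b` carrying its shape so that `devectorize()` restores the
#' array bit-exactly.
#'
#' The scan order is last-dimension-first: bands vary fastest, then columns,
#' then rows.  Every matrix in the package that acts on stimulus vectors
#' (convolutions, wavelets, filter banks) is built for this order.
#'
#' @param img numeric array `h x w x b`, matrix, or plain numeric vector
#'   (kept as-is with shape `c(length, 1, 1)`).
#' @param calibration scalar mapping stored digital values to cd/m^2;
#'   the values are multiplied by it.
#' @return a `stimulus`: numeric vector with attributes `shape` and `scan`.
#' @examples
#' x <- vectorize(matrix(1:6, 2, 3))
#' all.equal(devectorize(x), matrix(1:6, 2, 3) * 1)
#' @export
vectorize <- function(img, calibration = 1) {
  if (is.null(dim(img))) {
    v <- as.numeric(img) * calibration
    stopifnot_finite(v, "stimulus values")
    return(new_stimulus(v, c(length(v), 1L, 1L)))
  }
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  stopifnot(length(dim(img)) == 3L)
  stopifnot_finite(img, "stimulus values")
  sh <- dim(img)
  # bands fastest, then columns, then rows
  v <- as.vector(aperm(img, c(3L, 2L, 1L))) * calibration
  new_stimulus(v, sh)
}

new_stimulus <- function(values, shape) {
  structure(as.numeric(values), shape = as.integer(shape),
            scan = "band-col-row", class = "stimulus")
}

#' @rdname vectorize
#' @param x a `stimulus` (or a plain vector together with `shape`).
#' @param shape optional `c(h, w, b)` overriding the stored shape.
#' @export
devectorize <- function(x, shape = NULL) {
  sh <- shape %||% attr(x, "shape")
  if (is.null(sh)) stop("no shape available; supply `shape`")
  stopifnot(length(x) == prod(sh))
  a <- array(as.numeric(x), dim = rev(sh))
  out <- aperm(a, c(3L, 2L, 1L))
  if (sh[3] == 1L) dim(out) <- sh[1:2]
  out
}

#' @export
print.stimulus <- function(x, ...) {
  sh <- attr(x, "shape")
  cat(sprintf("<stimulus %dx%dx%d, range [%.3g, %.3g]>\n",
              sh[1], sh[2], sh[3], min(x), max(x)))
  invisible(x)
}

#' Read / write calibrated luminance images
#'
#' Thin wrappers over PNG input/output.  `read_stimulus()` loads a PNG
#' (grayscale or color), applies the digital-to-luminance calibration factor
#' and returns a vectorized [stimulus][vectorize].  `write_stimulus()` divides
#' by the calibration, clips to \[0, 1\] and writes a PNG.
#'
#' There is no canonical calibration: it depends on the display the digital
#' values were shown on, so it is an explicit argument (default 1).
#'
#' @param path file path.
#' @param calibration cd/m^2 per digital unit.
#' @export
read_stimulus <- function(path, calibration = 1) {
  img <- png::readPNG(path)
  vectorize(img, calibration = calibration)
}

#' @rdname read_stimulus
#' @param x a `stimulus`.
#' @export
write_stimulus <- function(x, path, calibration = 1) {
  img <- devectorize(x) / calibration
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}
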