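#' Linear+nonlinear layers and cascades
#'
#' A layer applies a linear filter bank `y = L x` followed by a saturating
#' nonlinearity `x' = N(y)`; a cascade is an ordered composition of layers
#' `S = S(n) o ... o S(1)`.  Layer dimensions may shrink or grow: `L` is
#' `d_i x d_{i-1}` and adjacent layers must chain.
#'
#' @param L numeric matrix `d_i x d_{i-1}` (a scalar is taken as `1 x 1`).
#' @param nonlin a [nonlinearity] bundle; its dimension (when it has one)
#'   must equal `nrow(L)`.
#' @param name optional layer label used in error messages and summaries.
#' @param pinv_ridge ridge added to squared singular values when the layer
#'   is pseudo-inverted during decoding.
#' @return `lnl_layer()`: a layer; `lnl_cascade()`: a cascade.
#' @examples
#' lay <- lnl_layer(diag(2), dn_nonlin(gamma = 1, b = 1, d = 2))
#' casc <- lnl_cascade(lay)
#' respond(casc, c(1, 2))
#' @export
lnl_layer <- function(L, nonlin = id_nonlin(), name = NULL, pinv_ridge = 0) {
  L <- as.matrix(L)
  stopifnot_finite(L, "L")
  if (!is.null(nonlin$d) && nonlin$d != nrow(L)) {
    stop(sprintf("nonlinearity dimension %d does not match nrow(L) = %d",
                 nonlin$d, nrow(L)))
  }
  structure(list(L = L, nonlin = nonlin, name = name,
                 pinv_ridge = pinv_ridge),
            class = "lnl_layer")
}

#' @rdname lnl_layer
#' @param ... layers (or a single list of layers).
#' @param geometry optional list describing the spatial layout of the final
#'   response (fields `subbands`: list of `list(idx, h, w)`;
#'   `samples_per_deg`), used by the measurement simulator.
#' @export
lnl_cascade <- function(..., geometry = NULL) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "lnl_layer")) {
    layers <- layers[[1]]
  }
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "lnl_layer")))
  dims <- c(ncol(layers[[1]]$L),
            vapply(layers, function(l) nrow(l$L), integer(1)))
  for (i in seq_along(layers)[-1]) {
    if (ncol(layers[[i]]$L) != dims[i]) {
      stop(sprintf("layer %d expects input of length %d but layer %d outputs %d",
                   i, ncol(layers[[i]]$L), i - 1L, dims[i]))
    }
  }
  structure(list(layers = layers, n = length(layers), dims = dims,
                 geometry = geometry),
            class = "lnl_cascade")
}

#' @export
print.lnl_cascade <- function(x, ...) {
  cat(sprintf("<lnl_cascade: %d layer(s), dims %s>\n", x$n,
              paste(x$dims, collapse = " -> ")))
  for (i in seq_len(x$n)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] %s: L %dx%d + %s\n", i, l$name %||% "", nrow(l$L),
                ncol(l$L), class(l$nonlin)[1]))
  }
  invisible(x)
}

#' Forward evaluation of a layer and a cascade
#'
#' `forward_layer()` returns the linear drive `y = L x_prev` and the
#' nonlinear response `x = N(y)` of one layer.  `forward_cascade()` runs all
#' layers and returns every intermediate state; `respond()` returns only the
#' final response.  All three accept a matrix whose columns are samples.
#'
#' @param x_prev,x0 input vector (length matching the layer/cascade input
#'   dimension) or matrix of column samples.
#' @param layer an [lnl_layer()].
#' @param cascade an [lnl_cascade()].
#' @return `forward_layer()`: `list(y, x)`; `forward_cascade()`: list with
#'   one `list(y, x)` per layer; `respond()`: the final response.
#' @export
forward_layer <- function(x_prev, layer) {
  if (NROW(x_prev) != ncol(layer$L)) {
    stop(sprintf("dimension mismatch: input has length %d, layer expects %d",
                 NROW(x_prev), ncol(layer$L)))
  }
  y <- layer$L %*% as.matrix(x_prev)
  x <- nl_forward(layer$nonlin, y)
  if (is.null(dim(x_prev))) {
    list(y = as.numeric(y), x = as.numeric(x))
  } else {
    list(y = y, x = as.matrix(x))
  }
}

#' @rdname forward_layer
#' @export
forward_cascade <- function(x0, cascade) {
  states <- vector("list", cascade$n)
  xi <- x0
  for (i in seq_len(cascade$n)) {
    states[[i]] <- tryCatch(forward_layer(xi, cascade$layers[[i]]),
      error = function(e) {
        stop(sprintf("layer %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    xi <- states[[i]]$x
  }
  states
}

#' @rdname forward_layer
#' @export
respond <- function(x0, cascade) {
  st <- forward_cascade(x0, cascade)
  st[[cascade$n]]$x
}

#' @export
predict.lnl_cascade <- function(object, newdata, ...) respond(newdata, object)

# ---- parameter packing -------------------------------------------------

#' Flat parameter vector of a cascade
#'
#' Concatenates the free parameters of every layer into a single vector
#' `theta` with a layout table mapping slices back to (layer, parameter).
#' Matrix parameters (`L`, `H`) are vectorized row-wise, the convention all
#' parameter Jacobians in the package use.
#'
#' `free` selects which parameters enter `theta`: a list with one character
#' vector per layer (subset of `"L"` plus the nonlinearity's parameter
#' names), or a single character vector recycled to all layers.  The default
#' takes everything available.
#'
#' @param cascade an [lnl_cascade()].
#' @param free see above.
#' @return `pack_params()`: `list(theta, layout)`, `layout` a tibble with
#'   columns layer, param, offset, length, positive.  `unpack_params()`: the
#'   updated cascade.
#' @export
pack_params <- function(cascade, free = NULL) {
  layout <- param_layout(cascade, free)
  theta <- numeric(sum(layout$length))
  for (r in seq_len(nrow(layout))) {
    idx <- layout$offset[r] + seq_len(layout$length[r])
    theta[idx] <- get_layer_param(cascade$layers[[layout$layer[r]]],
                                  layout$param[r])
  }
  list(theta = theta, layout = layout)
}

#' @rdname pack_params
#' @param theta flat parameter vector.
#' @param layout layout table from `pack_params()`.
#' @export
unpack_params <- function(cascade, theta, layout) {
  stopifnot(length(theta) == sum(layout$length))
  for (r in seq_len(nrow(layout))) {
    idx <- layout$offset[r] + seq_len(layout$length[r])
    i <- layout$layer[r]
    cascade$layers[[i]] <- set_layer_param(cascade$layers[[i]],
                                           layout$param[r], theta[idx])
  }
  cascade
}

param_layout <- function(cascade, free = NULL) {
  if (is.character(free) || is.null(free)) {
    free <- rep(list(free), cascade$n)
  }
  stopifnot(length(free) == cascade$n)
  rows <- list()
  off <- 0L
  for (i in seq_len(cascade$n)) {
    lay <- cascade$layers[[i]]
    nlay <- nl_theta_layout(lay$nonlin)
    avail <- data.frame(param = c("L", nlay$param),
                        length = c(length(lay$L), nlay$length),
                        positive = c(FALSE, nlay$positive),
                        stringsAsFactors = FALSE)
    sel <- free[[i]] %||% avail$param
    bad <- setdiff(sel, avail$param)
    if (length(bad)) {
      stop(sprintf("layer %d has no parameter(s): %s", i,
                   paste(bad, collapse = ", ")))
    }
    avail <- avail[match(intersect(avail$param, sel), avail$param), ,
                   drop = FALSE]
    if (nrow(avail)) {
      avail$layer <- i
      avail$offset <- off + c(0L, cumsum(avail$length)[-nrow(avail)])
      off <- off + sum(avail$length)
      rows[[length(rows) + 1L]] <- avail
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(layer = integer(), param = character(),
                          offset = integer(), length = integer(),
                          positive = logical()))
  }
  out <- do.call(rbind, rows)
  tibble::as_tibble(out[, c("layer", "param", "offset", "length", "positive")])
}

get_layer_param <- function(layer, param) {
  if (param == "L") return(as.vector(t(layer$L)))
  lay <- nl_theta_layout(layer$nonlin)
  th <- nl_get_theta(layer$nonlin)
  pos <- c(0L, cumsum(lay$length))
  r <- match(param, lay$param)
  th[(pos[r] + 1L):pos[r + 1L]]
}

set_layer_param <- function(layer, param, value) {
  if (param == "L") {
    layer$L <- matrix(value, nrow(layer$L), ncol(layer$L), byrow = TRUE)
    return(layer)
  }
  lay <- nl_theta_layout(layer$nonlin)
  th <- nl_get_theta(layer$nonlin)
  pos <- c(0L, cumsum(lay$length))
  r <- match(param, lay$param)
  th[(pos[r] + 1L):pos[r + 1L]] <- value
  layer$nonlin <- nl_set_theta(layer$nonlin, th)
  layer
}

# ---- config serialization ---------------------------------------------

#' Serialize a cascade to / from a model configuration file
#'
#' Cascades round-trip through a plain list representation written as YAML
#' or JSON (chosen from the file extension).  Matrices are stored inline,
#' row-wise.  Gaussian-kernel layers store the kernel spec, not the
#' materialized `H`.
#'
#' @param cascade an [lnl_cascade()].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @export
write_cascade_config <- function(cascade, path) {
  cfg <- list(layers = lapply(cascade$layers, layer_to_config))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_cascade_config
#' @export
read_cascade_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  layers <- cfg$layers
  if (!is.null(names(layers))) layers <- list(layers)
  lnl_cascade(lapply(layers, layer_from_config))
}

mat_to_cfg <- function(M) list(nrow = nrow(M), values = as.vector(t(M)))
mat_from_cfg <- function(m) {
  v <- as.numeric(unlist(m$values))
  matrix(v, nrow = m$nrow, byrow = TRUE)
}

layer_to_config <- function(layer) {
  nl <- layer$nonlin
  base <- list(L = mat_to_cfg(layer$L), name = layer$name,
               pinv_ridge = layer$pinv_ridge)
  nlc <- switch(class(nl)[1],
    id_nonlin = list(type = "identity"),
    dn_nonlin = c(list(type = "dn", gamma = nl$gamma, b = nl$b),
                  if (is.null(nl$kernel)) list(H = mat_to_cfg(nl$H))
                  else list(kernel = kernel_to_config(nl$kernel))),
    wc_nonlin = list(type = "wc", alpha = nl$alpha, mu = nl$mu,
                     lam = nl$lam, W = mat_to_cfg(nl$W),
                     f = nl$f$name, slope = nl$f$slope),
    tg_nonlin = list(type = "tg", gamma_l = nl$gamma_l, gamma_h = nl$gamma_h,
                     mu1 = nl$mu1, m = nl$m, eps = nl$eps),
    stop("unsupported nonlinearity for serialization"))
  c(base, list(nonlin = nlc))
}

layer_from_config <- function(cfg) {
  nlc <- cfg$nonlin
  nl <- switch(nlc$type,
    identity = id_nonlin(),
    dn = if (!is.null(nlc$kernel)) {
      dn_nonlin(gamma = nlc$gamma, b = as.numeric(unlist(nlc$b)),
                kernel = kernel_from_config(nlc$kernel))
    } else {
      dn_nonlin(gamma = nlc$gamma, b = as.numeric(unlist(nlc$b)),
                H = mat_from_cfg(nlc$H))
    },
    wc = wc_nonlin(alpha = nlc$alpha, mu = nlc$mu, lam = nlc$lam,
                   W = mat_from_cfg(nlc$W), f = nlc$f, slope = nlc$slope),
    tg = tg_nonlin(nlc$gamma_l, nlc$gamma_h, nlc$mu1, nlc$m, nlc$eps),
    stop(sprintf("unknown nonlinearity type '%s'", nlc$type)))
  lnl_layer(mat_from_cfg(cfg$L), nl, name = cfg$name,
            pinv_ridge = cfg$pinv_ridge %||% 0)
}

kernel_to_config <- function(spec) {
  out <- list(positions = mat_to_cfg(spec$positions), sigma = spec$sigma,
              c = spec$c, dp = spec$dp, subband = spec$subband)
  if (!is.null(spec$sigma_struct)) out$sigma_struct <- mat_to_cfg(spec$sigma_struct)
  if (!is.null(spec$c_struct)) out$c_struct <- mat_to_cfg(spec$c_struct)
  out
}

kernel_from_config <- function(cfg) {
  has <- function(x) !is.null(x) && length(x) > 0
  gaussian_kernel_spec(
    positions = mat_from_cfg(cfg$positions),
    sigma = as.numeric(unlist(cfg$sigma)), c = as.numeric(unlist(cfg$c)),
    dp = as.numeric(unlist(cfg$dp)), subband = as.integer(unlist(cfg$subband)),
    sigma_struct = if (has(cfg$sigma_struct)) mat_from_cfg(cfg$sigma_struct),
    c_struct = if (has(cfg$c_struct)) mat_from_cfg(cfg$c_struct))
}
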