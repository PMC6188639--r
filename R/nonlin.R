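#' Nonlinearity interface
#'
#' Every layer of a cascade is a linear stage followed by a nonlinearity
#' bundle.  Bundles implement a small generic API used by the cascade
#' machinery:
#'
#' * `nl_forward(nl, y)` -- response `x = N(y)`; accepts a vector or a matrix
#'   whose columns are samples.
#' * `nl_inverse(nl, x)` -- analytic (or root-found) inverse.
#' * `nl_jacobian(nl, y)` -- Jacobian of the forward map w.r.t. `y`.
#' * `nl_param_jacobian(nl, y)` -- Jacobian w.r.t. the bundle's free
#'   parameters, columns ordered as in `nl_theta_layout(nl)`.
#' * `nl_theta_layout(nl)`, `nl_get_theta(nl)`, `nl_set_theta(nl, theta)` --
#'   flat parameter plumbing.
#'
#' Available bundles: [dn_nonlin()] (canonical divisive normalization),
#' [wc_nonlin()] (Wilson-Cowan steady state), [tg_nonlin()] (two-gamma tone
#' mapping) and [id_nonlin()] (identity, for purely linear stages).
#'
#' @param nl a nonlinearity bundle.
#' @param y,x numeric vector (or matrix of column samples for the forward /
#'   inverse maps).
#' @name nonlinearity
NULL

#' @rdname nonlinearity
#' @export
nl_forward <- function(nl, y) UseMethod("nl_forward")

#' @rdname nonlinearity
#' @param ... passed to methods (e.g. `method`, `order` for the divisive
#'   normalization inverse).
#' @export
nl_inverse <- function(nl, x, ...) UseMethod("nl_inverse")

#' @rdname nonlinearity
#' @export
nl_jacobian <- function(nl, y) UseMethod("nl_jacobian")

#' @rdname nonlinearity
#' @export
nl_param_jacobian <- function(nl, y) UseMethod("nl_param_jacobian")

#' @rdname nonlinearity
#' @export
nl_theta_layout <- function(nl) UseMethod("nl_theta_layout")

#' @rdname nonlinearity
#' @export
nl_get_theta <- function(nl) UseMethod("nl_get_theta")

#' @rdname nonlinearity
#' @param theta numeric vector matching `sum(nl_theta_layout(nl)$length)`.
#' @export
nl_set_theta <- function(nl, theta) UseMethod("nl_set_theta")

empty_layout <- function() {
  data.frame(param = character(), length = integer(),
             positive = logical(), stringsAsFactors = FALSE)
}

#' @rdname nonlinearity
#' @export
nl_theta_layout.default <- function(nl) empty_layout()

#' @rdname nonlinearity
#' @export
nl_get_theta.default <- function(nl) numeric(0)

#' @rdname nonlinearity
#' @export
nl_set_theta.default <- function(nl, theta) {
  stopifnot(length(theta) == 0L)
  nl
}

#' @rdname nonlinearity
#' @export
nl_param_jacobian.default <- function(nl, y) {
  matrix(0, nrow = length(y), ncol = 0L)
}

# ---- identity ----------------------------------------------------------

#' @rdname nonlinearity
#' @export
id_nonlin <- function() structure(list(), class = c("id_nonlin", "nonlinearity"))

#' @export
nl_forward.id_nonlin <- function(nl, y) y

#' @export
nl_inverse.id_nonlin <- function(nl, x, ...) x

#' @export
nl_jacobian.id_nonlin <- function(nl, y) diag(length(y))

#' @export
print.nonlinearity <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  invisible(x)
}
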