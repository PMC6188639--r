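# shared fixture builders: all randomness goes through an explicit seed

# valid random divisive-normalization bundle; drives kept away from 0 so the
# gamma-derivative log term and the |y|^(gamma-1) factor are well defined
random_dn <- function(d, gamma_range = c(0.6, 1.4), h_scale = 0.15) {
  dn_nonlin(gamma = stats::runif(1, gamma_range[1], gamma_range[2]),
            b = stats::runif(d, 0.5, 1.5),
            H = matrix(stats::runif(d * d, 0, h_scale), d, d))
}

random_drive <- function(d, min_abs = 0.2) {
  y <- stats::rnorm(d)
  sign(y) * (abs(y) + min_abs)
}

random_wc <- function(d) {
  W <- exp(-abs(outer(seq_len(d), seq_len(d), `-`)))
  W <- W / max(rowSums(W))
  wc_nonlin(alpha = 1, mu = stats::runif(1, 0.2, 0.6), lam = 1, W = W)
}

random_tg <- function() {
  tg_nonlin(gamma_l = stats::runif(1, 0.5, 0.9),
            gamma_h = stats::runif(1, 0.9, 1.3),
            mu1 = stats::runif(1, 0.5, 2), m = stats::runif(1, 1, 3))
}

# small random cascade mixing nonlinearity families
random_cascade <- function(dims, kinds = NULL) {
  n <- length(dims) - 1L
  kinds <- kinds %||% sample(c("dn", "tg", "wc"), n, replace = TRUE)
  layers <- lapply(seq_len(n), function(i) {
    L <- matrix(stats::rnorm(dims[i + 1] * dims[i]), dims[i + 1], dims[i])
    nl <- switch(kinds[i],
                 dn = random_dn(dims[i + 1]),
                 tg = random_tg(),
                 wc = random_wc(dims[i + 1]),
                 id = id_nonlin())
    lnl_layer(L, nl)
  })
  lnl_cascade(layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}
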