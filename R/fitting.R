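#' Quality-rating dataset
#'
#' Originals, distorted versions and mean opinion scores (MOS), the usual
#' ground truth for perceptual-metric fitting: the model's distances
#' `D_c = D_P(x_c, z_c)` should align with the scores `M_c`.
#'
#' @param originals `N x d0` matrix, one original stimulus per row.
#' @param distorted `N x d0` matrix of distorted stimuli `z_c = x_c + dx_c`.
#' @param mos numeric vector of length `N`.
#' @param truth optional list with generation ground truth (kept for
#'   recovery studies).
#' @export
quality_dataset <- function(originals, distorted, mos, truth = NULL) {
  originals <- as.matrix(originals)
  distorted <- as.matrix(distorted)
  stopifnot(nrow(originals) == nrow(distorted),
            nrow(originals) == length(mos),
            all(is.finite(distorted)))
  structure(list(originals = originals, distorted = distorted,
                 mos = as.numeric(mos), truth = truth),
            class = "quality_dataset")
}

#' @export
print.quality_dataset <- function(x, ...) {
  cat(sprintf("<quality_dataset: %d items, d0 = %d>\n",
              nrow(x$originals), ncol(x$originals)))
  invisible(x)
}

model_distances <- function(cascade, dataset, items = NULL) {
  items <- items %||% seq_len(nrow(dataset$originals))
  vapply(items, function(c) {
    perceptual_distance(dataset$originals[c, ], dataset$distorted[c, ],
                        cascade)
  }, numeric(1))
}

#' Gradient of the quadratic response-matching cost
#'
#' For observed responses `x_exp` to known inputs, the cost
#' `eps(Theta) = sum_c ||x_exp_c - S(x0_c, Theta)||^2` has gradient
#' `d eps / d Theta = -2 sum_c (x_exp_c - S(x0_c))^T grad_Theta S(x0_c)`.
#'
#' @param cascade an [lnl_cascade()].
#' @param x0_batch `n x d0` matrix of inputs (rows).
#' @param target_responses `n x dn` matrix of observed responses.
#' @param layout parameter layout from [pack_params()].
#' @return list with `value` (the cost) and `gradient` (length `d_Theta`).
#' @export
quadratic_cost_gradient <- function(cascade, x0_batch, target_responses,
                                    layout) {
  x0_batch <- as.matrix(x0_batch)
  target_responses <- as.matrix(target_responses)
  stopifnot(nrow(x0_batch) == nrow(target_responses))
  g <- numeric(sum(layout$length))
  val <- 0
  for (c in seq_len(nrow(x0_batch))) {
    r <- target_responses[c, ] - respond(x0_batch[c, ], cascade)
    val <- val + sum(r^2)
    g <- g - 2 * as.numeric(r %*% jacobian_params(cascade, x0_batch[c, ],
                                                  layout))
  }
  list(value = val, gradient = g)
}

#' Gradient of the inverse-consistency cost
#'
#' The decoding-side constraint `eps'(Theta) = sum_c ||x0_c -
#' S^-1(x_exp_c, Theta)||^2`, assembled from the identity
#' `grad_Theta S^-1 = -(grad_x0 S)^-1 grad_Theta S` evaluated at the decoded
#' point.
#'
#' @inheritParams quadratic_cost_gradient
#' @param responses `n x dn` matrix of observed responses (cascade must be
#'   square and invertible at them).
#' @export
inverse_consistency_gradient <- function(cascade, x0_batch, responses,
                                         layout) {
  x0_batch <- as.matrix(x0_batch)
  responses <- as.matrix(responses)
  g <- numeric(sum(layout$length))
  val <- 0
  for (c in seq_len(nrow(x0_batch))) {
    xhat <- cascade_inverse(responses[c, ], cascade)
    r <- x0_batch[c, ] - xhat
    val <- val + sum(r^2)
    Jinv_theta <- inverse_param_jacobian(cascade, xhat, layout)
    g <- g - 2 * as.numeric(r %*% Jinv_theta)
  }
  list(value = val, gradient = g)
}

#' Pearson alignment with opinion scores and its gradient
#'
#' `pearson_objective()` is the Pearson correlation between the mean opinion
#' scores `M` and the model distances `D(Theta)`.  Its gradient w.r.t. the
#' parameters chains the correlation derivative through the centering matrix
#' `(I - 11^T/N)` and, per item,
#' `dD_c/dTheta = (dx_c^n)^T / |dx_c^n| . [grad_Theta S(z_c) - grad_Theta
#' S(x_c)]`.  Items whose response difference is numerically zero carry no
#' gradient information and are dropped with a warning.
#'
#' @param cascade an [lnl_cascade()].
#' @param dataset a [quality_dataset()].
#' @param items optional item subset (rows of the dataset).
#' @export
pearson_objective <- function(cascade, dataset, items = NULL) {
  D <- model_distances(cascade, dataset, items)
  M <- dataset$mos[items %||% seq_along(dataset$mos)]
  if (length(M) < 3) stop("need at least 3 items")
  if (stats::sd(M) == 0 || stats::sd(D) == 0) {
    stop("zero variance in scores or distances; correlation undefined")
  }
  Ms <- M - mean(M)
  Ds <- D - mean(D)
  sum(Ms * Ds) / sqrt(sum(Ms^2) * sum(Ds^2))
}

#' @rdname pearson_objective
#' @param layout parameter layout from [pack_params()].
#' @export
pearson_gradient <- function(cascade, dataset, layout, items = NULL) {
  items <- items %||% seq_len(nrow(dataset$originals))
  N <- length(items)
  D <- model_distances(cascade, dataset, items)
  keep <- D > 1e-12
  if (!all(keep)) {
    warning(sprintf("%d item(s) with zero response difference dropped",
                    sum(!keep)))
    items <- items[keep]; D <- D[keep]; N <- length(items)
  }
  M <- dataset$mos[items]
  Ms <- M - mean(M); Ds <- D - mean(D)
  nM <- sqrt(sum(Ms^2)); nD <- sqrt(sum(Ds^2))
  # d rho / d D (row vector), including the centering matrix
  drho_dD <- Ms / (nM * nD) - sum(Ms * Ds) * Ds / (nM * nD^3)
  drho_dD <- drho_dD - mean(drho_dD)          # right-multiplied by (I - 11^T/N)
  g <- numeric(sum(layout$length))
  for (j in seq_len(N)) {
    c <- items[j]
    x <- dataset$originals[c, ]; z <- dataset$distorted[c, ]
    dresp <- respond(z, cascade) - respond(x, cascade)
    dD_dtheta <- as.numeric(
      (dresp / sqrt(sum(dresp^2))) %*%
        (jacobian_params(cascade, z, layout) -
           jacobian_params(cascade, x, layout)))
    g <- g + drho_dD[j] * dD_dtheta
  }
  g
}

#' Gradient-driven parameter fitting
#'
#' Seeded, reproducible gradient ascent/descent on a fitting objective, with
#' optional stochastic mini-batching and a train/held-out split.  Positivity
#' of parameters flagged positive in the layout (`gamma`, `b`, `sigma`, `c`)
#' is maintained by optimizing their logs.
#'
#' Objectives:
#' * `"pearson"` -- maximize [pearson_objective()] on a [quality_dataset()].
#' * `"quadratic"` -- minimize the response-matching cost; `data` is a list
#'   with `inputs` and `targets` matrices (rows = samples).
#'
#' Steps are accepted only when they improve the training objective
#' (backtracking halving, growth on success), so in deterministic mode the
#' training trace is monotone.  Early stopping monitors the held-out
#' objective with the given patience.
#'
#' @param cascade starting [lnl_cascade()].
#' @param data dataset (see above).
#' @param objective `"pearson"` or `"quadratic"`.
#' @param free free-parameter selection (see [pack_params()]).
#' @param max_iter iteration cap.
#' @param step initial step size in the (log-reparameterized) parameter
#'   space.
#' @param batch mini-batch size; `NULL` for full-batch deterministic mode.
#' @param holdout fraction of items held out (pearson only; 0 disables).
#' @param patience early-stopping patience on the held-out objective.
#' @param seed seed controlling the split and the batch schedule.
#' @param method `"gd"` -- backtracking gradient ascent/descent (monotone
#'   trace, supports mini-batches and early stopping); `"lbfgs"` --
#'   quasi-Newton refinement via [stats::optim()] on the log-reparameterized
#'   parameters with the analytic gradient (deterministic full-batch only;
#'   the tool of choice for noiseless parameter recovery).
#' @return a `fit_trace`: the fitted cascade plus a tibble trace of
#'   objective values.
#' @export
fit_cascade <- function(cascade, data, objective = c("pearson", "quadratic"),
                        free = NULL, max_iter = 100, step = 0.1,
                        batch = NULL, holdout = 0, patience = 20,
                        seed = 1, method = c("gd", "lbfgs")) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  packed <- pack_params(cascade, free)
  layout <- packed$layout
  maximize <- objective == "pearson"

  if (objective == "pearson") {
    stopifnot(inherits(data, "quality_dataset"))
    n_items <- nrow(data$originals)
    idx <- with_seed(seed, sample.int(n_items))
    n_test <- floor(holdout * n_items)
    test_items <- if (n_test > 0) idx[seq_len(n_test)] else integer(0)
    train_items <- setdiff(idx, test_items)
  } else {
    stopifnot(is.list(data), !is.null(data$inputs), !is.null(data$targets))
    train_items <- seq_len(nrow(as.matrix(data$inputs)))
    test_items <- integer(0)
    with_seed(seed, NULL)
  }

  eval_obj <- function(casc, items) {
    if (objective == "pearson") {
      pearson_objective(casc, data, items)
    } else {
      inp <- as.matrix(data$inputs)[items, , drop = FALSE]
      tgt <- as.matrix(data$targets)[items, , drop = FALSE]
      sum((tgt - t(respond(t(inp), casc)))^2)
    }
  }
  eval_grad <- function(casc, items) {
    if (objective == "pearson") {
      pearson_gradient(casc, data, layout, items)
    } else {
      inp <- as.matrix(data$inputs)[items, , drop = FALSE]
      tgt <- as.matrix(data$targets)[items, , drop = FALSE]
      quadratic_cost_gradient(casc, inp, tgt, layout)$gradient
    }
  }

  pos <- positivity_mask(layout)
  to_opt <- function(th) { th[pos] <- log(th[pos]); th }
  to_nat <- function(u) { u[pos] <- exp(u[pos]); u }
  u <- to_opt(packed$theta)
  casc <- cascade

  if (method == "lbfgs") {
    if (!is.null(batch) || holdout > 0) {
      stop("method = 'lbfgs' is deterministic full-batch only")
    }
    sgn <- if (maximize) -1 else 1   # optim minimizes
    evals <- list()
    fn <- function(uu) {
      cc <- try(unpack_params(cascade, to_nat(uu), layout), silent = TRUE)
      if (inherits(cc, "try-error")) return(1e10)
      val <- try(eval_obj(cc, train_items), silent = TRUE)
      if (inherits(val, "try-error") || !is.finite(val)) return(1e10)
      evals[[length(evals) + 1L]] <<- val
      sgn * val
    }
    gr <- function(uu) {
      cc <- unpack_params(cascade, to_nat(uu), layout)
      g <- eval_grad(cc, train_items)
      g[pos] <- g[pos] * to_nat(uu)[pos]
      sgn * g
    }
    opt <- stats::optim(u, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter,
                                       factr = 1e3, pgtol = 1e-12))
    final <- unpack_params(cascade, to_nat(opt$par), layout)
    vals <- unlist(evals)
    return(structure(list(
      cascade = final, layout = layout,
      theta = pack_params(final, free)$theta,
      trace = tibble::tibble(iter = seq_along(vals) - 1L, train = vals,
                             test = NA_real_, step = NA_real_),
      objective = objective, seed = seed, converged = opt$convergence == 0,
      train_items = train_items, test_items = test_items),
      class = "fit_trace"))
  }

  obj <- eval_obj(casc, train_items)
  test_obj <- if (length(test_items)) eval_obj(casc, test_items) else NA_real_
  best_test <- test_obj
  best_casc <- casc
  wait <- 0L
  trace <- list(tibble::tibble(iter = 0L, train = obj, test = test_obj,
                               step = step))
  lam <- step
  for (it in seq_len(max_iter)) {
    items <- if (is.null(batch)) train_items else
      sample(train_items, min(batch, length(train_items)))
    g_nat <- eval_grad(casc, items)
    # chain through the log reparameterization: du = dtheta * theta
    g <- g_nat
    g[pos] <- g[pos] * to_nat(u)[pos]
    dir <- if (maximize) g else -g
    accepted <- FALSE
    lam_try <- lam
    for (try in 1:20) {
      u_new <- u + lam_try * dir / max(sqrt(sum(dir^2)), 1e-12)
      casc_new <- try(unpack_params(cascade, to_nat(u_new), layout),
                      silent = TRUE)
      if (!inherits(casc_new, "try-error")) {
        obj_new <- try(eval_obj(casc_new, train_items), silent = TRUE)
        if (!inherits(obj_new, "try-error") && is.finite(obj_new)) {
          better <- if (maximize) obj_new > obj - 1e-12 else
            obj_new < obj + 1e-12
          if (!is.null(batch)) better <- TRUE  # stochastic mode: accept
          if (better) {
            u <- u_new; casc <- casc_new; obj <- obj_new
            accepted <- TRUE
            break
          }
        }
      }
      lam_try <- lam_try / 2
    }
    if (!accepted) break
    lam <- min(lam_try * 1.5, 10 * step)
    test_obj <- if (length(test_items)) eval_obj(casc, test_items) else NA_real_
    trace[[length(trace) + 1L]] <-
      tibble::tibble(iter = it, train = obj, test = test_obj, step = lam_try)
    if (length(test_items)) {
      improved <- if (maximize) test_obj > best_test else test_obj < best_test
      if (is.na(best_test) || improved) {
        best_test <- test_obj; best_casc <- casc; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  final <- if (length(test_items)) best_casc else casc
  structure(list(cascade = final, layout = layout,
                 theta = pack_params(final, free)$theta,
                 trace = do.call(rbind, trace),
                 objective = objective, seed = seed,
                 train_items = train_items, test_items = test_items),
            class = "fit_trace")
}

positivity_mask <- function(layout) {
  mask <- logical(sum(layout$length))
  for (r in seq_len(nrow(layout))) {
    if (layout$positive[r]) {
      mask[layout$offset[r] + seq_len(layout$length[r])] <- TRUE
    }
  }
  mask
}

#' @export
print.fit_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<fit_trace: %s, %d iterations, train %.4g -> %.4g%s>\n",
              x$objective, max(tr$iter), tr$train[1], tr$train[nrow(tr)],
              if (!all(is.na(tr$test)))
                sprintf(", test %.4g", tr$test[nrow(tr)]) else ""))
  invisible(x)
}
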