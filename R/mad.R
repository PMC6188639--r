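#' MAximum Differentiation stimulus synthesis
#'
#' Given a reference stimulus `xA` and a fixed Euclidean (RMSE) budget, MAD
#' looks for the stimuli on the sphere `||x - xA|| = radius` with maximum and
#' minimum perceptual distance to the reference under a vision model.  The
#' best and worst pair is a single-trial probe of the model: a good model
#' yields a visibly different pair.
#'
#' `mad_problem()` bundles the search settings; [mad_run()] performs the
#' sphere-constrained gradient search (both directions from the same seeded
#' white-noise start), [eigen_mad()] the analytic second-order solution via
#' the extremal eigenvectors of the metric.
#'
#' @param reference stimulus vector `xA`.
#' @param radius Euclidean distance budget (`> 0`).
#' @param step gradient step as a fraction of the radius (default 0.1).
#' @param max_iter iteration cap.
#' @param seed seed for the initial white-noise point.
#' @param patches optional patch structure (see [patch_indices()]).
#' @export
mad_problem <- function(reference, radius, step = 0.1, max_iter = 200,
                        seed = 1, patches = NULL) {
  stopifnot(radius > 0, step > 0)
  structure(list(reference = as.numeric(reference), radius = radius,
                 step = step, max_iter = max_iter, seed = seed,
                 patches = patches),
            class = "mad_problem")
}

#' Gradient of the perceptual distance w.r.t. the probe stimulus
#'
#' \deqn{\nabla_{x_B} D_P = \frac{(S(x_B) - S(x_A))^\top}{D_P}
#'       \nabla_{x^0} S(x_B),}
#' a row vector to be applied to column increments.  At `D_P = 0` the
#' gradient is undefined; a zero vector with attribute `zero_distance` is
#' returned.
#'
#' @param xB probe stimulus.
#' @param xA reference stimulus.
#' @param cascade an [lnl_cascade()].
#' @param patches optional patch structure.
#' @export
perceptual_distance_gradient <- function(xB, xA, cascade, patches = NULL) {
  if (is.null(patches)) {
    rA <- respond(xA, cascade)
    rB <- respond(xB, cascade)
    dp <- sqrt(sum((rB - rA)^2))
    if (dp == 0) {
      return(structure(numeric(length(xB)), zero_distance = TRUE))
    }
    return(as.numeric((rB - rA) %*% jacobian_stimulus(cascade, xB)) / dp)
  }
  # patch mode: D^2 = sum_p D_p^2, so grad D = (1/D) sum_p D_p grad D_p
  g <- numeric(length(xB))
  sq <- 0
  for (idx in patches) {
    rA <- respond(xA[idx], cascade)
    rB <- respond(xB[idx], cascade)
    diffp <- rB - rA
    sq <- sq + sum(diffp^2)
    g[idx] <- as.numeric(diffp %*% jacobian_stimulus(cascade, xB[idx]))
  }
  dp <- sqrt(sq)
  if (dp == 0) return(structure(numeric(length(xB)), zero_distance = TRUE))
  g / dp
}

#' One sphere-constrained MAD step
#'
#' Takes a gradient step of size `lambda` up (`direction = "max"`) or down
#' the perceptual distance, removes the component parallel to the gradient
#' of the Euclidean distance, and solves analytically for the projection
#' constant `nu` that puts the point back on the sphere exactly (of the two
#' real roots of the quadratic, the one nearer the pre-projection point is
#' taken).
#'
#' @param x_m current iterate (on the sphere).
#' @param problem a [mad_problem()].
#' @param cascade an [lnl_cascade()].
#' @param direction `"max"` or `"min"`.
#' @param lambda absolute step size (default `problem$step * radius`).
#' @export
mad_step <- function(x_m, problem, cascade, direction = c("max", "min"),
                     lambda = NULL) {
  direction <- match.arg(direction)
  lambda <- lambda %||% (problem$step * problem$radius)
  xA <- problem$reference
  g <- perceptual_distance_gradient(x_m, xA, cascade, problem$patches)
  s <- if (direction == "max") 1 else -1
  x_naive <- x_m + s * lambda * g
  # remove the component parallel to the Euclidean-distance gradient
  u <- x_naive - xA
  nu_e <- u / sqrt(sum(u^2))
  disp <- x_naive - x_m
  x_prime <- x_m + disp - sum(disp * nu_e) * nu_e
  # project back onto the sphere along the radial direction: solve
  # ||(x' - xA) + nu * w|| = radius for nu (quadratic, root nearest x')
  w <- x_prime - xA
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    return(xA + problem$radius * nu_e)
  }
  wh <- w / nw
  bq <- 2 * nw
  cq <- nw^2 - problem$radius^2
  disc <- bq^2 - 4 * cq
  roots <- c(-bq + sqrt(disc), -bq - sqrt(disc)) / 2
  nu <- roots[which.min(abs(roots))]
  xA + (w + nu * wh)
}

#' Run the MAD search
#'
#' From a seeded white-noise start on the sphere, runs both the
#' distance-maximizing and distance-minimizing searches with step-halving
#' line search (a step is accepted only if it improves the objective, so the
#' distance traces are monotone).
#'
#' @param problem a [mad_problem()].
#' @param cascade an [lnl_cascade()].
#' @param keep_iterates store every iterate (memory heavy).
#' @return a `mad_trace`: list with per-direction final stimuli and distance
#'   traces, plus the shared initial point.
#' @export
mad_run <- function(problem, cascade, keep_iterates = FALSE) {
  xA <- problem$reference
  noise <- with_seed(problem$seed, stats::rnorm(length(xA)))
  x0 <- xA + problem$radius * noise / sqrt(sum(noise^2))
  run_one <- function(direction) {
    x <- x0
    d <- perceptual_distance(x, xA, cascade, problem$patches)
    trace <- d
    iterates <- if (keep_iterates) list(x) else NULL
    lambda <- problem$step * problem$radius
    stall <- 0L
    for (it in seq_len(problem$max_iter)) {
      improved <- FALSE
      lam <- lambda
      for (try in 1:12) {
        xn <- mad_step(x, problem, cascade, direction, lambda = lam)
        dn <- perceptual_distance(xn, xA, cascade, problem$patches)
        ok <- if (direction == "max") dn >= d else dn <= d
        if (ok) { improved <- TRUE; break }
        lam <- lam / 2
      }
      if (!improved) break
      rel <- abs(dn - d) / max(d, .Machine$double.eps)
      x <- xn; d <- dn
      trace <- c(trace, d)
      if (keep_iterates) iterates[[length(iterates) + 1L]] <- x
      stall <- if (rel < 1e-8) stall + 1L else 0L
      if (stall >= 20L) break
    }
    list(final = x, distances = trace, iterates = iterates)
  }
  structure(list(max = run_one("max"), min = run_one("min"),
                 initial = x0, problem = problem),
            class = "mad_trace")
}

#' @export
print.mad_trace <- function(x, ...) {
  cat(sprintf(
    "<mad_trace: D_P %.4g (init) -> max %.4g in %d it / min %.4g in %d it>\n",
    x$max$distances[1], max(x$max$distances), length(x$max$distances) - 1L,
    min(x$min$distances), length(x$min$distances) - 1L))
  invisible(x)
}

#' Analytic (second-order) MAD solution
#'
#' In the local-linear approximation the discrimination regions are
#' ellipsoids, and the best/worst stimuli at fixed Euclidean radius lie
#' along the eigenvectors of the metric `M(xA)` with largest/smallest
#' eigenvalue.  In patch mode the metric is block-diagonal, so the global
#' eigenvector is a per-patch eigenvector embedded at the patch with the
#' globally extremal eigenvalue.
#'
#' Degenerate (tied) extremal eigenvalues are broken deterministically
#' (lowest index) and flagged via attribute `tie` on the result.
#'
#' @param xA reference stimulus.
#' @param cascade an [lnl_cascade()].
#' @param radius Euclidean budget.
#' @param patches optional patch structure.
#' @return list with `best`, `worst` (stimuli), `lambda_max`, `lambda_min`,
#'   and the unit directions `v_max`, `v_min`.
#' @export
eigen_mad <- function(xA, cascade, radius, patches = NULL) {
  M <- perceptual_metric(xA, cascade, patches)
  if (is.null(patches)) {
    eg <- eigen(unclass(M), symmetric = TRUE)
    lmax <- eg$values[1]; vmax <- eg$vectors[, 1]
    lmin <- eg$values[length(eg$values)]; vmin <- eg$vectors[, ncol(eg$vectors)]
    tie <- isTRUE(all.equal(eg$values[1], eg$values[min(2, length(eg$values))])) ||
      isTRUE(all.equal(eg$values[length(eg$values)],
                       eg$values[max(1, length(eg$values) - 1L)]))
  } else {
    blocks <- attr(M, "blocks")
    eigs <- lapply(blocks, function(B) eigen(B, symmetric = TRUE))
    maxs <- vapply(eigs, function(e) e$values[1], numeric(1))
    mins <- vapply(eigs, function(e) e$values[length(e$values)], numeric(1))
    pmax_i <- which.max(maxs); pmin_i <- which.min(mins)
    lmax <- maxs[pmax_i]; lmin <- mins[pmin_i]
    vmax <- numeric(length(xA)); vmin <- numeric(length(xA))
    vmax[patches[[pmax_i]]] <- eigs[[pmax_i]]$vectors[, 1]
    vmin[patches[[pmin_i]]] <-
      eigs[[pmin_i]]$vectors[, ncol(eigs[[pmin_i]]$vectors)]
    tie <- sum(abs(maxs - lmax) < 1e-12 * max(abs(lmax), 1)) > 1L ||
      sum(abs(mins - lmin) < 1e-12 * max(abs(lmin), 1)) > 1L
  }
  structure(list(best = xA + radius * vmin, worst = xA + radius * vmax,
                 lambda_max = lmax, lambda_min = lmin,
                 v_max = vmax, v_min = vmin),
            tie = tie)
}
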