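#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns a tibble of per-element results,
#' `glance()` a one-row summary.
#'
#' @param x a fitted/derived object from this package.
#' @param ... unused.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.fit_trace <- function(x, ...) x$trace

#' @rdname tidiers
#' @export
glance.fit_trace <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(objective = x$objective,
                 iterations = max(tr$iter),
                 train_initial = tr$train[1],
                 train_final = tr$train[nrow(tr)],
                 test_final = tr$test[nrow(tr)],
                 n_params = length(x$theta),
                 seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.mad_trace <- function(x, ...) {
  rbind(
    tibble::tibble(direction = "max",
                   iter = seq_along(x$max$distances) - 1L,
                   distance = x$max$distances),
    tibble::tibble(direction = "min",
                   iter = seq_along(x$min$distances) - 1L,
                   distance = x$min$distances))
}

#' @rdname tidiers
#' @export
glance.mad_trace <- function(x, ...) {
  tibble::tibble(initial = x$max$distances[1],
                 final_max = max(x$max$distances),
                 final_min = min(x$min$distances),
                 iterations_max = length(x$max$distances) - 1L,
                 iterations_min = length(x$min$distances) - 1L,
                 radius = x$problem$radius)
}

#' @rdname tidiers
#' @export
tidy.info_report <- function(x, ...) {
  tibble::tibble(term = c("delta_h", "jac_term", "delta_mi"),
                 bits = c(x$delta_h, x$jac_term, x$delta_mi))
}

#' Plots of traces and reports
#'
#' `autoplot()` methods: MAD distance traces, fitting objective curves and
#' decoding-error surfaces over the luminance/contrast grid.
#'
#' @param object object to plot.
#' @param ... unused.
#' @export
autoplot.mad_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$distance,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "perceptual distance",
                  title = "MAD search on the RMSE sphere")
}

#' @rdname autoplot.mad_trace
#' @export
autoplot.fit_trace <- function(object, ...) {
  df <- tidy(object)
  df_long <- rbind(
    tibble::tibble(iter = df$iter, objective = df$train, set = "train"),
    tibble::tibble(iter = df$iter, objective = df$test, set = "held-out"))
  df_long <- df_long[is.finite(df_long$objective), ]
  ggplot2::ggplot(df_long, ggplot2::aes(x = .data$iter, y = .data$objective,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = object$objective)
}

#' @rdname autoplot.mad_trace
#' @export
autoplot.decode_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$con, y = .data$lum,
                                       fill = .data$mae)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~decoder) +
    ggplot2::labs(x = "RMS contrast", y = "mean luminance (cd/m^2)",
                  fill = "MAE (cd/m^2)")
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
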