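#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reconstruction's objective trace
#'
#' @param x A `pat_recon`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `objective`.
#' @export
tidy.pat_recon <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = as.numeric(x$objective_trace))
}

#' One-row summary of a reconstruction
#'
#' @param x A `pat_recon`.
#' @param ... Unused.
#' @return One-row tibble: method, lambda, iterations, convergence flag,
#'   residual norm.
#' @export
glance.pat_recon <- function(x, ...) {
  tibble::tibble(method = x$params$method, lambda = x$params$lambda,
                 iterations = x$iterations, converged = x$converged,
                 residual_norm = x$residual_norm)
}

#' Tidy a dual solver state
#'
#' @param x A `pat_dual_state`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `dual_objective`.
#' @export
tidy.pat_dual_state <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$dual_objective_trace) - 1L,
                 dual_objective = as.numeric(x$dual_objective_trace))
}

#' @rdname tidy.pat_dual_state
#' @export
glance.pat_dual_state <- function(x, ...) {
  tibble::tibble(iterations = x$iterations_run, converged = x$converged,
                 step = x$step, epsilon = x$epsilon,
                 dual_objective = utils::tail(x$dual_objective_trace, 1),
                 u0 = x$levels$u0, u1 = x$levels$u1)
}

#' Image as a long tibble
#'
#' @param x A `pat_pressure_image`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `y_mm`, `value`.
#' @export
tidy.pat_pressure_image <- function(x, ...) {
  co <- grid_coords(x$grid)
  tibble::tibble(x_mm = rep(co$x, times = x$grid$ny),
                 y_mm = rep(co$y, each = x$grid$nx),
                 value = as.vector(x$values))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pressure image
#'
#' @param object A `pat_pressure_image`.
#' @param ... Unused.
#' @return A ggplot raster of the field in physical coordinates.
#' @export
autoplot.pat_pressure_image <- function(object, ...) {
  df <- tidy.pat_pressure_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Pa") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = object$role) +
    ggplot2::theme_minimal()
}

#' Plot a sinogram
#'
#' @param object A `pat_sinogram`.
#' @param ... Unused.
#' @return A ggplot raster, detectors vs time samples.
#' @export
autoplot.pat_sinogram <- function(object, ...) {
  df <- tibble::tibble(
    detector = rep(seq_len(nrow(object$values)), times = ncol(object$values)),
    sample = rep(seq_len(ncol(object$values)), each = nrow(object$values)),
    value = as.vector(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$detector,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "Pa") +
    ggplot2::labs(x = "time sample", y = "detector") +
    ggplot2::theme_minimal()
}

#' Plot an FP/FN error overlay
#'
#' Green marks false positives, pink false negatives, white true positives.
#'
#' @param object A `pat_metrics` report.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.pat_metrics <- function(object, ...) {
  co <- grid_coords(object$grid)
  cls <- matrix("background", nrow(object$fp_map), ncol(object$fp_map))
  cls[object$tp_map == 1] <- "true positive"
  cls[object$fp_map == 1] <- "false positive"
  cls[object$fn_map == 1] <- "false negative"
  df <- tibble::tibble(x_mm = rep(co$x, times = object$grid$ny),
                       y_mm = rep(co$y, each = object$grid$nx),
                       class = as.vector(cls))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      background = "black", `true positive` = "white",
      `false positive` = "#00c000", `false negative` = "#ff69b4")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Dice = %.4f", object$dice)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
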