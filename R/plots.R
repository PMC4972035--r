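#' Plot a tomogram slice
#'
#' @param object An `mt_volume`.
#' @param slice_index z slice (default middle).
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @method autoplot mt_volume
#' @export
autoplot.mt_volume <- function(object, slice_index = NULL, ...) {
  d <- dim(object$data)
  if (is.null(slice_index)) slice_index <- ceiling(d[3] / 2)
  sl <- object$data[, , slice_index]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("z slice", slice_index))
}

#' Convergence-metric curve across series counts
#'
#' @param cv_table Tibble with columns `n` (series count) and `cv`.
#' @return A ggplot line plot of the coefficient of variation versus the
#'   number of series folded into the reconstruction.
#' @export
plot_cv_curve <- function(cv_table) {
  ggplot2::ggplot(cv_table, ggplot2::aes(x = .data$n, y = .data$cv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of tilt series N",
                  y = "coefficient of variation")
}

#' Missing-fraction curve q(n)
#'
#' @param aspect,theta_max See [missing_fraction()].
#' @param n_max Largest (power-of-two) series count shown.
#' @return A ggplot of q(n) with the conical limit as a horizontal line.
#' @export
plot_missing_fraction <- function(aspect = 1, theta_max = 60, n_max = 32) {
  ns <- 2^(1:floor(log2(n_max)))
  df <- tibble::tibble(
    n = ns,
    q = vapply(ns, missing_fraction, numeric(1), aspect = aspect,
               theta_max = theta_max)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = 100 * .data$q)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = 100 * missing_fraction(Inf, aspect, theta_max),
      linetype = "dashed") +
    ggplot2::scale_x_log10(breaks = ns) +
    ggplot2::labs(x = "number of tilt series n",
                  y = "missing Fourier fraction q (%)")
}
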