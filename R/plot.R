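#' Plot empirical Lorenz points
#'
#' Draws the empirical Lorenz polygon together with the egalitarian
#' diagonal. Fitted curves can be overlaid with [lines.lorenz_fit()].
#'
#' @param x a `lorenz_points` object.
#' @param ... further arguments passed to [graphics::plot.default()].
#' @export
plot.lorenz_points <- function(x, ...) {
  graphics::plot(c(0, x$x), c(0, x$y), type = "l", lwd = 2,
                 xlab = "cumulative normalized rank of size",
                 ylab = "cumulative normalized size",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("Lorenz plot: %s", x$label), ...)
  graphics::abline(0, 1, lty = 3, col = "grey40")
  invisible(x)
}

#' Overlay a fitted Lorenz curve
#'
#' @param x a `lorenz_fit` object.
#' @param n_grid number of curve evaluation points.
#' @param ... further arguments passed to [graphics::lines()].
#' @export
lines.lorenz_fit <- function(x, n_grid = 512L, ...) {
  grid <- seq(0, 1, length.out = n_grid)
  graphics::lines(grid, model_curve(x$model, x$params)(grid), ...)
  invisible(x)
}

#' Render a Lorenz plot with fitted curves to a file
#'
#' The device is chosen from the file extension (`.png` or `.svg`).
#'
#' @param points empirical Lorenz points (or sizes).
#' @param fits named list of `lorenz_fit` objects to overlay.
#' @param file output path ending in `.png` or `.svg`.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `file`, invisibly.
#' @export
plot_lorenz_file <- function(points, fits = list(), file,
                             width = 7, height = 7) {
  points <- as_lorenz_points(points)
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") grDevices::png(file, width = width, height = height,
                                   units = "in", res = 150)
  else if (ext == "svg") grDevices::svg(file, width = width, height = height)
  else stop(sprintf("unsupported plot format '.%s' (use .png or .svg)", ext),
            call. = FALSE)
  on.exit(grDevices::dev.off())
  plot(points)
  if (length(fits) > 0L) {
    cols <- seq_along(fits) + 1L
    for (i in seq_along(fits)) lines(fits[[i]], col = cols[i], lwd = 2)
    graphics::legend("topleft", bty = "n",
                     legend = c("empirical", paste(names(fits), "model")),
                     col = c(1L, cols), lwd = 2,
                     lty = c(1, rep(1, length(fits))))
  }
  invisible(file)
}
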