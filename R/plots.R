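# Base-graphics displays of the validation output: explained-variation
# curves and the bisector calibration plot with its histogram of predicted
# values.

#' Plot explained-variation (R^2) prediction-error curves
#'
#' One line per prediction setting. When several windows `w` are present the
#' x-axis is the horizon `s + w` for fixed `s`; when several prediction
#' times are present the x-axis is `s` for fixed `w`.
#'
#' @param curves data.frame from [prediction_error_curve()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_error_curves <- function(curves, ...) {
  vary_w <- length(unique(curves$w)) > 1
  xvar <- if (vary_w) curves$s + curves$w else curves$s
  xlab <- if (vary_w) "prediction horizon s + w (years)"
          else "prediction time s (years)"
  settings <- unique(curves$setting)
  xs <- sort(unique(xvar))
  Y <- sapply(settings, function(st)
    curves$r2[curves$setting == st][order(xvar[curves$setting == st])])
  graphics::matplot(xs, Y, type = "b", pch = 19, lty = 1,
                    col = seq_along(settings), xlab = xlab,
                    ylab = expression(R^2), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = settings, col = seq_along(settings),
                   lty = 1, pch = 19, bty = "n")
  invisible(NULL)
}

#' Calibration plot (observed vs predicted, with histogram)
#'
#' Decile points with 95% confidence bars against the first bisector, and
#' below it the histogram of the predicted values in 5%-wide bins.
#'
#' @param tab a `"calibration_table"`.
#' @param main plot title.
#' @export
plot_calibration <- function(tab, main = "Calibration") {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- c(0, max(0.2, tab$mean_pred, tab$upper))
  graphics::plot(tab$mean_pred, tab$obs_prop, xlim = lim, ylim = lim,
                 pch = 19, xlab = "mean predicted risk",
                 ylab = "observed proportion", main = main)
  graphics::arrows(tab$mean_pred, tab$lower, tab$mean_pred, tab$upper,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(0, 1, lty = 2)
  h <- attr(tab, "histogram")
  graphics::barplot(as.numeric(h), names.arg = NULL, space = 0,
                    xlab = "predicted risk (5% bins)", ylab = "count")
  invisible(NULL)
}
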