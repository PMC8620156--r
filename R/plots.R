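# Diagnostic plots.  An adequate model shows RQRs scattered evenly
# around zero (within about +/-3) against fitted values, and a Q-Q plot
# hugging the identity line; misfit shows banding, trends or S-shapes.

resolve_values <- function(residuals)
  if (inherits(residuals, "rqr_resid")) residuals$values else residuals

open_device <- function(file, width = 6, height = 5) {
  if (is.null(file)) return(FALSE)
  if (grepl("\\.svg$", file, ignore.case = TRUE))
    grDevices::svg(file, width = width, height = height)
  else grDevices::png(file, width = width * 120, height = height * 120,
                      res = 120)
  TRUE
}

#' Residual-vs-fitted scatter plot
#'
#' Residuals against fitted values with a reference line at 0 and
#' guides at -3 and +3 (the range standardized residuals of an
#' adequate model should essentially occupy).
#'
#' @param residuals An `rqr_resid` or numeric vector.
#' @param fitted Fitted values (same length).
#' @param file Output PNG/SVG path, or `NULL` to draw on the current
#'   device.
#' @param log_fitted Plot fitted values on a log axis? (Sequencing
#'   counts span orders of magnitude.)
#' @param ... Passed to [graphics::plot()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_residual_scatter <- function(residuals, fitted, file = NULL,
                                  log_fitted = TRUE, ...) {
  r <- resolve_values(residuals)
  stopifnot(length(r) == length(fitted))
  dev <- open_device(file)
  if (dev) on.exit(grDevices::dev.off())
  ylim <- range(c(r, -3.2, 3.2))
  graphics::plot(fitted, r, ylim = ylim,
                 log = if (log_fitted && all(fitted > 0)) "x" else "",
                 xlab = "fitted value", ylab = "residual",
                 pch = 16, col = grDevices::adjustcolor("black", 0.6), ...)
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(h = c(-3, 3), lty = 2, col = "grey60")
  invisible(file)
}

#' Normal Q-Q plot of residuals
#'
#' Q-Q plot against the standard normal with the identity reference
#' line (intercept 0, slope 1 — not a fitted line: RQRs of an adequate
#' model are standard normal, not merely normal).
#'
#' @inheritParams plot_residual_scatter
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_qq <- function(residuals, file = NULL, ...) {
  r <- resolve_values(residuals)
  stopifnot(length(r) >= 3)
  dev <- open_device(file, width = 5, height = 5)
  if (dev) on.exit(grDevices::dev.off())
  stats::qqnorm(r, pch = 16, col = grDevices::adjustcolor("black", 0.6),
                main = "", ...)
  graphics::abline(0, 1, col = "grey40")
  invisible(file)
}
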