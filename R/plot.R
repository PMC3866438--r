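#' Plot a locational rate map in 20% peak-rate bands
#'
#' Renders the smoothed rate in five colour bands of 20% of the peak
#' rate, from dark blue (0-20%) to red (80-100%); unvisited bins are
#' white.
#'
#' @param x A `bvc_ratemap`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.bvc_ratemap <- function(x, ...) {
  z <- x$rate
  z[!x$visited] <- NA
  pk <- max(x$peak_rate, .Machine$double.eps)
  cols <- c("darkblue", "deepskyblue3", "green3", "orange", "red")
  graphics::image(x = x$xedges, y = x$yedges, z = z,
                  breaks = seq(0, pk, length.out = 6) + c(-1e-9, rep(0, 4), 1e-9),
                  col = cols, asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                  main = sprintf("peak %.2f Hz", x$peak_rate), ...)
  invisible(x)
}

#' Plot a directional polar map
#'
#' @param x A `bvc_polarmap`.
#' @param ... Passed to [graphics::lines()].
#' @export
plot.bvc_polarmap <- function(x, ...) {
  r <- ifelse(is.na(x$rate), 0, x$rate)
  a <- c(x$centres, x$centres[1])
  r <- c(r, r[1])
  graphics::plot(NA, xlim = c(-1, 1) * max(r), ylim = c(-1, 1) * max(r),
                 asp = 1, xlab = "", ylab = "",
                 main = sprintf("directional peak %.2f Hz", x$peak_rate))
  graphics::lines(r * cos(a), r * sin(a), ...)
  invisible(x)
}
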