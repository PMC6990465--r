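#' Scatter plot of viable samples for a two-parameter problem
#'
#' A minimal diagnostic: the viable points of a sample set inside the
#' bounding box, with projection values marked on the axes.  Only
#' available for problems whose free space is two-dimensional.
#'
#' @param problem a [tf_problem()].
#' @param samples a [sample_set()].
#' @param which_params the two parameters to plot (defaults to the first
#'   two reducible ones).
#' @param ... forwarded to [graphics::plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot_viable_samples <- function(problem, samples,
                                which_params = problem$catalog$reducible[1:2], ...) {
  stopifnot(length(which_params) == 2L)
  pts <- samples$points[, which_params, drop = FALSE]
  lo <- problem$space$lower[which_params]
  hi <- problem$space$upper[which_params]
  graphics::plot(pts[, 1L], pts[, 2L],
                 xlim = range(lo[1L], hi[1L], pts[, 1L]),
                 ylim = range(lo[2L], hi[2L], pts[, 2L]),
                 xlab = which_params[1L], ylab = which_params[2L],
                 pch = 16, col = "#2c7fb8", ...)
  graphics::rect(lo[1L], lo[2L], hi[1L], hi[2L], border = "grey40", lty = 2)
  pv <- problem$catalog$projection_values
  if (which_params[1L] %in% names(pv)) graphics::abline(v = pv[[which_params[1L]]], col = "#d95f02", lty = 3)
  if (which_params[2L] %in% names(pv)) graphics::abline(h = pv[[which_params[2L]]], col = "#d95f02", lty = 3)
  invisible(pts)
}
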