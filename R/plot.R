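#' Plot a skeleton projection
#'
#' Draws the edges of a skeleton projected onto a coordinate plane.
#'
#' @param x a [skeleton_tree()].
#' @param axes which two coordinates to draw (default mediolateral vs
#'   dorsoventral).
#' @param col line color.
#' @param add add to an existing plot.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the segment coordinates.
#' @export
plot.skeleton_tree <- function(x, axes = c("x", "y"), col = "black",
                               add = FALSE, ...) {
  nd <- x$nodes
  i <- match(x$edges$from, nd$id)
  j <- match(x$edges$to, nd$id)
  seg <- data.frame(x0 = nd[[axes[1]]][i] / 1e3, y0 = nd[[axes[2]]][i] / 1e3,
                    x1 = nd[[axes[1]]][j] / 1e3, y1 = nd[[axes[2]]][j] / 1e3)
  if (!add) {
    graphics::plot(NA, xlim = range(c(seg$x0, seg$x1)),
                   ylim = range(c(seg$y0, seg$y1)),
                   xlab = paste(axes[1], "(um)"), ylab = paste(axes[2], "(um)"),
                   main = x$name, ...)
  }
  graphics::segments(seg$x0, seg$y0, seg$x1, seg$y1, col = col)
  invisible(seg)
}

#' Normalized sagittal view of a cell in the layer model
#'
#' Restricts the skeleton to the most lateral `window_um` micrometres,
#' assigns normalized depths, and draws the cell in (dorsoventral,
#' normalized depth) coordinates with the four layer bands marked — the
#' "normalized to layer structure" rendering of the layer analysis.
#'
#' @param tree a [skeleton_tree()] (resampled for smooth rendering).
#' @param model a `layer_model`.
#' @param window_um sagittal clipping window (default 118).
#' @param col line color.
#' @return invisibly, the plotted data frame.
#' @export
sagittal_view <- function(tree, model, window_um = 118, col = "black") {
  cl <- sagittal_clip(tree, window_um)
  if (!nrow(cl$nodes) || !nrow(cl$edges)) return(invisible(NULL))
  a <- assign_depth(cl, model)
  nd <- cl$nodes
  i <- match(cl$edges$from, nd$id)
  j <- match(cl$edges$to, nd$id)
  keep <- a$in_footprint[i] & a$in_footprint[j]
  graphics::plot(NA, xlim = range(nd$y / 1e3), ylim = c(1.2, -0.2),
                 xlab = "dorsoventral (um)", ylab = "normalized depth",
                 main = tree$name)
  graphics::abline(h = c(0, 0.25, 0.5, 0.75, 1), col = "grey70", lty = 2)
  graphics::text(x = graphics::par("usr")[1], y = c(0.125, 0.375, 0.625, 0.875),
                 labels = paste("layer", 1:4), pos = 4, col = "grey40",
                 cex = 0.8)
  graphics::segments(nd$y[i][keep] / 1e3, a$depth[i][keep],
                     nd$y[j][keep] / 1e3, a$depth[j][keep], col = col)
  invisible(data.frame(y = nd$y, depth = a$depth))
}
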