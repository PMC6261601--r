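#' Plate outline point sets
#'
#' An expert-annotated skeletonized outline of the lobula plate, reduced to
#' its node positions. Points may carry an `anterior`/`posterior` side label;
#' unlabeled outlines are split geometrically by [split_outline()].
#'
#' @param points data frame with columns `x`, `y`, `z` (nm) and optionally
#'   `side` (`"anterior"`/`"posterior"`).
#' @return object of class `plate_outline`.
#' @export
plate_outline <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  structure(list(points = points), class = "plate_outline")
}

#' @export
print.plate_outline <- function(x, ...) {
  cat(sprintf("<plate_outline: %d points%s>\n", nrow(x$points),
              if (!is.null(x$points$side)) ", side-labeled" else ""))
  invisible(x)
}

#' Extract the plate outline from a skeleton annotation
#'
#' @param annotation a [skeleton_annotation()] holding the outline tracing.
#' @return a [plate_outline()]. Node comments containing "anterior" or
#'   "posterior" become side labels.
#' @export
outline_from_annotation <- function(annotation) {
  nodes <- do.call(rbind, lapply(annotation$trees, function(t) {
    t$nodes[, c("x", "y", "z", "comment")]
  }))
  pts <- nodes[, c("x", "y", "z")]
  cm <- tolower(ifelse(is.na(nodes$comment), "", nodes$comment))
  side <- rep(NA_character_, nrow(pts))
  side[grepl("anterior", cm)] <- "anterior"
  side[grepl("posterior", cm)] <- "posterior"
  if (!all(is.na(side))) pts$side <- side
  plate_outline(pts)
}

#' Split an outline into anterior and posterior point sets
#'
#' If the points carry side labels the split follows them. Otherwise a
#' quadratic mid-surface z = g(x, y) is fit by least squares and points are
#' assigned by the sign of their residual: below the mid-surface (smaller z,
#' more anterior) versus above. An outline whose points are all on one
#' surface (residuals indistinguishable from zero) cannot define a slab and
#' raises a degenerate-outline error.
#'
#' @param outline a [plate_outline()] with at least 8 points.
#' @return list with data frames `anterior` and `posterior` (columns x, y, z).
#' @export
split_outline <- function(outline) {
  pts <- outline$points
  if (nrow(pts) < 8) {
    stop_("split_outline: need at least 8 outline points",
          class = "lptc_degenerate_outline_error")
  }
  if (!is.null(pts$side) && !all(is.na(pts$side))) {
    ant <- pts[!is.na(pts$side) & pts$side == "anterior", c("x", "y", "z")]
    post <- pts[!is.na(pts$side) & pts$side == "posterior", c("x", "y", "z")]
  } else {
    fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = pts)
    res <- stats::residuals(fit)
    spread <- diff(range(pts$z))
    if (max(abs(res)) < max(spread, 1) * 1e-6) {
      stop_("split_outline: outline points are (quadratically) coplanar; ",
            "cannot separate anterior and posterior surfaces",
            class = "lptc_degenerate_outline_error")
    }
    ant <- pts[res < 0, c("x", "y", "z")]
    post <- pts[res >= 0, c("x", "y", "z")]
  }
  if (!nrow(ant) || !nrow(post)) {
    stop_("split_outline: one side of the outline is empty",
          class = "lptc_degenerate_outline_error")
  }
  rownames(ant) <- rownames(post) <- NULL
  list(anterior = ant, posterior = post)
}

check_support <- function(pts, what) {
  if (nrow(pts) < 4) {
    stop_("build_layer_model: ", what, " surface needs >= 4 support points",
          class = "lptc_model_error")
  }
  xy <- scale(as.matrix(pts[, c("x", "y")]), scale = FALSE)
  if (qr(xy)$rank < 2) {
    stop_("build_layer_model: ", what, " support points are collinear in ",
          "(ml, dv)", class = "lptc_model_error")
  }
}

surf_eval <- function(pts, x, y) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y)
  if (any(ok)) {
    r <- interp::interpp(pts$x, pts$y, pts$z, xo = x[ok], yo = y[ok],
                         linear = TRUE, duplicate = "mean")
    out[ok] <- r$z
  }
  out
}

#' Build the two-surface lobula plate model
#'
#' Each surface is a piecewise-linear interpolant z = f(x_ml, y_dv) over the
#' Delaunay triangulation of its support points; the footprint is the region
#' where both interpolants are defined (the intersection of the two convex
#' hulls). The model requires strictly positive thickness
#' (posterior - anterior) on the footprint; crossing surfaces are an error.
#'
#' @param anterior,posterior data frames with columns `x`, `y`, `z` (nm), as
#'   returned by [split_outline()].
#' @param check_grid resolution of the grid on which the positive-thickness
#'   invariant is verified.
#' @return object of class `layer_model`.
#' @export
build_layer_model <- function(anterior, posterior, check_grid = 25) {
  anterior <- as.data.frame(anterior)
  posterior <- as.data.frame(posterior)
  check_support(anterior, "anterior")
  check_support(posterior, "posterior")
  model <- structure(list(anterior = anterior, posterior = posterior),
                     class = "layer_model")
  # verify positive thickness on a grid over the footprint
  gx <- seq(max(min(anterior$x), min(posterior$x)),
            min(max(anterior$x), max(posterior$x)), length.out = check_grid)
  gy <- seq(max(min(anterior$y), min(posterior$y)),
            min(max(anterior$y), max(posterior$y)), length.out = check_grid)
  g <- expand.grid(x = gx, y = gy)
  ev <- predict(model, g)
  on_fp <- which(ev$in_footprint)
  if (length(on_fp) && any(ev$thickness[on_fp] <= 0)) {
    bad <- on_fp[which(ev$thickness[on_fp] <= 0)[1]]
    stop_(sprintf(
      "build_layer_model: surfaces cross on the footprint near (ml = %.0f, dv = %.0f) nm",
      g$x[bad], g$y[bad]), class = "lptc_model_error")
  }
  model
}

#' Evaluate the plate surfaces at query points
#'
#' @param object a `layer_model`.
#' @param newdata data frame with columns `x`, `y` (nm).
#' @param ... unused.
#' @return data frame with columns `anterior`, `posterior`, `thickness` (nm)
#'   and `in_footprint`.
#' @export
predict.layer_model <- function(object, newdata, ...) {
  a <- surf_eval(object$anterior, newdata$x, newdata$y)
  p <- surf_eval(object$posterior, newdata$x, newdata$y)
  data.frame(anterior = a, posterior = p, thickness = p - a,
             in_footprint = !is.na(a) & !is.na(p))
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf(
    "<layer_model: %d anterior + %d posterior support points>\n",
    nrow(x$anterior), nrow(x$posterior)))
  invisible(x)
}

#' Assign normalized depth and layer to every skeleton node
#'
#' Nodes whose (ml, dv) position falls inside the footprint get a normalized
#' anteroposterior depth d = (z - anterior) / (posterior - anterior), with 0
#' on the anterior surface and 1 on the posterior surface, evaluated by
#' vertical projection onto the two surfaces. The plate is quartered into
#' layers 1-4 of equal width with half-open bins [0, .25), ..., [.75, 1];
#' d = 1 exactly maps to layer 4. Nodes with d < 0 are anterior of the
#' plate, d > 1 posterior of it; nodes outside the footprint get no depth.
#'
#' The tree should be resampled ([resample_max_spacing()]) first so node
#' counts act as a cable-length proxy.
#'
#' @param tree a [skeleton_tree()].
#' @param model a `layer_model`.
#' @return data frame with columns `id`, `in_footprint`, `depth`, `layer`
#'   (integer or NA) and `region` (factor: layer1..layer4, anterior,
#'   posterior, outside).
#' @export
assign_depth <- function(tree, model) {
  nd <- tree$nodes
  ev <- predict(model, nd)
  d <- ifelse(ev$in_footprint, (nd$z - ev$anterior) / ev$thickness, NA_real_)
  layer <- ifelse(!is.na(d) & d >= 0 & d <= 1,
                  pmin(4L, 1L + floor(4 * d)), NA_integer_)
  region <- rep("outside", nrow(nd))
  region[!is.na(d) & d < 0] <- "anterior"
  region[!is.na(d) & d > 1] <- "posterior"
  region[!is.na(layer)] <- paste0("layer", layer[!is.na(layer)])
  data.frame(
    id = nd$id, in_footprint = ev$in_footprint, depth = d,
    layer = as.integer(layer),
    region = factor(region, levels = c("layer1", "layer2", "layer3", "layer4",
                                       "anterior", "posterior", "outside"))
  )
}

#' Layer histogram of a depth assignment
#'
#' Fractions of in-footprint nodes (or of their weights) over the six bins
#' layer1..layer4, anterior-of-plate and posterior-of-plate. Fractions sum
#' to 1 over in-footprint nodes.
#'
#' @param assignment result of [assign_depth()].
#' @param weights optional per-node weights (e.g. half the summed incident
#'   cable); default: each node counts 1.
#' @return named numeric vector of 6 fractions, with attribute `n` (number
#'   of in-footprint nodes).
#' @export
layer_histogram <- function(assignment, weights = NULL) {
  keep <- assignment$in_footprint
  if (!any(keep)) {
    stop_("layer_histogram: no nodes inside the plate footprint",
          class = "lptc_empty_histogram_error")
  }
  w <- if (is.null(weights)) rep(1, nrow(assignment)) else weights
  bins <- c("layer1", "layer2", "layer3", "layer4", "anterior", "posterior")
  tot <- vapply(bins, function(b) sum(w[keep & assignment$region == b]),
                numeric(1))
  out <- tot / sum(tot)
  attr(out, "n") <- sum(keep)
  out
}

#' Boxplot statistics of normalized depth
#'
#' Depth values further than 50% anterior or posterior of the plate
#' (d < -0.5 or d > 1.5) are excluded, then Tukey five-number statistics are
#' computed: hinges by the midpoint rule, whiskers at the most extreme value
#' within 1.5 x IQR of the hinges, points beyond flagged as outliers.
#'
#' @param assignment result of [assign_depth()] (or a numeric vector of
#'   depths).
#' @return list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
depth_boxplot_stats <- function(assignment) {
  d <- if (is.numeric(assignment)) assignment else assignment$depth
  d <- d[!is.na(d) & d >= -0.5 & d <= 1.5]
  if (!length(d)) {
    stop_("depth_boxplot_stats: no depths in the inclusion window",
          class = "lptc_empty_histogram_error")
  }
  fn <- stats::fivenum(d)
  q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- d >= lo_fence & d <= hi_fence
  list(
    n = length(d), median = med, q1 = q1, q3 = q3,
    whisker_low = min(d[inside]), whisker_high = max(d[inside]),
    outliers = sort(d[!inside])
  )
}

#' Convert a slice index to depth from the lateral end
#'
#' Slices are cut at a constant thickness (25 nm) proceeding from lateral to
#' medial, so slice index times thickness is the mediolateral depth of a
#' slice.
#'
#' @param slice_index non-negative slice index (vectorized).
#' @param thickness_nm cutting thickness in nm (default 25).
#' @return depth in micrometres.
#' @examples
#' slice_to_depth(3960)  # 99 um
#' @export
slice_to_depth <- function(slice_index, thickness_nm = 25) {
  stopifnot(all(slice_index >= 0))
  slice_index * thickness_nm / 1e3
}
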