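#' Measure the shift between two overlapping tiles
#'
#' Searches a window of candidate displacements around the nominal offset and
#' scores each by the normalized cross-correlation (zero-mean, unit-variance;
#' robust to block-face brightness drift) of the overlapping pixels. The
#' returned shift is the argmax; `peak_quality` is the peak correlation
#' divided by the mean absolute correlation in a ring around the peak, a
#' sharpness score that is low when the correlation maximum is blurry or
#' spurious.
#'
#' Images are matrices indexed `[row, col]`; a shift `c(dx, dy)` means image
#' `b`'s origin sits `dx` columns right and `dy` rows down of image `a`'s
#' origin.
#'
#' @param img_a,img_b numeric matrices.
#' @param nominal integer shift `c(dx, dy)` expected from the grid geometry.
#' @param search_radius maximum deviation (px) from the nominal shift.
#' @param min_overlap minimum number of overlapping pixels for a candidate.
#' @return list of class `shift_measurement`: `shift`, `ncc_peak`,
#'   `peak_quality`, `weight` (1), `nominal`.
#' @export
measure_shift <- function(img_a, img_b, nominal, search_radius = 8L,
                          min_overlap = 64L) {
  nominal <- as.integer(round(nominal))
  cand <- expand.grid(dx = nominal[1] + (-search_radius):search_radius,
                      dy = nominal[2] + (-search_radius):search_radius)
  ncc <- rep(NA_real_, nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    sx <- cand$dx[ci]; sy <- cand$dy[ci]
    rows_a <- max(1L, 1L + sy):min(nrow(img_a), nrow(img_b) + sy)
    cols_a <- max(1L, 1L + sx):min(ncol(img_a), ncol(img_b) + sx)
    if (length(rows_a) < 1L || length(cols_a) < 1L ||
        rows_a[1] > rows_a[length(rows_a)] ||
        cols_a[1] > cols_a[length(cols_a)]) next
    a <- img_a[rows_a, cols_a]
    b <- img_b[rows_a - sy, cols_a - sx]
    if (length(a) < min_overlap) next
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ncc[ci] <- stats::cor(as.vector(a), as.vector(b))
  }
  if (all(is.na(ncc))) {
    stop_("measure_shift: no candidate shift yields an overlap of >= ",
          min_overlap, " px", class = "lptc_geometry_error")
  }
  best <- which.max(ncc)
  cheb <- base::pmax(abs(cand$dx - cand$dx[best]), abs(cand$dy - cand$dy[best]))
  ring <- which(cheb >= 2 & cheb <= 4 & !is.na(ncc))
  if (!length(ring)) ring <- which(cheb >= 1 & !is.na(ncc))
  quality <- if (length(ring)) {
    denom <- mean(abs(ncc[ring]))
    if (denom <= .Machine$double.eps) Inf else ncc[best] / denom
  } else Inf
  structure(list(
    shift = c(cand$dx[best], cand$dy[best]),
    ncc_peak = ncc[best], peak_quality = quality, weight = 1,
    nominal = nominal
  ), class = "shift_measurement")
}

#' Down-weight deviant or blurry shift measurements
#'
#' Multiplies each weight by a Huber-style factor
#' `min(1, deviation_tol / ||shift - expected||)`, rejects outright
#' (weight 0) measurements deviating more than `hard_reject` tolerances —
#' beyond a few tolerances a shift is a mismatch, not noise, and a linear
#' down-weight would still let it drag the solution — and zeroes the weight
#' when the correlation peak quality is below `quality_floor`. Weights stay
#' in `[0, 1]`.
#'
#' @param measurements data frame of measurements (see [solve_layout()] for
#'   the columns) with `dx`, `dy`, `ex`, `ey` (expected shift), `quality`,
#'   `weight`.
#' @param deviation_tol deviation (px) beyond which down-weighting starts.
#' @param quality_floor minimum acceptable peak quality; measurements below
#'   it get weight 0. See [calibrate_quality_floor()].
#' @param hard_reject deviations above `hard_reject * deviation_tol` get
#'   weight 0 (default 5).
#' @return the measurements with updated `weight`.
#' @export
reweight_shifts <- function(measurements, deviation_tol = 5,
                            quality_floor = 6, hard_reject = 5) {
  dev <- sqrt((measurements$dx - measurements$ex)^2 +
                (measurements$dy - measurements$ey)^2)
  fac <- base::pmin(1, deviation_tol / base::pmax(dev, .Machine$double.eps))
  fac[dev > hard_reject * deviation_tol] <- 0
  w <- measurements$weight * fac
  w[measurements$quality < quality_floor] <- 0
  measurements$weight <- base::pmin(1, base::pmax(0, w))
  measurements
}

#' Calibrate the peak-quality floor on pure-noise tile pairs
#'
#' Measures the peak quality of `n` pairs of independent noise images and
#' returns their 99th percentile: sharper peaks than essentially all chance
#' correlations.
#'
#' @param n number of noise pairs.
#' @param size image size in px.
#' @param nominal nominal shift used for the search window.
#' @param seed RNG seed.
#' @param search_radius as in [measure_shift()].
#' @return the calibrated quality floor (scalar).
#' @export
calibrate_quality_floor <- function(n = 100, size = c(64, 64),
                                    nominal = c(0, 0), seed = 1,
                                    search_radius = 8L) {
  q <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      a <- matrix(stats::rnorm(prod(size)), size[1], size[2])
      b <- matrix(stats::rnorm(prod(size)), size[1], size[2])
      measure_shift(a, b, nominal, search_radius)$peak_quality
    }, numeric(1))
  })
  as.numeric(stats::quantile(q, 0.99, type = 7))
}

#' Solve globally optimal tile positions from pairwise shifts
#'
#' Minimizes `sum_ij w_ij || (p_j - p_i) - shift_ij ||^2` over tile positions
#' `p`, decoupled per axis into two weighted sparse linear systems (exact for
#' a pure-translation model). The gauge is fixed by anchoring the first tile
#' at (0, 0). The solution is exact (zero residual) on any consistent
#' measurement set.
#'
#' @param measurements data frame with columns `a`, `b` (tile ids), `dx`,
#'   `dy` (measured shift of b relative to a) and optionally `weight`
#'   (default 1).
#' @return object of class `tile_layout`: `positions` (data frame `tile`,
#'   `x`, `y`), `gauge` (anchored tile id), `residuals` (per measurement).
#' @export
solve_layout <- function(measurements) {
  m <- as.data.frame(measurements)
  if (is.null(m$weight)) m$weight <- 1
  m <- m[m$weight > 0, , drop = FALSE]
  if (!nrow(m)) stop_("solve_layout: no measurements with positive weight",
                      class = "lptc_connectivity_error")
  tiles <- sort(unique(c(m$a, m$b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(m$a), to = as.character(m$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(tiles))
  )
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- table(comp$membership)
    stop_("solve_layout: measurement graph is disconnected (",
          comp$no, " components of sizes ",
          paste(sizes, collapse = ", "), ")",
          class = "lptc_connectivity_error")
  }
  n <- length(tiles)
  ia <- match(m$a, tiles)
  ib <- match(m$b, tiles)
  nm <- nrow(m)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(nm), 2), j = c(ia, ib),
    x = rep(c(-1, 1), each = nm), dims = c(nm, n)
  )
  A <- A[, -1, drop = FALSE]                    # anchor tile 1 at the origin
  sw <- sqrt(m$weight)
  Aw <- A * sw
  M <- Matrix::crossprod(Aw)
  solve_axis <- function(s) {
    rhs <- Matrix::crossprod(Aw, s * sw)
    as.numeric(Matrix::solve(M, rhs))
  }
  px <- c(0, solve_axis(m$dx))
  py <- c(0, solve_axis(m$dy))
  res <- data.frame(
    a = m$a, b = m$b,
    rx = (px[ib] - px[ia]) - m$dx,
    ry = (py[ib] - py[ia]) - m$dy,
    weight = m$weight
  )
  structure(list(
    positions = data.frame(tile = tiles, x = px, y = py),
    gauge = tiles[1], residuals = res
  ), class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  rms <- sqrt(mean(x$residuals$rx^2 + x$residuals$ry^2))
  cat(sprintf("<tile_layout: %d tiles anchored at '%s', residual RMS %.3g px>\n",
              nrow(x$positions), x$gauge, rms))
  invisible(x)
}

#' z-only fallback layout
#'
#' For stacks where lateral alignment is done manually, tiles keep their
#' nominal grid positions; only the slice ordering is recorded. No lateral
#' corrections are applied. Idempotent.
#'
#' @param nominal_positions data frame with columns `tile`, `x`, `y`.
#' @param slice_order optional slice indices (defaults to input order).
#' @return a `tile_layout` with `z_only = TRUE`.
#' @export
z_only_stack <- function(nominal_positions, slice_order = NULL) {
  pos <- as.data.frame(nominal_positions)[, c("tile", "x", "y")]
  structure(list(
    positions = pos, gauge = pos$tile[1],
    residuals = data.frame(a = character(0), b = character(0),
                           rx = numeric(0), ry = numeric(0),
                           weight = numeric(0)),
    slice_order = slice_order %||% seq_len(nrow(pos)),
    z_only = TRUE
  ), class = "tile_layout")
}

#' Align a rectangular grid of tiles
#'
#' Measures shifts for all horizontally and vertically adjacent tile pairs,
#' optionally reweights them against the nominal grid offsets, and solves
#' the global layout. One reweight/re-solve pass is the default; set
#' `reweight_iterations = 0` for unweighted least squares.
#'
#' @param tiles list of image matrices in row-major order (row 1: tiles
#'   1..cols).
#' @param rows,cols grid dimensions.
#' @param step nominal tile step `c(x, y)` in px (tile size minus overlap).
#' @param search_radius,deviation_tol,quality_floor see [measure_shift()] and
#'   [reweight_shifts()].
#' @param reweight_iterations number of reweight passes (default 1).
#' @return list: `layout` (a `tile_layout`), `measurements`.
#' @export
align_tile_grid <- function(tiles, rows, cols, step, search_radius = 8L,
                            deviation_tol = 5, quality_floor = 6,
                            reweight_iterations = 1L) {
  stopifnot(length(tiles) == rows * cols)
  idx <- function(r, c) (r - 1L) * cols + c
  meas <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) {       # right neighbor: nominal shift (+step_x, 0)
        s <- measure_shift(tiles[[idx(r, c)]], tiles[[idx(r, c + 1)]],
                           nominal = c(step[1], 0), search_radius)
        meas[[length(meas) + 1L]] <- data.frame(
          a = idx(r, c), b = idx(r, c + 1), dx = s$shift[1], dy = s$shift[2],
          ex = step[1], ey = 0, quality = s$peak_quality, weight = 1)
      }
      if (r < rows) {       # bottom neighbor: nominal shift (0, +step_y)
        s <- measure_shift(tiles[[idx(r, c)]], tiles[[idx(r + 1, c)]],
                           nominal = c(0, step[2]), search_radius)
        meas[[length(meas) + 1L]] <- data.frame(
          a = idx(r, c), b = idx(r + 1, c), dx = s$shift[1], dy = s$shift[2],
          ex = 0, ey = step[2], quality = s$peak_quality, weight = 1)
      }
    }
  }
  meas <- do.call(rbind, meas)
  for (it in seq_len(reweight_iterations)) {
    meas <- reweight_shifts(meas, deviation_tol, quality_floor)
  }
  list(layout = solve_layout(meas), measurements = meas)
}
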