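#' Label volumes
#'
#' A dense 3D voxel grid with one integer label per voxel: 0 is background,
#' k > 0 is process k. Voxel `(i, j, l)` has its center at
#' `origin + (c(i, j, l) - 0.5) * voxel_nm`. Labels are pairwise disjoint by
#' construction (contested voxels are background).
#'
#' @param arr integer 3D array of labels.
#' @param voxel_nm isotropic voxel edge length in nm.
#' @param origin_nm lower corner of voxel (1,1,1), nm.
#' @param names optional character vector naming labels 1..K.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(arr, voxel_nm, origin_nm = c(0, 0, 0), names = NULL) {
  stopifnot(length(dim(arr)) == 3L, voxel_nm > 0)
  if (any(arr < 0)) stop_("label_volume: negative labels",
                          class = "lptc_structure_error")
  structure(list(arr = arr, voxel_nm = voxel_nm, origin_nm = origin_nm,
                 label_names = names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- label_ids(x)
  cat(sprintf("<label_volume: %s voxels @ %g nm, %d labels>\n",
              paste(dim(x$arr), collapse = "x"), x$voxel_nm, length(labs)))
  invisible(x)
}

label_ids <- function(volume) {
  u <- sort(unique(as.integer(volume$arr)))
  u[u > 0]
}

#' Voxelize radius-annotated skeletons into a label volume
#'
#' Each edge is rasterized as a capsule sweep: a voxel center gets label k
#' when it lies within the linearly interpolated radius of the edge axis of
#' tree k. Voxels claimed by two or more different processes are left as
#' background, keeping labels disjoint. Only the requested depth window
#' along the mediolateral axis is rasterized.
#'
#' @param trees list of [skeleton_tree()]s with strictly positive radii
#'   (resample first; see [resample_max_spacing()]).
#' @param voxel_nm isotropic voxel size in nm (default 140).
#' @param roi_um depth window (min, max) in micrometres from the lateral end
#'   along `axis`; `NULL` for the full extent. Default c(86, 203), the
#'   axonal-tract stretch.
#' @param axis mediolateral axis index (default 1).
#' @param pad_voxels background margin added around the bounding box so that
#'   later dilation rounds do not clip at the array edge.
#' @param max_voxels resource guard on the array size (default 2e8).
#' @return a [label_volume()]; label k corresponds to `trees[[k]]`.
#' @export
voxelize <- function(trees, voxel_nm = 140, roi_um = c(86, 203), axis = 1L,
                     pad_voxels = 12L, max_voxels = 2e8) {
  if (inherits(trees, "skeleton_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  ax <- c("x", "y", "z")[axis]
  roi_nm <- if (is.null(roi_um)) c(-Inf, Inf) else roi_um * 1e3

  all_nodes <- do.call(rbind, lapply(trees, function(t) {
    nd <- t$nodes[, c("x", "y", "z", "radius")]
    if (any(is.na(nd$radius) | nd$radius <= 0)) {
      stop_("voxelize: tree '", t$name, "' has non-positive radii",
            class = "lptc_validation_error")
    }
    nd[nd[[ax]] >= roi_nm[1] & nd[[ax]] <= roi_nm[2], , drop = FALSE]
  }))
  if (!nrow(all_nodes)) {
    stop_("voxelize: no nodes inside the depth window",
          class = "lptc_validation_error")
  }
  rmax <- max(all_nodes$radius)
  lo <- c(min(all_nodes$x), min(all_nodes$y), min(all_nodes$z)) - rmax
  hi <- c(max(all_nodes$x), max(all_nodes$y), max(all_nodes$z)) + rmax
  lo[axis] <- max(lo[axis], roi_nm[1])
  hi[axis] <- min(hi[axis], roi_nm[2])
  origin <- lo - pad_voxels * voxel_nm
  dims <- as.integer(ceiling((hi - origin) / voxel_nm)) + pad_voxels
  if (prod(as.numeric(dims)) > max_voxels) {
    stop_(sprintf(
      "voxelize: %s grid (%.2g voxels) exceeds the budget of %.2g",
      paste(dims, collapse = "x"), prod(as.numeric(dims)), max_voxels),
      class = "lptc_resource_error")
  }
  arr <- array(0L, dims)
  conflict <- array(FALSE, dims)
  centers <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * voxel_nm)

  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    nd <- tr$nodes
    if (!nrow(tr$edges)) next
    i <- match(tr$edges$from, nd$id)
    j <- match(tr$edges$to, nd$id)
    for (e in seq_along(i)) {
      p1 <- c(nd$x[i[e]], nd$y[i[e]], nd$z[i[e]])
      p2 <- c(nd$x[j[e]], nd$y[j[e]], nd$z[j[e]])
      r1 <- nd$radius[i[e]]; r2 <- nd$radius[j[e]]
      # skip edges entirely outside the roi slab
      if (max(p1[axis], p2[axis]) < roi_nm[1] - max(r1, r2) ||
          min(p1[axis], p2[axis]) > roi_nm[2] + max(r1, r2)) next
      rpad <- max(r1, r2)
      elo <- pmin.int(p1, p2) - rpad
      ehi <- pmax.int(p1, p2) + rpad
      il <- pmax.int(1L, as.integer(floor((elo - origin) / voxel_nm)) + 1L)
      ih <- pmin.int(dims, as.integer(ceiling((ehi - origin) / voxel_nm)))
      if (any(il > ih)) next
      xs <- centers[[1]][il[1]:ih[1]]
      ys <- centers[[2]][il[2]:ih[2]]
      zs <- centers[[3]][il[3]:ih[3]]
      nx <- length(xs); ny <- length(ys); nz <- length(zs)
      cx <- rep(xs, times = ny * nz)
      cy <- rep(rep(ys, each = nx), times = nz)
      cz <- rep(zs, each = nx * ny)
      w <- p2 - p1
      ww <- sum(w^2)
      t <- if (ww == 0) rep(0, length(cx)) else
        ((cx - p1[1]) * w[1] + (cy - p1[2]) * w[2] + (cz - p1[3]) * w[3]) / ww
      t <- base::pmin(1, base::pmax(0, t))
      dx <- cx - (p1[1] + t * w[1])
      dy <- cy - (p1[2] + t * w[2])
      dz <- cz - (p1[3] + t * w[3])
      inside <- dx * dx + dy * dy + dz * dz <= (r1 + t * (r2 - r1))^2
      if (!any(inside)) next
      sub <- array(FALSE, c(nx, ny, nz))
      sub[inside] <- TRUE
      # map into the full array
      full_idx <- which(sub)
      ai <- arrayInd(full_idx, c(nx, ny, nz))
      lin <- (il[1] - 1L + ai[, 1]) +
        dims[1] * ((il[2] - 2L + ai[, 2]) + dims[2] * (il[3] - 2L + ai[, 3]))
      cur <- arr[lin]
      conflict[lin[cur != 0L & cur != k]] <- TRUE
      arr[lin[cur == 0L]] <- k
    }
  }
  arr[conflict] <- 0L
  # only the depth window itself is rasterized: clear voxels whose center
  # falls outside it (capsules of boundary nodes can spill past the window)
  if (is.finite(roi_nm[1]) || is.finite(roi_nm[2])) {
    ax_centers <- centers[[axis]]
    outside <- ax_centers < roi_nm[1] | ax_centers > roi_nm[2]
    if (any(outside)) {
      if (axis == 1L) arr[outside, , ] <- 0L
      else if (axis == 2L) arr[, outside, ] <- 0L
      else arr[, , outside] <- 0L
    }
  }
  label_volume(arr, voxel_nm, origin,
               names = vapply(trees, `[[`, character(1), "name"))
}

#' Morphological closing of every label
#'
#' Each label is closed independently against everything else as background:
#' dilated `rounds` times with the 3x3x3 cubic element, then eroded `rounds`
#' times with the same element. Closing fills gaps and tunnels smaller than
#' the element without net growth of convex solids, and is idempotent.
#' Disjointness is re-enforced afterwards: voxels claimed by two closed
#' labels become background.
#'
#' @param volume a [label_volume()].
#' @param rounds dilation (then erosion) repetitions, default 2.
#' @return a closed [label_volume()].
#' @export
close_labels <- function(volume, rounds = 2L) {
  arr <- volume$arr
  dims <- dim(arr)
  out <- array(0L, dims)
  claimed <- array(FALSE, dims)
  conflict <- array(FALSE, dims)
  for (k in label_ids(volume)) {
    mask <- arr == k
    bb <- bbox_of(mask, margin = rounds + 1L)
    sub <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                drop = FALSE]
    sub <- erode_bin(dilate_bin(sub, rounds), rounds)
    full <- array(FALSE, dims)
    full[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- sub
    conflict <- conflict | (full & claimed)
    out[full & !claimed] <- k
    claimed <- claimed | full
  }
  out[conflict] <- 0L
  label_volume(out, volume$voxel_nm, volume$origin_nm, volume$label_names)
}

#' Constrained (mutually exclusive) label dilation
#'
#' Runs `rounds` synchronous growth sweeps. In each sweep every label dilates
#' by the 3x3x3 element into background only; a background voxel reachable by
#' two or more different labels in the same sweep is contested and stays
#' background permanently; labels never overwrite labels. The synchronous
#' update with permanent ties makes the result independent of label
#' numbering. Per-label voxel counts are non-decreasing and labels stay
#' pairwise disjoint after every sweep.
#'
#' @param volume a [label_volume()] with disjoint labels.
#' @param rounds number of sweeps, default 7 (a growth reach of about 1 um
#'   at 140 nm voxels, the neighborhood within which two processes are
#'   considered to appose).
#' @return a grown [label_volume()]; the contested-voxel mask is attached as
#'   attribute `contested`.
#' @export
constrained_dilate <- function(volume, rounds = 7L) {
  arr <- volume$arr
  contested <- array(FALSE, dim(arr))
  for (s in seq_len(rounds)) {
    nmax <- max_filter3(arr, 0L)
    m <- arr * 1.0
    m[m == 0] <- Inf
    nmin <- min_filter3(m, Inf)
    claim <- arr == 0L & !contested & nmax > 0L
    tie <- claim & (nmin != nmax)
    take <- claim & (nmin == nmax)
    arr[take] <- nmax[take]
    contested[tie] <- TRUE
  }
  out <- label_volume(arr, volume$voxel_nm, volume$origin_nm,
                      volume$label_names)
  attr(out, "contested") <- contested
  out
}

#' Contact area of one process against all others
#'
#' Label `k` is dilated once with the 3x3x3 cubic element while all other
#' labels stay fixed; the overlap voxel count with each other label, divided
#' by the area divisor, is the apposed surface area in um^2. The default
#' divisor 51 is the reciprocal voxel face area of a 140 nm voxel
#' (1 / 0.14^2 = 51.02) rounded to an integer; set
#' `exact_face_area = TRUE` for the unrounded value.
#'
#' @param volume a [label_volume()] after [constrained_dilate()].
#' @param k label to dilate.
#' @param divisor voxels-per-um^2 conversion divisor; default 51 for 140 nm
#'   voxels, otherwise `(voxel_nm / 1000)^-2`.
#' @param exact_face_area use the exact reciprocal face area instead of the
#'   integer divisor.
#' @param dilate_rounds rounds of the final overlap dilation (default 1).
#'   When measuring at a finer voxel size than 140 nm, scale this up (and
#'   the divisor by the same factor) to probe the same physical shell
#'   thickness.
#' @return named numeric vector: contact area (um^2) against every other
#'   label.
#' @export
contact_area <- function(volume, k, divisor = NULL, exact_face_area = FALSE,
                         dilate_rounds = 1L) {
  labs <- label_ids(volume)
  if (!(k %in% labs)) {
    stop_("contact_area: unknown label ", k, class = "lptc_unknown_label_error")
  }
  if (is.null(divisor)) {
    divisor <- dilate_rounds * if (exact_face_area || volume$voxel_nm != 140) {
      (volume$voxel_nm / 1000)^-2
    } else 51
  }
  arr <- volume$arr
  mask <- arr == k
  bb <- bbox_of(mask, margin = as.integer(dilate_rounds))
  sub_mask <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                   drop = FALSE]
  sub_arr <- arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                 drop = FALSE]
  grown <- dilate_bin(sub_mask, as.integer(dilate_rounds))
  others <- setdiff(labs, k)
  counts <- vapply(others, function(m) sum(grown & sub_arr == m), numeric(1))
  stats::setNames(counts / divisor, as.character(others))
}

#' Pairwise axon-axon contact matrix
#'
#' Computes all directed contact areas ([contact_area()] for every label) and
#' symmetrizes them by the mean of the two directions. Pairs with zero area
#' are flagged for manual review.
#'
#' @inheritParams contact_area
#' @return object of class `contact_matrix`: list with `area` (symmetric
#'   matrix, um^2), `directed_area`, `zero_pairs` (data frame), `divisor`.
#' @export
contact_matrix <- function(volume, divisor = NULL, exact_face_area = FALSE,
                           dilate_rounds = 1L) {
  labs <- label_ids(volume)
  if (length(labs) < 2L) {
    stop_("contact_matrix: need at least 2 labels",
          class = "lptc_validation_error")
  }
  nms <- if (!is.null(volume$label_names)) volume$label_names[labs]
         else as.character(labs)
  K <- length(labs)
  D <- matrix(0, K, K, dimnames = list(nms, nms))
  for (a in seq_len(K)) {
    ca <- contact_area(volume, labs[a], divisor, exact_face_area,
                       dilate_rounds)
    D[a, match(names(ca), as.character(labs))] <- ca
  }
  A <- (D + t(D)) / 2
  diag(A) <- 0
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  zero <- pairs[A[pairs] == 0, , drop = FALSE]
  structure(list(
    area = A, directed_area = D,
    zero_pairs = data.frame(a = nms[zero[, 1]], b = nms[zero[, 2]]),
    labels = nms
  ), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<contact_matrix: %d processes, %d pairs, %d zero-contact>\n",
              length(x$labels), choose(length(x$labels), 2),
              nrow(x$zero_pairs)))
  print(round(x$area, digits))
  if (nrow(x$zero_pairs)) {
    cat("zero-contact pairs (verify by manual inspection):\n")
    print(x$zero_pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Full contact-analysis chain on skeletons
#'
#' Convenience wrapper: resample, voxelize the depth window, close labels,
#' grow by constrained dilation, and measure the pairwise contact matrix.
#'
#' @inheritParams voxelize
#' @param closing_rounds closing repetitions (default 2).
#' @param growth_rounds constrained-dilation sweeps (default 7).
#' @param resample_nm resampling spacing (default 400).
#' @param ... passed to [contact_matrix()].
#' @return a `contact_matrix`.
#' @export
measure_contacts <- function(trees, voxel_nm = 140, roi_um = c(86, 203),
                             closing_rounds = 2L, growth_rounds = 7L,
                             resample_nm = 400, axis = 1L,
                             max_voxels = 2e8, ...) {
  trees <- lapply(trees, resample_max_spacing, max_nm = resample_nm)
  vol <- voxelize(trees, voxel_nm = voxel_nm, roi_um = roi_um, axis = axis,
                  pad_voxels = as.integer(closing_rounds + growth_rounds + 3L),
                  max_voxels = max_voxels)
  vol <- close_labels(vol, rounds = closing_rounds)
  vol <- constrained_dilate(vol, rounds = growth_rounds)
  contact_matrix(vol, ...)
}
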