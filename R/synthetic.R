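#' Generate a synthetic lobula plate outline with known analytic surfaces
#'
#' Samples side-labeled points on two analytic surfaces: a gently curved
#' (sinusoidal) or flat slab of constant thickness. The closed-form surface
#' functions are returned alongside the point sample, so any depth computed
#' by the layer model can be checked against the exact value.
#'
#' @param extent_um (ml, dv) extent of the plate in micrometres.
#' @param thickness_um slab thickness (anterior to posterior), > 0.
#' @param curvature_um amplitude of the sinusoidal corrugation; 0 gives a
#'   flat slab.
#' @param n_points number of support points per side.
#' @param z0_um anteroposterior position of the anterior surface centre.
#' @param seed RNG seed; the outline is deterministic given the seed.
#' @return object of class `synthetic_plate`: `outline` (a
#'   [plate_outline()] with side labels), `anterior_fn(x, y)`,
#'   `posterior_fn(x, y)` (nm in, nm out), `depth_fn(x, y, z)`, `extent_nm`,
#'   `thickness_nm`.
#' @export
gen_plate_outline <- function(extent_um = c(100, 100), thickness_um = 20,
                              curvature_um = 5, n_points = 200,
                              z0_um = 30, seed = 1) {
  stopifnot(thickness_um > 0)
  ext <- extent_um * 1e3
  th <- thickness_um * 1e3
  A <- curvature_um * 1e3
  z0 <- z0_um * 1e3
  anterior_fn <- function(x, y) {
    z0 + A * sin(pi * x / ext[1]) * sin(pi * y / ext[2])
  }
  posterior_fn <- function(x, y) anterior_fn(x, y) + th
  g <- ceiling(sqrt(n_points))
  pts <- with_seed(seed, {
    gx <- seq(0, ext[1], length.out = g)
    gy <- seq(0, ext[2], length.out = g)
    base <- expand.grid(x = gx, y = gy)
    base <- base[sample.int(nrow(base), min(n_points, nrow(base))), ]
    jit <- function(v, extent) {
      step <- extent / (g - 1)
      base::pmin(extent, base::pmax(0, v + stats::runif(length(v), -0.3, 0.3) * step))
    }
    base$x <- jit(base$x, ext[1])
    base$y <- jit(base$y, ext[2])
    base
  })
  ant <- data.frame(x = pts$x, y = pts$y, z = anterior_fn(pts$x, pts$y),
                    side = "anterior")
  post <- data.frame(x = pts$x, y = pts$y, z = posterior_fn(pts$x, pts$y),
                     side = "posterior")
  structure(list(
    outline = plate_outline(rbind(ant, post)),
    anterior_fn = anterior_fn, posterior_fn = posterior_fn,
    depth_fn = function(x, y, z) (z - anterior_fn(x, y)) / th,
    extent_nm = ext, thickness_nm = th,
    params = list(extent_um = extent_um, thickness_um = thickness_um,
                  curvature_um = curvature_um, n_points = n_points,
                  z0_um = z0_um, seed = seed)
  ), class = "synthetic_plate")
}

# cable fractions of a tree over the 6 depth bins, from the analytic surfaces
analytic_cable_fractions <- function(tree, plate) {
  nd <- tree$nodes
  i <- match(tree$edges$from, nd$id)
  j <- match(tree$edges$to, nd$id)
  mx <- (nd$x[i] + nd$x[j]) / 2
  my <- (nd$y[i] + nd$y[j]) / 2
  mz <- (nd$z[i] + nd$z[j]) / 2
  len <- edge_lengths(tree)
  inside <- mx >= 0 & mx <= plate$extent_nm[1] &
    my >= 0 & my <= plate$extent_nm[2]
  d <- plate$depth_fn(mx, my, mz)
  bin <- ifelse(d < 0, "anterior",
                ifelse(d > 1, "posterior",
                       paste0("layer", base::pmin(4, 1 + floor(4 * d)))))
  bins <- c("layer1", "layer2", "layer3", "layer4", "anterior", "posterior")
  tot <- vapply(bins, function(b) sum(len[inside & bin == b]), numeric(1))
  tot / sum(tot)
}

#' Generate a synthetic tangential cell with prescribed layer occupancy
#'
#' Grows a random branching dendritic tree inside a synthetic plate whose
#' cable is placed, layer by layer, to match the target per-layer fractions:
#' for each layer a branched random walk is grown at depths confined to that
#' layer's band until its cable quota is met; the per-layer subtrees are then
#' connected, and an axon is appended running medially out of the plate,
#' ending in a soma-flagged stub. The realized per-layer cable fractions
#' (measured analytically against the generating surfaces) are returned as
#' ground truth.
#'
#' @param plate a `synthetic_plate` from [gen_plate_outline()].
#' @param fractions length-4 numeric, target cable fractions for layers 1-4;
#'   must be non-negative and sum to 1.
#' @param total_cable_um total dendritic cable to grow (default 5000 um =
#'   5 mm, a large-tangential-cell scale).
#' @param step_um dendrite step length (default 2).
#' @param branch_prob per-step branching probability (default 0.08).
#' @param radius_um mean dendrite radius (default 0.4).
#' @param margin_frac fraction of the plate extent kept clear at the border
#'   so the dendrite stays inside the outline's support hull.
#' @param seed RNG seed.
#' @param name cell name.
#' @return list: `tree` (a [skeleton_tree()]), `realized_fractions` (named,
#'   6 bins), `target_fractions`, `cable_um`.
#' @export
gen_tangential_cell <- function(plate, fractions, total_cable_um = 5000,
                                step_um = 2, branch_prob = 0.08,
                                radius_um = 0.4, margin_frac = 0.12,
                                seed = 1, name = "synthetic_cell") {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_("gen_tangential_cell: fractions must be 4 non-negative numbers ",
          "summing to 1", class = "lptc_spec_error")
  }
  ext <- plate$extent_nm
  th <- plate$thickness_nm
  step <- step_um * 1e3
  lo_xy <- margin_frac * ext
  hi_xy <- (1 - margin_frac) * ext
  r_nm <- radius_um * 1e3

  res <- with_seed(seed, {
    nodes <- list(); edges <- list()
    next_id <- 1L
    add_node <- function(x, y, d_or_z, radius, comment = NA_character_,
                         analytic_depth = TRUE) {
      z <- if (analytic_depth) {
        plate$anterior_fn(x, y) + d_or_z * th
      } else d_or_z
      id <- next_id
      next_id <<- next_id + 1L
      nodes[[id]] <<- data.frame(id = id, x = x, y = y, z = z,
                                 radius = radius, comment = comment)
      id
    }
    add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- data.frame(from = a, to = b)
    get_node <- function(id) nodes[[id]]

    subtree_entry <- integer(0)   # one node id per grown layer subtree
    for (l in 1:4) {
      quota <- fractions[l] * total_cable_um * 1e3
      if (quota <= 0) next
      band <- c((l - 1) / 4 + 0.03, l / 4 - 0.03)
      x0 <- stats::runif(1, lo_xy[1], hi_xy[1])
      y0 <- stats::runif(1, lo_xy[2], hi_xy[2])
      d0 <- stats::runif(1, band[1], band[2])
      root <- add_node(x0, y0, d0, r_nm * stats::runif(1, 0.8, 1.2))
      subtree_entry <- c(subtree_entry, root)
      # active tips: id, heading, depth
      tips <- list(list(id = root, heading = stats::runif(1, 0, 2 * pi),
                        d = d0))
      grown <- 0
      while (grown < quota && length(tips)) {
        ti <- sample.int(length(tips), 1)
        tip <- tips[[ti]]
        nd <- get_node(tip$id)
        heading <- tip$heading + stats::rnorm(1, 0, 0.45)
        nx <- nd$x + step * cos(heading)
        ny <- nd$y + step * sin(heading)
        if (nx < lo_xy[1] || nx > hi_xy[1]) {
          heading <- pi - heading
          nx <- nd$x + step * cos(heading)
        }
        if (ny < lo_xy[2] || ny > hi_xy[2]) {
          heading <- -heading
          ny <- nd$y + step * sin(heading)
        }
        nx <- base::pmin(hi_xy[1], base::pmax(lo_xy[1], nx))
        ny <- base::pmin(hi_xy[2], base::pmax(lo_xy[2], ny))
        d_new <- base::pmin(band[2], base::pmax(band[1],
                   tip$d + stats::rnorm(1, 0, 0.015)))
        nid <- add_node(nx, ny, d_new, r_nm * stats::runif(1, 0.8, 1.2))
        add_edge(tip$id, nid)
        new_nd <- get_node(nid)
        grown <- grown + vnorm(c(new_nd$x - nd$x, new_nd$y - nd$y,
                                 new_nd$z - nd$z))
        tips[[ti]] <- list(id = nid, heading = heading, d = d_new)
        if (stats::runif(1) < branch_prob) {
          tips[[length(tips) + 1L]] <- list(
            id = nid, heading = stats::runif(1, 0, 2 * pi), d = d_new)
        }
      }
    }
    # connect consecutive layer subtrees
    if (length(subtree_entry) > 1L) {
      for (k in 2:length(subtree_entry)) {
        add_edge(subtree_entry[k - 1L], subtree_entry[k])
      }
    }
    # axon: run medially (increasing ml) out of the plate, then a soma stub
    start <- get_node(subtree_entry[length(subtree_entry)])
    ax_x <- seq(start$x, ext[1] + 15e3, by = step)
    prev <- subtree_entry[length(subtree_entry)]
    for (xx in ax_x[-1]) {
      nid <- add_node(xx, start$y, start$z, 1.2 * r_nm,
                      analytic_depth = FALSE)
      add_edge(prev, nid)
      prev <- nid
    }
    for (s in 1:3) {
      nid <- add_node(ext[1] + 15e3 + s * 1e3, start$y, start$z, 2e3,
                      comment = "soma", analytic_depth = FALSE)
      add_edge(prev, nid)
      prev <- nid
    }
    list(nodes = do.call(rbind, nodes), edges = do.call(rbind, edges))
  })
  tree <- skeleton_tree(res$nodes, res$edges, name = name)
  realized <- analytic_cable_fractions(tree, plate)
  list(tree = tree,
       realized_fractions = realized,
       target_fractions = stats::setNames(fractions, paste0("layer", 1:4)),
       cable_um = cable_length(tree) / 1e3)
}

#' Generate a bundle of intertwined tubular axons with known contacts
#'
#' Emulates the medially running axonal tract: `n_tubes` tubes run along the
#' mediolateral axis, resting on a ring in the (dv, ap) cross-section. The
#' tract length is divided into one slot per tube pair (except `omit_pair`);
#' in its slot the two tubes of the pair dip to the bundle centre and into
#' wall contact (axis distance `contact_overlap * (r_a + r_b)`), then return
#' home. The omitted pair is placed on opposite sides of the ring and is
#' never scheduled, so its wall-to-wall gap stays larger than the contact
#' method's growth reach: it is the constructed zero-contact pair.
#'
#' The returned truth table reports each pair's minimal wall-to-wall gap
#' (computed from the generating axis curves on a fine parameter grid) and
#' its classification: `touching` (gap <= 0) or `expected_zero`
#' (gap > `clearance_um`).
#'
#' @param n_tubes number of tubes (default 9).
#' @param omit_pair the pair left without a contact slot (default c(1, 6),
#'   which sits 160 degrees apart on the ring).
#' @param ring_radius_um home ring radius (default 7.5).
#' @param radius_um_range tube radius range; radii are drawn uniformly
#'   (default 1.0-1.5 um, large-tangential-cell axon calibers).
#' @param slot_len_um tract length allotted to each contact slot.
#' @param step_um spacing of skeleton nodes along the tubes.
#' @param contact_overlap axis distance at slot centre as a fraction of the
#'   radius sum; < 1 means walls overlap slightly (robust contact).
#' @param clearance_um gap above which a pair is expected to measure zero
#'   contact; default 2.6 um, just above the default growth reach
#'   (7 + 7 + 1 voxels of 140 nm ~ 2.1 um).
#' @param x0_um mediolateral position where the bundle starts.
#' @param seed RNG seed (tube radii).
#' @return list: `trees`, `truth` (data frame `a`, `b`, `min_gap_um`,
#'   `touching`, `expected_zero`), `length_um`, `params`.
#' @export
gen_axon_bundle <- function(n_tubes = 9, omit_pair = c(1, 6),
                            ring_radius_um = 7.5,
                            radius_um_range = c(1.0, 1.5),
                            slot_len_um = 2.4, step_um = 0.4,
                            contact_overlap = 0.9, clearance_um = 2.6,
                            x0_um = 0, seed = 1) {
  stopifnot(n_tubes >= 2)
  pairs <- t(utils::combn(n_tubes, 2))
  if (!is.null(omit_pair)) {
    o1 <- min(omit_pair); o2 <- max(omit_pair)
    drop <- pairs[, 1] == o1 & pairs[, 2] == o2
    slots <- pairs[!drop, , drop = FALSE]
    # Tubes from slots close in tract coordinate all pass near the bundle
    # centre, so they come within the contact method's growth reach of each
    # other even without a scheduled meeting. Schedule all slots involving
    # one omitted-pair tube first and the other's last, with at least 3
    # neutral/rest slots between the blocks, so the omitted pair stays
    # clear of the reach everywhere along the tract.
    in1 <- slots[, 1] == o1 | slots[, 2] == o1
    in2 <- slots[, 1] == o2 | slots[, 2] == o2
    neutral <- which(!in1 & !in2)
    n_rest <- max(0L, 3L - length(neutral))
    order_idx <- c(which(in1), neutral, which(in2))
    slots <- slots[order_idx, , drop = FALSE]
    if (n_rest > 0L) {
      insert_at <- sum(in1) + length(neutral)
      slots <- rbind(slots[seq_len(insert_at), , drop = FALSE],
                     matrix(NA_integer_, n_rest, 2),
                     slots[-seq_len(insert_at), , drop = FALSE])
    }
  } else {
    slots <- pairs
  }
  R <- ring_radius_um * 1e3
  slot <- slot_len_um * 1e3
  margin <- slot / 2
  len <- nrow(slots) * slot + 2 * margin
  x0 <- x0_um * 1e3
  radii <- with_seed(seed, stats::runif(n_tubes, radius_um_range[1],
                                        radius_um_range[2]) * 1e3)
  theta <- 2 * pi * (seq_len(n_tubes) - 1) / n_tubes
  home <- cbind(R * cos(theta), R * sin(theta))

  # (dv, ap) position of tube i at tract coordinate x (vectorized over x)
  pos_fn <- function(i, x) {
    py <- rep(home[i, 1], length(x))
    pz <- rep(home[i, 2], length(x))
    for (s in seq_len(nrow(slots))) {
      if (is.na(slots[s, 1]) || !(i %in% slots[s, ])) next
      jj <- slots[s, ][slots[s, ] != i]
      s0 <- margin + (s - 1) * slot
      inb <- x >= s0 & x <= s0 + slot
      if (!any(inb)) next
      b <- 0.5 * (1 - cos(2 * pi * (x[inb] - s0) / slot))
      e <- home[i, ] - home[jj, ]
      e <- e / vnorm(e)
      u <- contact_overlap * (radii[i] + radii[jj])
      target <- e * u / 2
      py[inb] <- home[i, 1] + b * (target[1] - home[i, 1])
      pz[inb] <- home[i, 2] + b * (target[2] - home[i, 2])
    }
    cbind(py, pz)
  }

  xs <- seq(0, len, by = step_um * 1e3)
  trees <- lapply(seq_len(n_tubes), function(i) {
    p <- pos_fn(i, xs)
    skeleton_tree(
      data.frame(id = seq_along(xs), x = x0 + xs, y = p[, 1], z = p[, 2],
                 radius = radii[i]),
      data.frame(from = seq_len(length(xs) - 1), to = 2:length(xs)),
      name = sprintf("tube%02d", i)
    )
  })

  xf <- seq(0, len, by = 50)          # fine grid for the gap oracle
  truth <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    pa <- pos_fn(a, xf); pb <- pos_fn(b, xf)
    gap <- min(sqrt(rowSums((pa - pb)^2))) - radii[a] - radii[b]
    data.frame(a = a, b = b, min_gap_um = gap / 1e3,
               touching = gap <= 0,
               expected_zero = gap / 1e3 > clearance_um)
  }))
  list(trees = trees, truth = truth, length_um = len / 1e3,
       params = list(n_tubes = n_tubes, omit_pair = omit_pair,
                     ring_radius_um = ring_radius_um, radii_um = radii / 1e3,
                     slot_len_um = slot_len_um, seed = seed,
                     clearance_um = clearance_um, x0_um = x0_um))
}

# separable box blur, used to make band-limited tile textures
box_blur <- function(m, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(t(m), 2, function(row) stats::filter(row, k, circular = TRUE)))
}

#' Generate a grid of overlapping noisy image tiles with known offsets
#'
#' Crops one band-limited textured mother image into an overlapping grid of
#' tiles at jittered true positions (integer pixel jitter), then adds
#' independent intensity noise per tile. The true positions are returned as
#' alignment ground truth.
#'
#' @param rows,cols grid size.
#' @param tile_size tile (rows, cols) in px.
#' @param overlap_px nominal overlap between adjacent tiles; must exceed the
#'   correlation search radius.
#' @param jitter_px standard deviation of the true-position jitter (rounded
#'   to integer pixels).
#' @param intensity_noise per-tile noise standard deviation relative to the
#'   texture standard deviation.
#' @param blur_radius texture correlation length control.
#' @param seed RNG seed.
#' @return list: `tiles` (row-major list of matrices), `truth` (data frame
#'   `tile`, `row`, `col`, `x`, `y` top-left positions), `nominal`, `step`.
#' @export
gen_tile_grid <- function(rows = 4, cols = 4, tile_size = c(128, 128),
                          overlap_px = 32, jitter_px = 2,
                          intensity_noise = 0.1, blur_radius = 1, seed = 1) {
  step <- c(tile_size[2] - overlap_px, tile_size[1] - overlap_px)  # (x, y)
  with_seed(seed, {
    margin <- max(16L, 6L * ceiling(jitter_px) + 4L)
    H <- (rows - 1) * step[2] + tile_size[1] + 2 * margin
    W <- (cols - 1) * step[1] + tile_size[2] + 2 * margin
    # short correlation length: keeps the cross-correlation peak sharp, as
    # in fine-grained block-face texture
    mother <- box_blur(matrix(stats::rnorm(H * W), H, W), blur_radius)
    sdm <- stats::sd(mother)
    tiles <- vector("list", rows * cols)
    truth <- nominal <- data.frame(tile = integer(0), row = integer(0),
                                   col = integer(0), x = integer(0),
                                   y = integer(0))
    for (r in seq_len(rows)) {
      for (c in seq_len(cols)) {
        i <- (r - 1L) * cols + c
        nx <- margin + (c - 1L) * step[1]
        ny <- margin + (r - 1L) * step[2]
        jx <- as.integer(round(stats::rnorm(1, 0, jitter_px)))
        jy <- as.integer(round(stats::rnorm(1, 0, jitter_px)))
        tx <- nx + jx; ty <- ny + jy
        tiles[[i]] <- mother[ty + seq_len(tile_size[1]),
                             tx + seq_len(tile_size[2])] +
          stats::rnorm(prod(tile_size), 0, intensity_noise * sdm)
        truth <- rbind(truth, data.frame(tile = i, row = r, col = c,
                                         x = tx, y = ty))
        nominal <- rbind(nominal, data.frame(tile = i, row = r, col = c,
                                             x = nx, y = ny))
      }
    }
    list(tiles = tiles, truth = truth, nominal = nominal, step = step,
         params = list(rows = rows, cols = cols, tile_size = tile_size,
                       overlap_px = overlap_px, jitter_px = jitter_px,
                       intensity_noise = intensity_noise, seed = seed))
  })
}
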