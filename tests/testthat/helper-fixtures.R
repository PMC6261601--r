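# fixture builders used across test files

# straight path along +x with constant radius
path_tree <- function(n = 5, spacing = 1000, radius = 200, y = 0, z = 0,
                      name = "path") {
  skeleton_tree(
    data.frame(id = seq_len(n), x = (seq_len(n) - 1) * spacing, y = y, z = z,
               radius = radius),
    if (n > 1) data.frame(from = seq_len(n - 1), to = 2:n),
    name = name
  )
}

# Y-shaped tree: center node 1, three arms
y_tree <- function(arm = 1000, radius = 200) {
  skeleton_tree(
    data.frame(id = 1:4,
               x = c(0, arm, -arm, 0), y = c(0, 0, 0, arm), z = 0,
               radius = radius),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4))
  )
}

# small random tree with gentle bends: a meandering main path plus a couple
# of short branches, radii small relative to segment lengths so the frustum
# model is geometrically clean
random_gentle_tree <- function(seed, n_steps = 20, step = 1200,
                               radius_range = c(80, 150),
                               branch_every = 9) {
  set.seed(seed)
  local({
    heading <- stats::runif(1, 0, 2 * pi)
    pitch <- stats::runif(1, -0.3, 0.3)
    pos <- c(0, 0, 0)
    nodes <- list(data.frame(id = 1L, x = 0, y = 0, z = 0,
                             radius = stats::runif(1, radius_range[1],
                                                   radius_range[2])))
    edges <- list()
    id <- 1L
    tip <- 1L
    for (s in seq_len(n_steps)) {
      heading <- heading + stats::rnorm(1, 0, 0.25)   # <~15 deg bends
      pitch <- pitch + stats::rnorm(1, 0, 0.1)
      dirv <- c(cos(heading) * cos(pitch), sin(heading) * cos(pitch),
                sin(pitch))
      pos <- pos + step * dirv
      id <- id + 1L
      nodes[[id]] <- data.frame(id = id, x = pos[1], y = pos[2], z = pos[3],
                                radius = stats::runif(1, radius_range[1],
                                                      radius_range[2]))
      edges[[length(edges) + 1L]] <- data.frame(from = tip, to = id)
      if (s %% branch_every == 0L) {
        # daughter branchlets are thinner than the trunk, as in real
        # dendrites; this also keeps the (uncorrected) frustum overlap at
        # the branch point small relative to total volume
        bdir <- c(-dirv[2], dirv[1], 0.2)
        bdir <- bdir / sqrt(sum(bdir^2))
        bpos <- pos + 0.6 * step * bdir
        id <- id + 1L
        nodes[[id]] <- data.frame(id = id, x = bpos[1], y = bpos[2],
                                  z = bpos[3],
                                  radius = 0.55 * stats::runif(1, radius_range[1],
                                                               radius_range[2]))
        edges[[length(edges) + 1L]] <- data.frame(from = id - 1L, to = id)
      }
      tip <- if (s %% branch_every == 0L) id - 1L else id
    }
    skeleton_tree(do.call(rbind, nodes), do.call(rbind, edges),
                  name = paste0("rnd", seed))
  })
}

# rigid motion: rotation about z by angle + translation
apply_rigid <- function(tree, angle = 0.7, shift = c(1e4, -2e4, 3e3)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% R
  tree$nodes$x <- xyz[, 1] + shift[1]
  tree$nodes$y <- xyz[, 2] + shift[2]
  tree$nodes$z <- xyz[, 3] + shift[3]
  tree
}

# parallel tube pair along x, given axis gap, for contact tests
tube_pair <- function(length_um = 20, radius_um = 0.7, axis_gap_um = 1.5) {
  mk <- function(y, name) skeleton_tree(
    data.frame(id = 1:2, x = c(0, length_um * 1e3), y = y, z = 0,
               radius = radius_um * 1e3),
    data.frame(from = 1, to = 2), name = name)
  list(mk(0, "tubeA"), mk(axis_gap_um * 1e3, "tubeB"))
}
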