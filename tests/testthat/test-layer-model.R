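# two parallel planes as a minimal labeled outline
flat_outline <- function(z_a = 0, z_p = 20e3, n_side = 5, extent = 100e3) {
  g <- expand.grid(x = seq(0, extent, length.out = n_side),
                   y = seq(0, extent, length.out = n_side))
  plate_outline(rbind(
    data.frame(x = g$x, y = g$y, z = z_a, side = "anterior"),
    data.frame(x = g$x, y = g$y, z = z_p, side = "posterior")
  ))
}

test_that("split_outline honors labels and splits unlabeled slabs", {
  ol <- flat_outline()
  s <- split_outline(ol)
  expect_equal(nrow(s$anterior), 25)
  expect_true(all(s$anterior$z == 0))
  expect_true(all(s$posterior$z == 20e3))

  # unlabeled: geometric split by the quadratic mid-surface
  ol2 <- plate_outline(ol$points[, c("x", "y", "z")])
  s2 <- split_outline(ol2)
  expect_equal(sort(unique(s2$anterior$z)), 0)
  expect_equal(sort(unique(s2$posterior$z)), 20e3)

  # labels win regardless of geometry: flip half the labels
  pts <- ol$points
  pts$side <- rev(pts$side)
  s3 <- split_outline(plate_outline(pts))
  expect_true(all(s3$anterior$z == 20e3))

  # coplanar unlabeled points cannot define a slab
  flat <- plate_outline(data.frame(x = runif(20) * 1e5, y = runif(20) * 1e5,
                                   z = 5e3))
  expect_error(split_outline(flat), class = "lptc_degenerate_outline_error")
  expect_error(split_outline(plate_outline(data.frame(x = 1:3, y = 1, z = 1))),
               class = "lptc_degenerate_outline_error")
})

test_that("layer model reproduces planes exactly (linear precision)", {
  s <- split_outline(flat_outline())
  m <- build_layer_model(s$anterior, s$posterior)
  q <- data.frame(x = c(10e3, 50e3, 90e3), y = c(10e3, 42e3, 77e3))
  ev <- predict(m, q)
  expect_true(all(ev$in_footprint))
  expect_equal(ev$anterior, rep(0, 3), tolerance = 1e-9)
  expect_equal(ev$thickness, rep(20e3, 3), tolerance = 1e-9)

  # tilted anterior plane z = 0.1 x
  g <- expand.grid(x = seq(0, 1e5, length.out = 5),
                   y = seq(0, 1e5, length.out = 5))
  tilted <- data.frame(x = g$x, y = g$y, z = 0.1 * g$x)
  post <- data.frame(x = g$x, y = g$y, z = 0.1 * g$x + 30e3)
  m2 <- build_layer_model(tilted, post)
  ev2 <- predict(m2, q)
  expect_equal(ev2$anterior, 0.1 * q$x, tolerance = 1e-6)
  expect_equal(ev2$thickness, rep(30e3, 3), tolerance = 1e-6)
})

test_that("crossing surfaces and degenerate supports are rejected", {
  g <- expand.grid(x = seq(0, 1e5, length.out = 4),
                   y = seq(0, 1e5, length.out = 4))
  a <- data.frame(x = g$x, y = g$y, z = 0)
  # posterior dips below anterior in one corner
  p <- data.frame(x = g$x, y = g$y,
                  z = ifelse(g$x < 2e4 & g$y < 2e4, -5e3, 10e3))
  expect_error(build_layer_model(a, p), class = "lptc_model_error")
  # collinear support
  line <- data.frame(x = 1:5 * 1e3, y = 1:5 * 1e3, z = 0)
  expect_error(build_layer_model(line, p), class = "lptc_model_error")
})

test_that("interpolated thickness tracks a curved analytic slab within 5%", {
  pl <- gen_plate_outline(curvature_um = 5, thickness_um = 20,
                          n_points = 200, seed = 4)
  s <- split_outline(pl$outline)
  m <- build_layer_model(s$anterior, s$posterior)
  set.seed(1)
  q <- data.frame(x = runif(300, 0.1, 0.9) * pl$extent_nm[1],
                  y = runif(300, 0.1, 0.9) * pl$extent_nm[2])
  ev <- predict(m, q)
  expect_true(all(ev$in_footprint))
  expect_lt(max(abs(ev$thickness - pl$thickness_nm) / pl$thickness_nm), 0.05)
  # surface positions themselves track the analytic anterior surface
  expect_lt(max(abs(ev$anterior - pl$anterior_fn(q$x, q$y))) /
              pl$thickness_nm, 0.05)
})

test_that("assign_depth matches the closed form on a flat slab", {
  s <- split_outline(flat_outline(z_a = 0, z_p = 20e3))
  m <- build_layer_model(s$anterior, s$posterior)
  nodes <- data.frame(
    id = 1:6,
    x = c(5e4, 5e4, 5e4, 5e4, 5e4, 150e3),  # last one outside footprint
    y = 5e4,
    z = c(2.5e3, 5e3, 19.99e3, -3e3, 21e3, 1e3),
    radius = 100
  )
  tr <- skeleton_tree(nodes)
  a <- assign_depth(tr, m)
  expect_equal(a$depth[1], 0.125)
  expect_equal(a$layer[1], 1L)
  expect_equal(a$depth[2], 0.25)
  expect_equal(a$layer[2], 2L)           # half-open bins: d = 0.25 -> layer 2
  expect_equal(a$layer[3], 4L)
  expect_equal(as.character(a$region[4]), "anterior")
  expect_equal(as.character(a$region[5]), "posterior")
  expect_false(a$in_footprint[6])
  expect_true(is.na(a$depth[6]))
  # d exactly 1 maps to layer 4
  tr2 <- skeleton_tree(data.frame(id = 1, x = 5e4, y = 5e4, z = 20e3,
                                  radius = 1))
  expect_equal(assign_depth(tr2, m)$layer, 4L)
})

test_that("depth is invariant under a rigid translation of slab + skeleton", {
  shift <- c(13e3, -7e3, 11e3)
  s <- split_outline(flat_outline())
  m1 <- build_layer_model(s$anterior, s$posterior)
  move <- function(df) data.frame(x = df$x + shift[1], y = df$y + shift[2],
                                  z = df$z + shift[3])
  m2 <- build_layer_model(move(s$anterior), move(s$posterior))
  tr <- skeleton_tree(data.frame(id = 1:3, x = 4e4, y = 4e4,
                                 z = c(3e3, 9e3, 17e3), radius = 1))
  tr2 <- tr
  tr2$nodes$x <- tr$nodes$x + shift[1]
  tr2$nodes$y <- tr$nodes$y + shift[2]
  tr2$nodes$z <- tr$nodes$z + shift[3]
  expect_equal(assign_depth(tr2, m2)$depth, assign_depth(tr, m1)$depth,
               tolerance = 1e-9)
})

test_that("layer_histogram normalizes, is permutation invariant, errors empty", {
  s <- split_outline(flat_outline())
  m <- build_layer_model(s$anterior, s$posterior)
  set.seed(7)
  n <- 500
  tr <- skeleton_tree(data.frame(id = 1:n, x = runif(n, 1e4, 9e4),
                                 y = runif(n, 1e4, 9e4),
                                 z = runif(n, -5e3, 25e3), radius = 1))
  a <- assign_depth(tr, m)
  h <- layer_histogram(a)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  perm <- a[sample(nrow(a)), ]
  expect_equal(layer_histogram(perm), h, tolerance = 1e-12)
  # all nodes at d = 0.9: all mass in layer 4
  tr4 <- skeleton_tree(data.frame(id = 1:10, x = 5e4, y = 5e4, z = 18e3,
                                  radius = 1))
  h4 <- layer_histogram(assign_depth(tr4, m))
  expect_equal(unname(h4["layer4"]), 1)
  # no in-footprint nodes
  out <- skeleton_tree(data.frame(id = 1, x = 5e6, y = 5e6, z = 0,
                                  radius = 1))
  expect_error(layer_histogram(assign_depth(out, m)),
               class = "lptc_empty_histogram_error")
})

test_that("boxplot stats use Tukey hinges and the inclusion window", {
  st <- depth_boxplot_stats(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(st$median, 0.3)
  expect_equal(st$q1, 0.2)
  expect_equal(st$q3, 0.4)
  expect_length(st$outliers, 0)
  # d = 1.7 excluded before statistics
  st2 <- depth_boxplot_stats(c(0.1, 0.2, 0.3, 0.4, 0.5, 1.7))
  expect_equal(st2$n, 5)
  expect_equal(st2$median, 0.3)
  # uniform depths: median near 0.5
  set.seed(42)
  st3 <- depth_boxplot_stats(runif(1e4))
  expect_equal(st3$median, 0.5, tolerance = 0.02)
  # outliers flagged beyond 1.5 IQR
  st4 <- depth_boxplot_stats(c(rep(c(0.4, 0.5, 0.6), 10), 1.45))
  expect_equal(st4$outliers, 1.45)
  expect_lte(st4$whisker_high, 0.9)
})

test_that("slice index converts to depth from the lateral end", {
  expect_equal(slice_to_depth(3960), 99)
  expect_equal(slice_to_depth(6120), 153)
  expect_equal(slice_to_depth(0), 0)
  # the printed depths for all five start-point slices round to <= 1 um away
  printed <- c(`3664` = 92, `3960` = 99, `4416` = 111, `6120` = 153,
               `7312` = 183)
  computed <- slice_to_depth(as.integer(names(printed)))
  expect_true(all(abs(computed - printed) <= 1))
})
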