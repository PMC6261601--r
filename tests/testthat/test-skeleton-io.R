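test_that("read_nml converts voxel coordinates to nm with the file scale", {
  nml <- c(
    '<?xml version="1.0"?>',
    '<things>',
    '  <parameters><scale x="11" y="11" z="25"/></parameters>',
    '  <thing id="1" name="cell">',
    '    <nodes>',
    '      <node id="1" radius="2" x="0" y="0" z="0"/>',
    '      <node id="2" radius="2" x="10" y="0" z="0"/>',
    '    </nodes>',
    '    <edges><edge source="1" target="2"/></edges>',
    '  </thing>',
    '</things>'
  )
  f <- withr::local_tempfile(fileext = ".nml")
  writeLines(nml, f)
  ann <- read_nml(f)
  expect_equal(ann$scale, c(11, 11, 25))
  tr <- ann$trees[[1]]
  expect_equal(tr$nodes$x, c(0, 110))
  expect_equal(tr$nodes$y, c(0, 0))
  expect_equal(tr$nodes$radius, c(22, 22))   # 2 voxels * 11 nm
  expect_equal(nrow(tr$edges), 1L)
})

test_that("NML round-trip preserves trees, positions, radii and comments", {
  tr <- skeleton_tree(
    data.frame(id = c(3L, 7L, 12L),
               x = c(0, 123.456, 5000), y = c(10, 20, 30),
               z = c(0, 250, 12345.678),
               radius = c(50, 110, 330),
               comment = c(NA, "soma", NA)),
    data.frame(from = c(3, 7), to = c(7, 12)), name = "rt"
  )
  ann <- skeleton_annotation(list(tr, path_tree(3)), scale = c(11, 11, 25))
  f <- withr::local_tempfile(fileext = ".nml")
  write_nml(ann, f)
  ann2 <- read_nml(f)
  expect_length(ann2$trees, 2)
  for (k in 1:2) {
    a <- ann$trees[[k]]; b <- ann2$trees[[k]]
    expect_equal(b$nodes$id, a$nodes$id)
    expect_equal(b$nodes$x, a$nodes$x, tolerance = 1e-9)
    expect_equal(b$nodes$y, a$nodes$y, tolerance = 1e-9)
    expect_equal(b$nodes$z, a$nodes$z, tolerance = 1e-9)
    expect_equal(b$nodes$radius, a$nodes$radius, tolerance = 1e-9)
    expect_equal(nrow(b$edges), nrow(a$edges))
    expect_equal(b$name, a$name)
  }
  expect_equal(ann2$trees[[1]]$nodes$comment[2], "soma")
  # second round trip is identical
  f2 <- withr::local_tempfile(fileext = ".nml")
  write_nml(ann2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("NML integrity and parse errors are informative", {
  bad_edge <- c(
    '<things><parameters><scale x="11" y="11" z="25"/></parameters>',
    '<thing id="1"><nodes><node id="1" x="0" y="0" z="0"/></nodes>',
    '<edges><edge source="1" target="99"/></edges></thing></things>'
  )
  f <- withr::local_tempfile(fileext = ".nml")
  writeLines(bad_edge, f)
  expect_error(read_nml(f), "99", class = "lptc_integrity_error")

  f2 <- withr::local_tempfile(fileext = ".nml")
  writeLines("<things><thing id=", f2)
  expect_error(read_nml(f2), class = "lptc_parse_error")
})

test_that("SWC round-trip preserves geometry up to renumbering", {
  tr <- y_tree()
  tr$nodes$radius <- c(150, 200, 250, 300)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, f)
  tr2 <- read_swc(f)
  expect_equal(nrow(tr2$nodes), 4)
  expect_equal(nrow(tr2$edges), 3)
  expect_equal(cable_length(tr2), cable_length(tr), tolerance = 1e-9)
  expect_equal(sort(tr2$nodes$radius), sort(tr$nodes$radius),
               tolerance = 1e-9)
  # parent pointers form a path for a path tree, root parent -1
  p <- path_tree(3)
  fp <- withr::local_tempfile(fileext = ".swc")
  write_swc(p, fp)
  m <- read.table(fp)
  expect_equal(m$V7, c(-1, 1, 2))
})

test_that("write_swc rejects cyclic trees", {
  triangle <- skeleton_tree(
    data.frame(id = 1:3, x = c(0, 1000, 0), y = c(0, 0, 1000), z = 0,
               radius = 100),
    data.frame(from = c(1, 2, 3), to = c(2, 3, 1))
  )
  f <- withr::local_tempfile(fileext = ".swc")
  expect_error(write_swc(triangle, f), class = "lptc_structure_error")
  expect_error(export_hoc(triangle, f), class = "lptc_structure_error")
})

test_that("hoc export emits one section per unbranched run", {
  f <- withr::local_tempfile(fileext = ".hoc")
  h <- export_hoc(path_tree(5), f)
  expect_length(h$sections, 1)
  expect_length(h$sections[[1]], 5)

  h2 <- export_hoc(y_tree(), f)
  expect_length(h2$sections, 3)
  # every node visited at least once; duplicates only at branch points
  visited <- unlist(h2$sections)
  expect_setequal(unique(visited), 1:4)
  expect_equal(length(visited), 4 + 2)  # branch node duplicated twice
  txt <- readLines(f)
  expect_equal(sum(grepl("pt3dadd", txt)), 6)
  expect_equal(sum(grepl("^connect", txt)), 2)
})

test_that("merge_parts joins matching endpoints across the seam", {
  seam <- 10e3
  lat <- skeleton_annotation(list(skeleton_tree(
    data.frame(id = 1:2, x = c(0, seam - 50), y = 0, z = 0, radius = 100),
    data.frame(from = 1, to = 2), name = "lat"
  )))
  med <- skeleton_annotation(list(skeleton_tree(
    data.frame(id = 1:2, x = c(seam + 50, 20e3), y = 0, z = 0, radius = 100),
    data.frame(from = 1, to = 2), name = "med"
  )))
  merged <- merge_parts(lat, med, seam = seam, tolerance = 500)
  expect_length(merged$trees, 1)
  tr <- merged$trees[[1]]
  expect_equal(nrow(tr$nodes), 4)      # no nodes deleted
  expect_equal(nrow(tr$edges), 3)      # one bridging edge added
  expect_setequal(unique(tr$nodes$part), c("lateral", "medial"))
  g <- igraph::components(lptcmorph:::tree_graph(tr))
  expect_equal(g$no, 1)
})

test_that("merge_parts leaves distant parts separate and preserves counts", {
  seam <- 10e3
  lat <- skeleton_annotation(list(skeleton_tree(
    data.frame(id = 1:2, x = c(0, seam - 50), y = 0, z = 0, radius = 100),
    data.frame(from = 1, to = 2)
  )))
  med <- skeleton_annotation(list(skeleton_tree(
    data.frame(id = 1:2, x = c(seam + 50, 20e3), y = 10e6, z = 0,
               radius = 100),
    data.frame(from = 1, to = 2)
  )))
  merged <- merge_parts(lat, med, seam = seam, tolerance = 500)
  expect_length(merged$trees, 2)
  expect_equal(sum(vapply(merged$trees, function(t) nrow(t$nodes),
                          integer(1))), 4)
})

test_that("merge_parts reports ambiguous multi-way matches", {
  seam <- 10e3
  lat <- skeleton_annotation(list(skeleton_tree(
    data.frame(id = 1:2, x = c(0, seam - 50), y = 0, z = 0, radius = 100),
    data.frame(from = 1, to = 2)
  )))
  med <- skeleton_annotation(list(
    skeleton_tree(data.frame(id = 1:2, x = c(seam + 50, 20e3), y = 0, z = 0,
                             radius = 100), data.frame(from = 1, to = 2)),
    skeleton_tree(data.frame(id = 3:4, x = c(seam + 50, 20e3), y = 100,
                             z = 0, radius = 100),
                  data.frame(from = 3, to = 4))
  ))
  err <- expect_error(merge_parts(lat, med, seam = seam, tolerance = 500),
                      class = "lptc_unresolved_match_error")
  expect_match(conditionMessage(err), "2")
})
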