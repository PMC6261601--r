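#' Total cable length of a skeleton
#'
#' Sum of Euclidean edge lengths, in nanometres. Invariant under node
#' renumbering and rigid motions.
#'
#' @param tree a [skeleton_tree()].
#' @return length in nm.
#' @export
cable_length <- function(tree) {
  if (!nrow(tree$edges)) return(0)
  sum(edge_lengths(tree))
}

edge_lengths <- function(tree) {
  if (!nrow(tree$edges)) return(numeric(0))
  i <- match(tree$edges$from, tree$nodes$id)
  j <- match(tree$edges$to, tree$nodes$id)
  sqrt((tree$nodes$x[i] - tree$nodes$x[j])^2 +
       (tree$nodes$y[i] - tree$nodes$y[j])^2 +
       (tree$nodes$z[i] - tree$nodes$z[j])^2)
}

#' Resample a skeleton to a maximum internode spacing
#'
#' Every edge of length L is replaced by `ceiling(L / max_nm)` colinear
#' sub-edges of equal length, with radii linearly interpolated along the
#' edge. Original nodes are kept fixed (their ids and positions are a subset
#' of the output) and total cable length is conserved exactly up to floating
#' point. The operation is idempotent. Inserted nodes carry the source edge
#' in columns `source_from`/`source_to`.
#'
#' @param tree a [skeleton_tree()].
#' @param max_nm maximum allowed internode distance in nm (default 400, the
#'   normalization spacing used throughout the layer analysis).
#' @return A resampled [skeleton_tree()] with attribute `resampled = max_nm`.
#' @export
resample_max_spacing <- function(tree, max_nm = 400) {
  stopifnot(max_nm > 0)
  nd <- tree$nodes
  if (is.null(nd$source_from)) nd$source_from <- NA_integer_
  if (is.null(nd$source_to)) nd$source_to <- NA_integer_
  if (!nrow(tree$edges)) {
    out <- tree
    out$nodes <- nd
    attr(out, "resampled") <- max_nm
    return(out)
  }
  lens <- edge_lengths(tree)
  # small tolerance so an exact-length edge is not split by float noise
  nsub <- pmax(1L, as.integer(ceiling(lens / max_nm - 1e-9)))
  next_id <- max(nd$id) + 1L
  new_nodes <- vector("list", nrow(tree$edges))
  new_edges <- vector("list", nrow(tree$edges))
  ii <- match(tree$edges$from, nd$id)
  jj <- match(tree$edges$to, nd$id)
  for (e in seq_len(nrow(tree$edges))) {
    k <- nsub[e]
    if (k == 1L) {
      new_edges[[e]] <- data.frame(from = tree$edges$from[e],
                                   to = tree$edges$to[e])
      next
    }
    t <- seq_len(k - 1L) / k
    i <- ii[e]; j <- jj[e]
    ids <- next_id + seq_len(k - 1L) - 1L
    next_id <- next_id + (k - 1L)
    new_nodes[[e]] <- data.frame(
      id = ids,
      x = nd$x[i] + t * (nd$x[j] - nd$x[i]),
      y = nd$y[i] + t * (nd$y[j] - nd$y[i]),
      z = nd$z[i] + t * (nd$z[j] - nd$z[i]),
      radius = nd$radius[i] + t * (nd$radius[j] - nd$radius[i]),
      comment = NA_character_,
      source_from = tree$edges$from[e],
      source_to = tree$edges$to[e]
    )
    chain <- c(tree$edges$from[e], ids, tree$edges$to[e])
    new_edges[[e]] <- data.frame(from = chain[-length(chain)],
                                 to = chain[-1])
  }
  extra_cols <- setdiff(names(nd), c("id", "x", "y", "z", "radius", "comment",
                                     "source_from", "source_to"))
  ins <- do.call(rbind, new_nodes)
  if (!is.null(ins) && length(extra_cols)) {
    for (cc in extra_cols) ins[[cc]] <- NA
  }
  base_cols <- c("id", "x", "y", "z", "radius", "comment",
                 "source_from", "source_to", extra_cols)
  all_nodes <- rbind(nd[, base_cols],
                     if (!is.null(ins)) ins[, base_cols])
  out <- skeleton_tree(all_nodes, do.call(rbind, new_edges), name = tree$name)
  attr(out, "resampled") <- max_nm
  out
}

#' Split a skeleton into connected components
#'
#' @param tree a [skeleton_tree()].
#' @return list of [skeleton_tree()]s, one per connected component.
#' @export
split_components <- function(tree) {
  if (!nrow(tree$nodes)) return(list(tree))
  g <- tree_graph(tree)
  memb <- igraph::components(g)$membership
  lapply(seq_len(max(memb)), function(c) {
    keep_ids <- tree$nodes$id[memb == c]
    nodes <- tree$nodes[tree$nodes$id %in% keep_ids, , drop = FALSE]
    edges <- tree$edges[tree$edges$from %in% keep_ids, , drop = FALSE]
    skeleton_tree(nodes, edges, name = sprintf("%s_c%d", tree$name, c))
  })
}

#' Largest connected component by cable length
#'
#' The component with the greatest total cable length (not node count) is
#' returned: a component's importance is how much neurite it carries, which
#' is robust to uneven annotation density.
#'
#' @param tree a [skeleton_tree()].
#' @return a [skeleton_tree()].
#' @export
largest_component <- function(tree) {
  comps <- split_components(tree)
  if (length(comps) == 1L) {
    out <- comps[[1]]
    out$name <- tree$name
    return(out)
  }
  lens <- vapply(comps, cable_length, numeric(1))
  out <- comps[[which.max(lens)]]
  out$name <- tree$name
  out
}

#' Estimate neurite volume from diameter annotations
#'
#' Models each edge as a truncated cone (frustum) between its two node radii:
#' V = pi/3 * L * (r1^2 + r1 r2 + r2^2), summed over edges and converted from
#' nm^3 to um^3. Overlap at branch points is not corrected. The soma
#' reconstruction (nodes commented `"soma"`, and edges touching them) is
#' excluded by default.
#'
#' @param tree a [skeleton_tree()] with strictly positive radii on all
#'   non-soma nodes.
#' @param exclude_soma drop soma-flagged nodes and their edges (default TRUE).
#' @return volume in um^3.
#' @export
estimate_volume <- function(tree, exclude_soma = TRUE) {
  soma <- is_soma_node(tree)
  nd <- tree$nodes
  bad <- which(!soma & (is.na(nd$radius) | nd$radius <= 0))
  if (length(bad)) {
    stop_("estimate_volume: non-positive radius on non-soma nodes: ",
          paste(utils::head(nd$id[bad], 10), collapse = ", "),
          if (length(bad) > 10) ", ...",
          class = "lptc_validation_error")
  }
  ed <- tree$edges
  if (!nrow(ed)) return(0)
  i <- match(ed$from, nd$id)
  j <- match(ed$to, nd$id)
  keep <- rep(TRUE, nrow(ed))
  if (exclude_soma) keep <- !(soma[i] | soma[j])
  if (!any(keep)) return(0)
  i <- i[keep]; j <- j[keep]
  L <- sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
              (nd$z[i] - nd$z[j])^2)
  r1 <- nd$radius[i]; r2 <- nd$radius[j]
  sum(pi / 3 * L * (r1^2 + r1 * r2 + r2^2)) / 1e9
}

#' Restrict skeletons to the most lateral part of the dataset
#'
#' Drops all nodes beyond `window_um` micrometres from the lateral face along
#' the mediolateral axis (with their dangling edges), the clipping used for
#' normalized sagittal views.
#'
#' @param trees a [skeleton_tree()], a list of trees, or a
#'   [skeleton_annotation()].
#' @param window_um window size in micrometres (default 118).
#' @param axis mediolateral axis index (default 1).
#' @return Same shape as the input, clipped. Idempotent.
#' @export
sagittal_clip <- function(trees, window_um = 118, axis = 1L) {
  clip1 <- function(tree) {
    ax <- c("x", "y", "z")[axis]
    keep <- tree$nodes[[ax]] <= window_um * 1e3
    ids <- tree$nodes$id[keep]
    edges <- tree$edges[tree$edges$from %in% ids & tree$edges$to %in% ids, ,
                        drop = FALSE]
    skeleton_tree(tree$nodes[keep, , drop = FALSE], edges, name = tree$name)
  }
  if (inherits(trees, "skeleton_tree")) return(clip1(trees))
  if (inherits(trees, "skeleton_annotation")) {
    trees$trees <- lapply(trees$trees, clip1)
    return(trees)
  }
  lapply(trees, clip1)
}
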