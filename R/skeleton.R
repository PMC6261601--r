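#' Skeleton trees and annotations
#'
#' A `skeleton_tree` is the universal currency of the pipeline: a graph of
#' annotated nodes (3D position in nanometres, per-node radius in nanometres,
#' optional free-text comment) joined by undirected edges. Despite the name it
#' is not required to be acyclic: annotations may contain cycles introduced by
#' merges. A `skeleton_annotation` bundles one or more trees with the voxel
#' scale of the source dataset and free-form metadata.
#'
#' Coordinate convention: `x` is the mediolateral (slicing) axis with the
#' lateral face of the dataset at 0, `y` is dorsoventral, `z` is
#' anteroposterior. Functions that depend on the convention expose it as an
#' argument.
#'
#' @param nodes data frame with columns `id` (unique positive integer), `x`,
#'   `y`, `z` (nm), and optionally `radius` (nm, default 0) and `comment`
#'   (character, default `NA`).
#' @param edges data frame with columns `from`, `to` holding node ids, or
#'   `NULL` for an edgeless tree.
#' @param name tree name.
#' @return An object of class `skeleton_tree`.
#' @examples
#' tr <- skeleton_tree(
#'   nodes = data.frame(id = 1:2, x = c(0, 300), y = c(0, 400), z = 0,
#'                      radius = 100),
#'   edges = data.frame(from = 1, to = 2)
#' )
#' cable_length(tr)
#' @export
skeleton_tree <- function(nodes, edges = NULL, name = "tree") {
  nodes <- as.data.frame(nodes)
  required <- c("id", "x", "y", "z")
  if (!all(required %in% names(nodes))) {
    stop_("skeleton_tree: nodes need columns ", paste(required, collapse = ", "),
          class = "lptc_structure_error")
  }
  if (is.null(nodes$radius)) nodes$radius <- rep(0, nrow(nodes))
  if (is.null(nodes$comment)) nodes$comment <- rep(NA_character_, nrow(nodes))
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) {
    stop_("skeleton_tree: duplicate node ids: ",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
          class = "lptc_structure_error")
  }
  if (any(nodes$radius < 0, na.rm = TRUE)) {
    stop_("skeleton_tree: negative radii", class = "lptc_structure_error")
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0))
  } else {
    edges <- as.data.frame(edges)[, c("from", "to")]
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
  }
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) {
    stop_("skeleton_tree: edges reference missing node ids: ",
          paste(sort(bad), collapse = ", "), class = "lptc_integrity_error")
  }
  if (any(edges$from == edges$to)) {
    stop_("skeleton_tree: self-edges not allowed", class = "lptc_structure_error")
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "skeleton_tree")
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat(sprintf("<skeleton_tree '%s': %d nodes, %d edges, cable %.1f um>\n",
              x$name, nrow(x$nodes), nrow(x$edges), cable_length(x) / 1e3))
  invisible(x)
}

#' @rdname skeleton_tree
#' @param trees list of `skeleton_tree` objects.
#' @param scale numeric length-3, nm per voxel of the source dataset.
#' @param metadata named list of free-form metadata.
#' @return `skeleton_annotation()` returns an object of class
#'   `skeleton_annotation`.
#' @export
skeleton_annotation <- function(trees, scale = c(11, 11, 25), metadata = list()) {
  if (inherits(trees, "skeleton_tree")) trees <- list(trees)
  stopifnot(all(vapply(trees, inherits, logical(1), "skeleton_tree")))
  scale <- as.numeric(scale)
  if (length(scale) != 3L || any(!is.finite(scale)) || any(scale <= 0)) {
    stop_("skeleton_annotation: voxel scale must be 3 strictly positive numbers",
          class = "lptc_structure_error")
  }
  structure(list(trees = trees, scale = scale, metadata = metadata),
            class = "skeleton_annotation")
}

#' @export
print.skeleton_annotation <- function(x, ...) {
  cat(sprintf("<skeleton_annotation: %d trees, scale (%g, %g, %g) nm/voxel>\n",
              length(x$trees), x$scale[1], x$scale[2], x$scale[3]))
  for (tr in x$trees) print(tr)
  invisible(x)
}

# igraph view of a tree; vertex names are node ids
tree_graph <- function(tree) {
  g <- igraph::make_empty_graph(n = nrow(tree$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(tree$nodes$id))
  if (nrow(tree$edges)) {
    g <- igraph::add_edges(g, rbind(
      match(tree$edges$from, tree$nodes$id),
      match(tree$edges$to, tree$nodes$id)
    ))
  }
  g
}

node_degrees <- function(tree) {
  deg <- integer(nrow(tree$nodes))
  names(deg) <- as.character(tree$nodes$id)
  if (nrow(tree$edges)) {
    tab <- table(c(tree$edges$from, tree$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Identify soma-flagged nodes
#'
#' Nodes whose comment contains `"soma"` (case-insensitive) form the soma
#' reconstruction; volume estimation excludes them by default.
#'
#' @param tree a `skeleton_tree`.
#' @return logical vector over nodes (in `tree$nodes` order).
#' @export
is_soma_node <- function(tree) {
  cm <- tree$nodes$comment
  !is.na(cm) & grepl("soma", cm, ignore.case = TRUE)
}
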