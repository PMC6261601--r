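#' Read a KNOSSOS/webKnossos NML skeleton file
#'
#' Parses the XML skeleton interchange dialect used by KNOSSOS and webKnossos
#' (`<things>`/`<thing>` containers with `<nodes>`, `<edges>` and optional
#' `<comments>`). Node positions and radii are stored in voxel units in the
#' file; they are converted to nanometres using the file's `<scale>` element
#' (positions per-axis, radii by the x scale, the convention of the isotropic
#' in-plane sampling). Node comments are taken both from a global
#' `<comments>` block (KNOSSOS) and from per-node `comment` attributes
#' (webKnossos).
#'
#' @param file path to an NML file or anything `xml2::read_xml` accepts.
#' @param default_scale voxel scale (nm) used if the file carries no
#'   `<scale>` element; the dataset default is 11 x 11 x 25 nm.
#' @return A [skeleton_annotation()].
#' @seealso [write_nml()], [read_swc()]
#' @export
read_nml <- function(file, default_scale = c(11, 11, 25)) {
  doc <- tryCatch(
    xml2::read_xml(file),
    error = function(e) {
      stop_("NML parse error: ", conditionMessage(e), class = "lptc_parse_error")
    }
  )
  root <- doc
  scale_node <- xml2::xml_find_first(root, ".//parameters/scale")
  if (inherits(scale_node, "xml_missing")) {
    scale <- default_scale
  } else {
    scale <- as.numeric(c(
      xml2::xml_attr(scale_node, "x"),
      xml2::xml_attr(scale_node, "y"),
      xml2::xml_attr(scale_node, "z")
    ))
  }

  # global comments (KNOSSOS flavor)
  cnodes <- xml2::xml_find_all(root, ".//comments/comment")
  comment_map <- character(0)
  if (length(cnodes)) {
    comment_map <- stats::setNames(
      xml2::xml_attr(cnodes, "content"),
      xml2::xml_attr(cnodes, "node")
    )
  }

  things <- xml2::xml_find_all(root, ".//thing")
  trees <- lapply(things, function(th) {
    nm <- xml2::xml_attr(th, "name")
    if (is.na(nm)) nm <- paste0("tree_", xml2::xml_attr(th, "id"))
    nd <- xml2::xml_find_all(th, ".//node")
    attr_num <- function(a) as.numeric(xml2::xml_attr(nd, a))
    if (length(nd)) {
      rad_vox <- attr_num("radius")
      rad_vox[is.na(rad_vox)] <- 0   # missing radius -> 0, flagged downstream
      nodes <- data.frame(
        id = as.integer(xml2::xml_attr(nd, "id")),
        x = attr_num("x") * scale[1],
        y = attr_num("y") * scale[2],
        z = attr_num("z") * scale[3],
        radius = rad_vox * scale[1],
        comment = xml2::xml_attr(nd, "comment")
      )
    } else {
      nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), radius = numeric(0),
                          comment = character(0))
    }
    if (length(comment_map)) {
      hit <- match(as.character(nodes$id), names(comment_map))
      nodes$comment <- ifelse(is.na(hit), nodes$comment, comment_map[hit])
    }
    ed <- xml2::xml_find_all(th, ".//edge")
    edges <- if (length(ed)) {
      data.frame(
        from = as.integer(xml2::xml_attr(ed, "source")),
        to = as.integer(xml2::xml_attr(ed, "target"))
      )
    } else NULL
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad)) {
      stop_("NML integrity error in tree '", nm,
            "': edges reference missing node ids: ",
            paste(sort(bad), collapse = ", "), class = "lptc_integrity_error")
    }
    skeleton_tree(nodes, edges, name = nm)
  })

  meta <- list()
  exp_node <- xml2::xml_find_first(root, ".//parameters/experiment")
  if (!inherits(exp_node, "xml_missing")) {
    meta$experiment <- xml2::xml_attr(exp_node, "name")
  }
  skeleton_annotation(trees, scale = scale, metadata = meta)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

num_chr <- function(x) sprintf("%.12g", x)

#' Write an annotation as KNOSSOS-flavor NML
#'
#' Emits positions and radii back in voxel units of the annotation's scale,
#' with node comments collected in a global `<comments>` block.
#'
#' @param annotation a [skeleton_annotation()] (a bare `skeleton_tree` is
#'   wrapped with the default scale).
#' @param file output path or connection.
#' @return `file`, invisibly.
#' @export
write_nml <- function(annotation, file) {
  if (inherits(annotation, "skeleton_tree")) {
    annotation <- skeleton_annotation(list(annotation))
  }
  sc <- annotation$scale
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<things>",
    "  <parameters>",
    if (!is.null(annotation$metadata$experiment)) {
      sprintf("    <experiment name=\"%s\"/>",
              xml_escape(annotation$metadata$experiment))
    },
    sprintf("    <scale x=\"%s\" y=\"%s\" z=\"%s\"/>",
            num_chr(sc[1]), num_chr(sc[2]), num_chr(sc[3])),
    "  </parameters>"
  )
  comments <- character(0)
  for (i in seq_along(annotation$trees)) {
    tr <- annotation$trees[[i]]
    lines <- c(lines, sprintf("  <thing id=\"%d\" name=\"%s\">",
                              i, xml_escape(tr$name)), "    <nodes>")
    nd <- tr$nodes
    lines <- c(lines, sprintf(
      "      <node id=\"%d\" radius=\"%s\" x=\"%s\" y=\"%s\" z=\"%s\"/>",
      nd$id, num_chr(nd$radius / sc[1]),
      num_chr(nd$x / sc[1]), num_chr(nd$y / sc[2]), num_chr(nd$z / sc[3])
    ))
    lines <- c(lines, "    </nodes>", "    <edges>")
    if (nrow(tr$edges)) {
      lines <- c(lines, sprintf(
        "      <edge source=\"%d\" target=\"%d\"/>", tr$edges$from, tr$edges$to
      ))
    }
    lines <- c(lines, "    </edges>", "  </thing>")
    has_cm <- !is.na(nd$comment) & nzchar(nd$comment)
    if (any(has_cm)) {
      comments <- c(comments, sprintf(
        "    <comment node=\"%d\" content=\"%s\"/>",
        nd$id[has_cm], xml_escape(nd$comment[has_cm])
      ))
    }
  }
  lines <- c(lines, "  <comments>", comments, "  </comments>", "</things>")
  writeLines(lines, file)
  invisible(file)
}

#' Read / write SWC skeleton files
#'
#' SWC is the classic rooted-forest morphology format: 7 whitespace-separated
#' columns (id, type, x, y, z, radius, parent), coordinates and radii in
#' micrometres by the common convention; they are converted to nanometres on
#' read. Soma-typed samples (type 1) get a `"soma"` comment so downstream
#' soma exclusion works across formats.
#'
#' @param file path or connection.
#' @return `read_swc()` returns a single [skeleton_tree()].
#' @export
read_swc <- function(file) {
  raw <- readLines(file)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  if (!length(raw)) {
    return(skeleton_tree(data.frame(id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0))))
  }
  m <- utils::read.table(text = raw, col.names = c("id", "type", "x", "y", "z",
                                                   "radius", "parent"))
  nodes <- data.frame(
    id = as.integer(m$id),
    x = m$x * 1e3, y = m$y * 1e3, z = m$z * 1e3,
    radius = m$radius * 1e3,
    comment = ifelse(m$type == 1L, "soma", NA_character_)
  )
  has_parent <- m$parent > 0
  edges <- if (any(has_parent)) {
    data.frame(from = as.integer(m$parent[has_parent]),
               to = as.integer(m$id[has_parent]))
  } else NULL
  skeleton_tree(nodes, edges, name = "swc")
}

# Root the tree and return parent ids (NA for root), in nodes order.
# Errors on cycles or disconnection.
rooted_parents <- function(tree, context = "write_swc") {
  n <- nrow(tree$nodes)
  if (n == 0L) return(integer(0))
  if (nrow(tree$edges) != n - 1L) {
    stop_(context, ": tree must be acyclic and connected (", n, " nodes, ",
          nrow(tree$edges), " edges)", class = "lptc_structure_error")
  }
  g <- tree_graph(tree)
  if (igraph::components(g)$no != 1L) {
    stop_(context, ": tree is disconnected", class = "lptc_structure_error")
  }
  soma <- which(is_soma_node(tree))
  root <- if (length(soma)) soma[1] else 1L
  bfs <- igraph::bfs(g, root = root, father = TRUE)
  parent_idx <- as.integer(bfs$father)
  parents <- tree$nodes$id[parent_idx]
  parents[root] <- NA_integer_
  parents
}

#' @rdname read_swc
#' @param tree a connected, acyclic [skeleton_tree()].
#' @export
write_swc <- function(tree, file) {
  parents <- rooted_parents(tree, "write_swc")
  nd <- tree$nodes
  # renumber to contiguous 1..n in DFS preorder so parents precede children
  ord <- dfs_order(tree)
  newid <- match(nd$id, nd$id[ord])
  type <- ifelse(is_soma_node(tree), 1L, 0L)
  out <- data.frame(
    id = seq_len(nrow(nd)),
    type = type[ord],
    x = nd$x[ord] / 1e3, y = nd$y[ord] / 1e3, z = nd$z[ord] / 1e3,
    radius = nd$radius[ord] / 1e3,
    parent = ifelse(is.na(parents[ord]), -1L, newid[match(parents[ord], nd$id)])
  )
  lines <- c("# SWC export (coordinates in um)",
             sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     out$id, out$type, out$x, out$y, out$z, out$radius,
                     out$parent))
  writeLines(lines, file)
  invisible(file)
}

# depth-first order of node indices starting at the SWC root
dfs_order <- function(tree) {
  n <- nrow(tree$nodes)
  if (n == 0L) return(integer(0))
  g <- tree_graph(tree)
  soma <- which(is_soma_node(tree))
  root <- if (length(soma)) soma[1] else 1L
  as.integer(igraph::dfs(g, root = root)$order)
}

#' Export a skeleton as a hoc morphology script
#'
#' Writes one `create`d section per unbranched run of edges with
#' `pt3dadd(x, y, z, diam)` point lists (micrometres) and `connect`
#' statements, the format consumed by NEURON-style tools and by Amira's hoc
#' reader. Branch-point nodes are duplicated into every section that touches
#' them, so the concatenated point lists visit every node at least once.
#'
#' @param tree a connected, acyclic [skeleton_tree()] with radii.
#' @param file output path or connection.
#' @return Invisibly, a list with the section node-index lists.
#' @export
export_hoc <- function(tree, file) {
  parents <- rooted_parents(tree, "export_hoc")
  nd <- tree$nodes
  n <- nrow(nd)
  idx_of <- function(id) match(id, nd$id)
  children <- split(seq_len(n), factor(parents, levels = nd$id))
  child_idx <- lapply(nd$id, function(id) {
    which(!is.na(parents) & parents == id)
  })
  root <- which(is.na(parents))
  deg <- lengths(child_idx)          # out-degree in rooted tree
  # sections: start at root/branch nodes, run to next branch/leaf inclusive
  sections <- list()
  parent_section <- integer(0)
  queue <- list()                    # (start_idx, parent_section)
  for (ci in child_idx[[root]]) queue[[length(queue) + 1L]] <- c(ci, NA, root)
  if (!length(child_idx[[root]])) {
    sections[[1]] <- root
    parent_section[1] <- NA_integer_
  }
  while (length(queue)) {
    item <- queue[[1]]; queue[[1]] <- NULL
    start <- item[1]; psec <- item[2]; prev <- item[3]
    run <- c(prev, start)
    cur <- start
    while (deg[cur] == 1L) {
      cur <- child_idx[[cur]][1]
      run <- c(run, cur)
    }
    sections[[length(sections) + 1L]] <- run
    parent_section[length(sections)] <- psec
    for (ci in child_idx[[cur]]) {
      queue[[length(queue) + 1L]] <- c(ci, length(sections), cur)
    }
  }
  # sections spawned directly at a branching root have no parent section;
  # anchor them to the first such section at its 0 end
  root_secs <- which(is.na(parent_section))
  anchor <- rep(1, length(sections))
  if (length(root_secs) > 1L) {
    parent_section[root_secs[-1]] <- root_secs[1]
    anchor[root_secs[-1]] <- 0
  }
  nm <- function(i) sprintf("sect_%d", i - 1L)
  lines <- c(sprintf("// hoc morphology export: %s", tree$name),
             sprintf("create %s", paste(vapply(seq_along(sections), nm,
                                               character(1)), collapse = ", ")))
  for (i in seq_along(sections)) {
    run <- sections[[i]]
    lines <- c(lines, sprintf("%s {", nm(i)), "  pt3dclear()",
               sprintf("  pt3dadd(%.9g, %.9g, %.9g, %.9g)",
                       nd$x[run] / 1e3, nd$y[run] / 1e3, nd$z[run] / 1e3,
                       2 * nd$radius[run] / 1e3),
               "}")
  }
  for (i in seq_along(sections)) {
    if (!is.na(parent_section[i])) {
      lines <- c(lines, sprintf("connect %s(0), %s(%g)",
                                nm(i), nm(parent_section[i]), anchor[i]))
    }
  }
  writeLines(lines, file)
  invisible(list(sections = sections, parent_section = parent_section))
}

#' Merge the lateral and medial parts of a split reconstruction
#'
#' The source volume was stored as two datasets split along the slicing axis,
#' so every cell has a lateral and a medial part. Free endpoints (degree <= 1
#' nodes) lying within `tolerance` of the seam plane are matched across the
#' seam by Euclidean distance; matched trees are joined with a bridging edge.
#' Medial node ids are renumbered with an offset to avoid collisions and each
#' node records its provenance in a `part` column; an id-mapping table is
#' attached as attribute `id_map`.
#'
#' @param lateral,medial [skeleton_annotation()]s in a common coordinate
#'   frame.
#' @param seam seam position (nm) along `axis`.
#' @param tolerance maximum endpoint-to-endpoint distance (nm) for a join.
#' @param axis axis index of the seam normal (1 = mediolateral, the default).
#' @return A merged [skeleton_annotation()]; node counts are preserved.
#' @export
merge_parts <- function(lateral, medial, seam, tolerance, axis = 1L) {
  stopifnot(inherits(lateral, "skeleton_annotation"),
            inherits(medial, "skeleton_annotation"))
  ax <- c("x", "y", "z")[axis]
  max_id <- max(0L, unlist(lapply(lateral$trees, function(t) t$nodes$id)))
  offset <- as.integer(10^ceiling(log10(max(max_id, 1) + 1)))

  tag <- function(tree, part, off = 0L) {
    tree$nodes$part <- part
    if (off) {
      tree$nodes$id <- tree$nodes$id + off
      if (nrow(tree$edges)) {
        tree$edges$from <- tree$edges$from + off
        tree$edges$to <- tree$edges$to + off
      }
    }
    tree
  }
  lat <- lapply(lateral$trees, tag, part = "lateral")
  med <- lapply(medial$trees, tag, part = "medial", off = offset)
  pool <- c(lat, med)
  side <- rep(c("lateral", "medial"), c(length(lat), length(med)))

  endpoints <- function(tree, tree_idx) {
    deg <- node_degrees(tree)
    keep <- deg <= 1L &
      abs(tree$nodes[[ax]] - seam) <= tolerance
    if (!any(keep)) return(NULL)
    cbind(tree$nodes[keep, c("id", "x", "y", "z")], tree = tree_idx)
  }
  ep <- do.call(rbind, c(
    lapply(seq_along(pool), function(i) endpoints(pool[[i]], i)),
    list(make.row.names = FALSE)
  ))
  bridges <- NULL
  if (!is.null(ep) && nrow(ep)) {
    ep_lat <- ep[side[ep$tree] == "lateral", , drop = FALSE]
    ep_med <- ep[side[ep$tree] == "medial", , drop = FALSE]
    if (nrow(ep_lat) && nrow(ep_med)) {
      d <- outer(seq_len(nrow(ep_lat)), seq_len(nrow(ep_med)),
                 Vectorize(function(i, j) {
                   vnorm(as.numeric(ep_lat[i, c("x", "y", "z")]) -
                           as.numeric(ep_med[j, c("x", "y", "z")]))
                 }))
      within <- d <= tolerance
      multi_l <- which(rowSums(within) > 1L)
      multi_m <- which(colSums(within) > 1L)
      if (length(multi_l) || length(multi_m)) {
        cand <- if (length(multi_l)) {
          paste0("lateral node ", ep_lat$id[multi_l[1]], " -> medial nodes ",
                 paste(ep_med$id[within[multi_l[1], ]], collapse = ", "))
        } else {
          paste0("medial node ", ep_med$id[multi_m[1]], " -> lateral nodes ",
                 paste(ep_lat$id[within[, multi_m[1]]], collapse = ", "))
        }
        stop_("merge_parts: ambiguous endpoint correspondence within tolerance (",
              cand, "); resolve manually", class = "lptc_unresolved_match_error")
      }
      hit <- which(within, arr.ind = TRUE)
      if (nrow(hit)) {
        bridges <- data.frame(
          from = ep_lat$id[hit[, 1]], to = ep_med$id[hit[, 2]],
          tree_from = ep_lat$tree[hit[, 1]], tree_to = ep_med$tree[hit[, 2]]
        )
      }
    }
  }

  # union-find over trees joined by bridges
  comp <- seq_along(pool)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (!is.null(bridges)) {
    for (k in seq_len(nrow(bridges))) {
      a <- find(bridges$tree_from[k]); b <- find(bridges$tree_to[k])
      if (a != b) comp[b] <- a
    }
  }
  roots <- vapply(seq_along(pool), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    members <- which(roots == r)
    nodes <- do.call(rbind, lapply(pool[members], `[[`, "nodes"))
    edges <- do.call(rbind, lapply(pool[members], `[[`, "edges"))
    if (!is.null(bridges)) {
      br <- bridges[bridges$tree_from %in% members, c("from", "to")]
      if (nrow(br)) edges <- rbind(edges, br)
    }
    nm <- paste(unique(vapply(pool[members], `[[`, character(1), "name")),
                collapse = "+")
    skeleton_tree(nodes, edges, name = nm)
  })
  out <- skeleton_annotation(merged, scale = lateral$scale,
                             metadata = c(lateral$metadata,
                                          list(merged_seam = seam)))
  attr(out, "id_map") <- data.frame(
    part = "medial",
    original_id = unlist(lapply(medial$trees, function(t) t$nodes$id)),
    merged_id = unlist(lapply(medial$trees, function(t) t$nodes$id)) + offset
  )
  out
}
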