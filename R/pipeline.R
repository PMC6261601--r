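#' Study configuration
#'
#' Bundles every tunable constant of the analysis with the defaults used
#' throughout: 400 nm resampling, 140 nm contact voxels, 2 closing rounds,
#' 7 growth rounds, area divisor 51, contact depth window 86-203 um,
#' sagittal window 118 um, and a 500 um^3 volume classification threshold.
#'
#' @param cells named list; each element is either a [skeleton_tree()], a
#'   [skeleton_annotation()], a file path, or a list with elements `lateral`
#'   and `medial` (paths or annotations) to be merged.
#' @param outline a [plate_outline()], `synthetic_plate`, annotation or file
#'   path holding the plate outline.
#' @param resample_nm,voxel_nm,roi_um,sagittal_window_um,closing_rounds,growth_rounds,area_divisor,volume_threshold_um3
#'   pipeline constants (see Details for defaults).
#' @param merge_seam,merge_tolerance seam position and tolerance (nm) for
#'   two-part cells.
#' @param seed seed recorded for provenance.
#' @return object of class `study_config`.
#' @export
study_config <- function(cells = list(), outline = NULL,
                         resample_nm = 400, voxel_nm = 140,
                         roi_um = c(86, 203), sagittal_window_um = 118,
                         closing_rounds = 2, growth_rounds = 7,
                         area_divisor = 51, volume_threshold_um3 = 500,
                         merge_seam = NULL, merge_tolerance = 500,
                         seed = 1) {
  num <- c(resample_nm = resample_nm, voxel_nm = voxel_nm,
           closing_rounds = closing_rounds, growth_rounds = growth_rounds,
           area_divisor = area_divisor,
           volume_threshold_um3 = volume_threshold_um3,
           sagittal_window_um = sagittal_window_um)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop_("study_config: all numeric parameters must be positive",
          class = "lptc_config_error")
  }
  structure(list(
    cells = cells, outline = outline, resample_nm = resample_nm,
    voxel_nm = voxel_nm, roi_um = roi_um,
    sagittal_window_um = sagittal_window_um,
    closing_rounds = closing_rounds, growth_rounds = growth_rounds,
    area_divisor = area_divisor,
    volume_threshold_um3 = volume_threshold_um3,
    merge_seam = merge_seam, merge_tolerance = merge_tolerance,
    seed = seed
  ), class = "study_config")
}

config_list <- function(config) {
  unclass(config)[c("resample_nm", "voxel_nm", "roi_um",
                    "sagittal_window_um", "closing_rounds", "growth_rounds",
                    "area_divisor", "volume_threshold_um3", "seed")]
}

#' Read a skeleton file, sniffing its format
#'
#' NML (XML) is detected by a leading `<`; anything else is read as SWC.
#'
#' @param path file path.
#' @return a [skeleton_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop_("file not found: ", path, class = "lptc_io_error")
  }
  head <- readChar(path, 256)
  if (grepl("^\\s*<", head)) {
    read_nml(path)
  } else {
    skeleton_annotation(list(read_swc(path)))
  }
}

# resolve a config cell entry to one skeleton_tree
resolve_cell <- function(entry, config, merge = TRUE) {
  if (inherits(entry, "skeleton_tree")) return(entry)
  if (inherits(entry, "skeleton_annotation")) {
    return(entry$trees[[1]])
  }
  if (is.character(entry)) {
    return(resolve_cell(read_annotation(entry), config))
  }
  if (is.list(entry) && !is.null(entry$lateral) && !is.null(entry$medial)) {
    as_ann <- function(x) {
      if (is.character(x)) read_annotation(x)
      else if (inherits(x, "skeleton_tree")) skeleton_annotation(list(x))
      else x
    }
    if (is.null(config$merge_seam)) {
      stop_("study_config: two-part cell given but merge_seam is NULL",
            class = "lptc_config_error")
    }
    merged <- merge_parts(as_ann(entry$lateral), as_ann(entry$medial),
                          seam = config$merge_seam,
                          tolerance = config$merge_tolerance)
    return(merged$trees[[1]])
  }
  stop_("cannot interpret cell entry of class ", paste(class(entry),
        collapse = "/"), class = "lptc_config_error")
}

resolve_outline <- function(outline) {
  if (inherits(outline, "plate_outline")) return(outline)
  if (inherits(outline, "synthetic_plate")) return(outline$outline)
  if (is.character(outline)) return(outline_from_annotation(read_annotation(outline)))
  if (inherits(outline, "skeleton_annotation")) return(outline_from_annotation(outline))
  stop_("cannot interpret outline of class ", paste(class(outline),
        collapse = "/"), class = "lptc_config_error")
}

#' Per-cell layer analysis
#'
#' Builds the layer model from the configured outline, then for every cell:
#' resamples the skeleton, assigns depths and layers, and reports the
#' six-bin layer histogram plus depth boxplot statistics. With `out_dir`,
#' writes `layers.csv`, `boxplots.json`, a resolved-config `config.json`
#' and a `sagittal.pdf` with one normalized sagittal view per cell
#' (see [sagittal_view()]).
#'
#' @param config a [study_config()] with at least one cell and an outline.
#' @param out_dir optional output directory.
#' @return list: `table` (data frame: cell, layer1..layer4, anterior,
#'   posterior, n_nodes), `boxplots`, `model`, `config`.
#' @export
run_layers <- function(config, out_dir = NULL) {
  if (!length(config$cells)) {
    stop_("run_layers: empty cell list", class = "lptc_config_error")
  }
  if (is.null(config$outline)) {
    stop_("run_layers: no outline configured", class = "lptc_config_error")
  }
  sides <- split_outline(resolve_outline(config$outline))
  model <- build_layer_model(sides$anterior, sides$posterior)
  nms <- names(config$cells) %||% paste0("cell", seq_along(config$cells))
  rows <- list(); boxplots <- list(); resampled <- list()
  for (i in seq_along(config$cells)) {
    tree <- resolve_cell(config$cells[[i]], config)
    rs <- resample_max_spacing(tree, config$resample_nm)
    rs$name <- nms[i]
    resampled[[i]] <- rs
    asg <- assign_depth(rs, model)
    h <- layer_histogram(asg)
    boxplots[[nms[i]]] <- depth_boxplot_stats(asg)
    rows[[i]] <- data.frame(cell = nms[i], t(as.matrix(h)),
                            n_nodes = attr(h, "n"))
  }
  table <- do.call(rbind, rows)
  out <- list(table = table, boxplots = boxplots, model = model,
              config = config_list(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "layers.csv"),
                     row.names = FALSE)
    jsonlite::write_json(boxplots, file.path(out_dir, "boxplots.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(out$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    grDevices::pdf(file.path(out_dir, "sagittal.pdf"), width = 7, height = 5)
    for (rs in resampled) {
      sagittal_view(rs, model, window_um = config$sagittal_window_um)
    }
    grDevices::dev.off()
  }
  out
}

#' Per-cell volume estimation
#'
#' For every cell: merge parts if needed, keep the largest component by
#' cable length, exclude the soma reconstruction, and estimate the frustum
#' volume; cells are classified against the volume threshold (inclusive
#' `>=`, so a cell exactly at the threshold counts as above).
#'
#' @inheritParams run_layers
#' @return list: `table` (cell, volume_um3, cable_mm, above_threshold),
#'   `config`.
#' @export
run_volumes <- function(config, out_dir = NULL) {
  if (!length(config$cells)) {
    stop_("run_volumes: empty cell list", class = "lptc_config_error")
  }
  nms <- names(config$cells) %||% paste0("cell", seq_along(config$cells))
  rows <- lapply(seq_along(config$cells), function(i) {
    tree <- largest_component(resolve_cell(config$cells[[i]], config))
    v <- estimate_volume(tree, exclude_soma = TRUE)
    data.frame(cell = nms[i], volume_um3 = v,
               cable_mm = cable_length(tree) / 1e6,
               above_threshold = v >= config$volume_threshold_um3)
  })
  table <- do.call(rbind, rows)
  out <- list(table = table, config = config_list(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "volumes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Pairwise contact analysis of the axonal tract
#'
#' Runs the full contact chain ([measure_contacts()]) on the configured
#' cells within the configured depth window and reports the symmetric
#' contact matrix as a long table with zero-contact pairs flagged for
#' manual review. Deterministic: identical config and inputs give
#' byte-identical CSVs.
#'
#' @inheritParams run_layers
#' @param max_voxels voxel budget forwarded to [voxelize()].
#' @return list: `matrix` (a `contact_matrix`), `table` (cell_a, cell_b,
#'   area_um2, zero_flag), `config`.
#' @export
run_contacts <- function(config, out_dir = NULL, max_voxels = 2e8) {
  if (length(config$cells) < 2L) {
    stop_("run_contacts: need at least 2 cells", class = "lptc_config_error")
  }
  nms <- names(config$cells) %||% paste0("cell", seq_along(config$cells))
  trees <- lapply(seq_along(config$cells), function(i) {
    tr <- resolve_cell(config$cells[[i]], config)
    tr$name <- nms[i]
    tr
  })
  cm <- measure_contacts(
    trees, voxel_nm = config$voxel_nm, roi_um = config$roi_um,
    closing_rounds = config$closing_rounds,
    growth_rounds = config$growth_rounds,
    resample_nm = config$resample_nm, max_voxels = max_voxels,
    divisor = config$area_divisor
  )
  pairs <- which(upper.tri(cm$area), arr.ind = TRUE)
  table <- data.frame(
    cell_a = cm$labels[pairs[, 1]], cell_b = cm$labels[pairs[, 2]],
    area_um2 = cm$area[pairs],
    zero_flag = cm$area[pairs] == 0
  )
  out <- list(matrix = cm, table = table, config = config_list(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "contacts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
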