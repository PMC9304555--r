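# Plain-text artifact formats: CSV tables + JSON metadata sidecars.
# All numbers are serialized as decimal text at 9 significant digits so
# write -> read -> write reproduces identical bytes.

default_sidecar_path <- function(path) {
  sub("\\.csv$", ".json", path)
}

write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a force-curve bundle to CSV + JSON sidecar
#'
#' The on-disk contract for raw curves: one long CSV with columns
#' `curve_id, grid_x_um, grid_y_um, sample_index, piezo_z_um,
#' deflection_um`, plus a JSON sidecar carrying the probe parameters, the
#' raster step, the seed, and (for synthetic bundles) the ground-truth
#' field parameters.
#'
#' @param bundle A `force_bundle` (or list of `force_curve`s).
#' @param path CSV output path.
#' @param meta_path Sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @param config_hash Optional provenance hash recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_force_bundle <- function(bundle, path,
                               meta_path = default_sidecar_path(path),
                               config_hash = NULL) {
  rows <- lapply(bundle, function(fc) {
    data.frame(curve_id = fc$curve_id,
               grid_x_um = fc$grid_x_um, grid_y_um = fc$grid_y_um,
               sample_index = seq_along(fc$piezo_z_um),
               piezo_z_um = fc$piezo_z_um, deflection_um = fc$deflection_um)
  })
  write_csv9(do.call(rbind, rows), path)
  probe <- attr(bundle, "probe")
  if (is.null(probe)) probe <- bundle[[1]]$probe
  truth <- attr(bundle, "truth")
  meta <- list(probe = unclass(probe),
               step_um = attr(bundle, "step_um"),
               seed = attr(bundle, "seed"),
               n_curves = length(bundle),
               n_rows = sum(vapply(bundle, function(fc) length(fc$piezo_z_um),
                                   numeric(1))),
               config_hash = config_hash)
  if (!is.null(truth)) {
    meta$truth <- list(params = as.list(truth$params),
                       profile = truth$profile,
                       segment_length_points = truth$segment_length_points,
                       k_noise_sd = truth$k_noise_sd,
                       starts_with = truth$starts_with)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a force-curve bundle written by [write_force_bundle()]
#'
#' Validates the column contract, groups rows by `curve_id`, orders
#' samples by `sample_index`, and checks that the piezo position is
#' strictly increasing within each curve. Errors name the offending
#' column or curve.
#'
#' @param path CSV path.
#' @param meta_path JSON sidecar path (default: alongside).
#' @return A `force_bundle` with the sidecar attached as attributes
#'   (`probe`, `step_um`, `seed`, `meta`).
#' @export
read_force_bundle <- function(path, meta_path = default_sidecar_path(path)) {
  if (!file.exists(meta_path)) {
    stop_input("read_force_bundle: missing JSON sidecar %s", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "grid_x_um", "grid_y_um", "sample_index",
            "piezo_z_um", "deflection_um")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop_input("read_force_bundle: missing column(s) %s in %s",
               paste(missing_cols, collapse = ", "), path)
  }
  probe <- do.call(probe_spec, meta$probe[c("spring_constant", "bead_radius_um",
                                            "set_force_nN",
                                            "approach_speed_um_s")])
  if (!is.null(meta$n_curves) &&
      length(unique(tab$curve_id)) != meta$n_curves) {
    stop_input("read_force_bundle: CSV holds %d curve(s) but sidecar declares %d",
               length(unique(tab$curve_id)), meta$n_curves)
  }
  if (!is.null(meta$n_rows) && nrow(tab) != meta$n_rows) {
    stop_input("read_force_bundle: truncated file: %d rows where sidecar declares %d (incomplete curve %s)",
               nrow(tab), meta$n_rows, tab$curve_id[nrow(tab)])
  }
  curves <- lapply(split(tab, tab$curve_id), function(g) {
    g <- g[order(g$sample_index), ]
    if (any(diff(g$piezo_z_um) <= 0)) {
      stop_input("read_force_bundle: piezo position not strictly increasing in curve %s",
                 g$curve_id[1])
    }
    if (any(diff(g$sample_index) != 1L) || g$sample_index[1] != 1L) {
      stop_input("read_force_bundle: incomplete sample series in curve %s",
                 g$curve_id[1])
    }
    structure(list(curve_id = g$curve_id[1], grid_x_um = g$grid_x_um[1],
                   grid_y_um = g$grid_y_um[1], piezo_z_um = g$piezo_z_um,
                   deflection_um = g$deflection_um, probe = probe,
                   truth = NULL),
              class = "force_curve")
  })
  curves <- curves[order(names(curves))]
  names(curves) <- NULL
  structure(curves, class = "force_bundle", probe = probe,
            step_um = meta$step_um, seed = meta$seed, meta = meta)
}

#' Write / read per-curve fit tables, maps, profiles and cell counts
#'
#' Thin CSV writers/readers for the pipeline's flat tables, all using the
#' 9-significant-digit decimal contract. `write_stiffness_map()` stores
#' the map in long form (`x_um, y_um, K_Pa`) with a JSON sidecar holding
#' the step and origin; `read_stiffness_map()` reassembles the matrix.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @param meta_path JSON sidecar path where applicable.
#' @param config_hash Optional provenance hash for the sidecar.
#' @return The path (writers, invisibly) or the parsed object (readers).
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
write_curve_fits <- function(x, path) write_csv9(as.data.frame(x), path)

#' @rdname artifact_io
#' @export
read_curve_fits <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("curve_fits", "data.frame")
  out
}

#' @rdname artifact_io
#' @export
write_stiffness_map <- function(x, path,
                                meta_path = default_sidecar_path(path),
                                config_hash = NULL) {
  stopifnot(inherits(x, "stiffness_map"))
  nr <- nrow(x$K_grid); nc <- ncol(x$K_grid)
  long <- data.frame(
    x_um = x$origin_um[["x"]] + (rep(seq_len(nc), each = nr) - 1) * x$step_um,
    y_um = x$origin_um[["y"]] + (rep(seq_len(nr), nc) - 1) * x$step_um,
    K_Pa = as.numeric(x$K_grid))
  write_csv9(long, path)
  jsonlite::write_json(list(step_um = x$step_um,
                            origin_um = as.list(x$origin_um),
                            ap_axis = x$ap_axis,
                            config_hash = config_hash),
                       meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_stiffness_map <- function(path, meta_path = default_sidecar_path(path)) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  assemble_map(data.frame(grid_x_um = long$x_um, grid_y_um = long$y_um,
                          K_Pa = long$K_Pa),
               step_um = meta$step_um)
}

#' @rdname artifact_io
#' @export
write_ap_profile <- function(x, path,
                             meta_path = default_sidecar_path(path),
                             config_hash = NULL) {
  stopifnot(inherits(x, "ap_profile"))
  write_csv9(as.data.frame(x), path)
  jsonlite::write_json(list(rows_used = attr(x, "rows_used"),
                            step_um = attr(x, "step_um"),
                            config_hash = config_hash),
                       meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_ap_profile <- function(path, meta_path = default_sidecar_path(path)) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "rows_used") <- meta$rows_used
    attr(out, "step_um") <- meta$step_um
  }
  class(out) <- c("ap_profile", "data.frame")
  out
}

#' @rdname artifact_io
#' @export
write_cell_counts <- function(x, path) write_csv9(as.data.frame(x), path)

#' @rdname artifact_io
#' @export
read_cell_counts <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "stage", "half", "roi_area_um2", "n_nuclei")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols) > 0) {
    stop_input("read_cell_counts: missing column(s) %s",
               paste(missing_cols, collapse = ", "))
  }
  class(out) <- c("cell_count_table", "data.frame")
  out
}
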