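# Spatial assembly of per-curve K estimates and A/P profile extraction.

#' Assemble per-curve fits into a raster stiffness map
#'
#' Places K estimates on a regular grid by rounding each curve's stage
#' coordinates to the nearest multiple of `step_um` (coordinates must land
#' within 10% of a grid node). Columns run along the antero-posterior axis
#' (`grid_x_um`), rows along dorso-ventral (`grid_y_um`). Non-converged
#' fits become missing cells; duplicate coordinates are an error.
#'
#' @param fits A `curve_fits` data frame (see [fit_grid()]), or any data
#'   frame with `grid_x_um`, `grid_y_um`, `K_Pa` and optionally
#'   `converged`.
#' @param step_um Raster step in micrometres (default 15).
#' @return An object of class `stiffness_map`: list with the `K_grid`
#'   matrix (rows = D/V, cols = A/P, `NA` for missing), `step_um`,
#'   `origin_um = c(x, y)` of the first grid node, and `ap_axis = "cols"`.
#' @export
assemble_map <- function(fits, step_um = 15) {
  need <- c("grid_x_um", "grid_y_um", "K_Pa")
  if (!all(need %in% names(fits))) {
    stop_input("assemble_map: fits must carry columns %s",
               paste(need, collapse = ", "))
  }
  if (step_um <= 0) stop_input("assemble_map: step_um must be positive")
  ox <- min(fits$grid_x_um)
  oy <- min(fits$grid_y_um)
  fx <- (fits$grid_x_um - ox) / step_um
  fy <- (fits$grid_y_um - oy) / step_um
  off <- pmax(abs(fx - round(fx)), abs(fy - round(fy)))
  if (any(off > 0.1)) {
    bad <- which(off > 0.1)
    stop_input("assemble_map: coordinates off the %g um raster at (%s)",
               step_um,
               paste(sprintf("%g,%g", fits$grid_x_um[bad], fits$grid_y_um[bad])[
                 seq_len(min(5L, length(bad)))], collapse = "; "))
  }
  col <- as.integer(round(fx)) + 1L
  row <- as.integer(round(fy)) + 1L
  key <- paste(row, col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_input("assemble_map: duplicate grid coordinates at (row col) %s", dup)
  }
  K <- matrix(NA_real_, nrow = max(row), ncol = max(col))
  val <- fits$K_Pa
  if ("converged" %in% names(fits)) val[!fits$converged] <- NA_real_
  K[cbind(row, col)] <- val
  structure(list(K_grid = K, step_um = step_um, origin_um = c(x = ox, y = oy),
                 ap_axis = "cols"),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("Stiffness map: %d (D/V) x %d (A/P) at %g um step, %d missing cell(s)\n",
              nrow(x$K_grid), ncol(x$K_grid), x$step_um, sum(is.na(x$K_grid))))
  cat(sprintf("  K range: %.3g .. %.3g Pa\n",
              min(x$K_grid, na.rm = TRUE), max(x$K_grid, na.rm = TRUE)))
  invisible(x)
}

#' Extract the antero-posterior stiffness profile of a map
#'
#' Averages K over a set of dorso-ventral rows at each step along the A/P
#' axis — by default the three central rows of the sclerotome band, the
#' "mean of three values at each step" representation used for the
#' periodicity fit. Missing cells are ignored; a column with no usable row
#' yields a missing profile point.
#'
#' @param map A `stiffness_map`.
#' @param rows Integer row indices to average; `NULL` selects the 3 central
#'   rows (or all rows for maps shorter than 3).
#' @return A data frame of class `ap_profile` with columns `t` (0-based
#'   step index along A/P), `position_um`, `K_Pa`, `n_rows_used`; the rows
#'   used and step size travel as attributes.
#' @export
ap_profile <- function(map, rows = NULL) {
  stopifnot(inherits(map, "stiffness_map"))
  nr <- nrow(map$K_grid)
  if (is.null(rows)) {
    rows <- if (nr <= 3L) seq_len(nr) else {
      start <- (nr - 3L) %/% 2L + 1L
      start:(start + 2L)
    }
  }
  if (length(rows) < 1L || any(rows < 1L | rows > nr)) {
    stop_input("ap_profile: row selection outside 1..%d", nr)
  }
  sub <- map$K_grid[rows, , drop = FALSE]
  n_used <- as.integer(colSums(!is.na(sub)))
  k <- colMeans(sub, na.rm = TRUE)
  k[n_used == 0L] <- NA_real_
  nc <- ncol(sub)
  out <- data.frame(t = seq_len(nc) - 1L,
                    position_um = map$origin_um[["x"]] + (seq_len(nc) - 1L) * map$step_um,
                    K_Pa = k, n_rows_used = n_used)
  attr(out, "rows_used") <- rows
  attr(out, "step_um") <- map$step_um
  class(out) <- c("ap_profile", "data.frame")
  out
}
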