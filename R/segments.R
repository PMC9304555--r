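# Half-sclerotome segmentation of the antero-posterior axis.

#' Divide the A/P axis into anterior/posterior half-segments
#'
#' Splits an antero-posterior extent into consecutive somite segments of a
#' fixed length and each segment into an anterior and a posterior half. For
#' odd segment lengths the anterior half receives the extra point. Partial
#' terminal segments (and, with `offset > 0`, the leading partial run) are
#' dropped.
#'
#' Column indices are 1-based (R convention); the matching 0-based profile
#' coordinate is `t = col - 1`.
#'
#' @param extent Number of points along the A/P axis.
#' @param segment_length_points Points per somite segment (15 by default:
#'   one segment per 15 steps of the raster).
#' @param starts_with Which half the first full segment begins with.
#' @param offset Points to skip before the first full segment.
#' @param first_stage Somite-stage index of the first segment (roman-numeral
#'   order, larger = older); stages increase along the axis.
#'
#' @return A data frame of class `segment_annotation` with one row per
#'   segment: `segment_id`, `stage`, and 1-based inclusive column ranges
#'   `anterior_start`, `anterior_end`, `posterior_start`, `posterior_end`.
#' @examples
#' assign_halves(45, 15, starts_with = "anterior")
#' @export
assign_halves <- function(extent, segment_length_points = 15,
                          starts_with = c("anterior", "posterior"),
                          offset = 0, first_stage = 8L) {
  starts_with <- match.arg(starts_with)
  if (!is_count(extent) || !is_count(segment_length_points)) {
    stop_input("assign_halves: extent and segment_length_points must be positive integers")
  }
  if (offset < 0 || offset >= extent) {
    stop_input("assign_halves: offset (%s) must lie in [0, extent)", offset)
  }
  usable <- extent - offset
  if (usable < segment_length_points) {
    stop_input("assign_halves: extent %d (offset %d) holds no full segment of length %d",
               extent, offset, segment_length_points)
  }
  n_seg <- usable %/% segment_length_points
  L <- segment_length_points
  n_ant <- ceiling(L / 2)  # ties to the anterior half
  n_post <- L - n_ant
  seg_start <- offset + (seq_len(n_seg) - 1L) * L + 1L
  if (starts_with == "anterior") {
    a_start <- seg_start
    a_end <- seg_start + n_ant - 1L
    p_start <- a_end + 1L
    p_end <- seg_start + L - 1L
  } else {
    p_start <- seg_start
    p_end <- seg_start + n_post - 1L
    a_start <- p_end + 1L
    a_end <- seg_start + L - 1L
  }
  ann <- data.frame(segment_id = seq_len(n_seg),
                    stage = as.integer(first_stage) + seq_len(n_seg) - 1L,
                    anterior_start = as.integer(a_start),
                    anterior_end = as.integer(a_end),
                    posterior_start = as.integer(p_start),
                    posterior_end = as.integer(p_end))
  attr(ann, "segment_length_points") <- L
  attr(ann, "starts_with") <- starts_with
  attr(ann, "extent") <- as.integer(extent)
  class(ann) <- c("segment_annotation", "data.frame")
  ann
}

#' Expand a segment annotation to per-column half labels
#'
#' @param annotation A `segment_annotation` from [assign_halves()].
#' @param extent Total number of A/P columns to label; columns outside any
#'   full segment get `NA`.
#' @return Character vector of length `extent` with values `"anterior"`,
#'   `"posterior"`, or `NA`.
#' @export
half_labels <- function(annotation, extent = attr(annotation, "extent")) {
  labels <- rep(NA_character_, extent)
  for (i in seq_len(nrow(annotation))) {
    labels[annotation$anterior_start[i]:annotation$anterior_end[i]] <- "anterior"
    labels[annotation$posterior_start[i]:annotation$posterior_end[i]] <- "posterior"
  }
  labels
}
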