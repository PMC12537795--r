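# Columnar field geometry: mesocolumns within macrocolumns, contextual rings,
# and the evaluation ring, all expressed as RF-center offsets in image pixels.
#
# The field has 19 macrocolumns: a central one, an inner ring of 6 at 60-degree
# steps, and an outer ring of 12 at 30-degree steps. Each macrocolumn holds 7
# mesocolumns: one central plus 6 shifted by meso_shift in 60-degree-spaced
# directions. Contextual input to the central mesocolumn comes from the
# central mesocolumn of each of the 18 surrounding macrocolumns. An
# additional evaluation ring of 12 mesocolumns sits at eval_ring_shift, far
# enough that RFs do not overlap the central one.

ring_offsets <- function(n, radius, phase_deg = 0) {
  ang <- (phase_deg + 360 * (0:(n - 1)) / n) * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang))
}

#' Build the columnar field layout
#'
#' @param meso_shift shift of the 6 surrounding mesocolumns within a
#'   macrocolumn, pixels (default 3).
#' @param inner_ring_shift radius of the inner ring of 6 macrocolumns
#'   (default 9).
#' @param outer_ring_shift radius of the outer ring of 12 macrocolumns
#'   (default 18).
#' @param eval_ring_shift radius of the 12-mesocolumn evaluation ring
#'   (default 21, the L3 RF diameter, giving abutting but non-overlapping
#'   RFs).
#' @return an object of class `field_layout`: data.frame `units` with one row
#'   per mesocolumn window (columns macro, meso, role, x, y) plus the shift
#'   parameters as attributes. Roles: "central" (the central macrocolumn's 7
#'   mesocolumns), "context" (7 mesocolumns of each of the 18 surrounding
#'   macrocolumns; their central mesocolumn carries `is_context_center`), and
#'   "eval" (7 windows for each of the 12 evaluation-ring mesocolumns).
#' @export
build_field <- function(meso_shift = 3, inner_ring_shift = 9,
                        outer_ring_shift = 18, eval_ring_shift = 21) {
  if (min(meso_shift, inner_ring_shift, outer_ring_shift,
          eval_ring_shift) <= 0) stop("shifts must be positive")
  meso_local <- rbind(c(0, 0), ring_offsets(6, meso_shift))
  macro_centers <- rbind(
    c(0, 0),
    ring_offsets(6, inner_ring_shift),
    ring_offsets(12, outer_ring_shift))
  macro_role <- c("central", rep("context", 18))
  units <- do.call(rbind, lapply(seq_len(nrow(macro_centers)), function(m) {
    data.frame(macro = m, meso = 1:7, role = macro_role[m],
               x = macro_centers[m, 1] + meso_local[, 1],
               y = macro_centers[m, 2] + meso_local[, 2],
               is_context_center = macro_role[m] == "context" & (1:7) == 1)
  }))
  eval_centers <- ring_offsets(12, eval_ring_shift)
  eval_units <- do.call(rbind, lapply(1:12, function(m) {
    data.frame(macro = 19 + m, meso = 1:7, role = "eval",
               x = eval_centers[m, 1] + meso_local[, 1],
               y = eval_centers[m, 2] + meso_local[, 2],
               is_context_center = FALSE)
  }))
  units <- rbind(units, eval_units)
  rownames(units) <- NULL
  structure(list(units = units,
                 macro_centers = macro_centers,
                 eval_centers = eval_centers,
                 meso_local = meso_local),
            class = "field_layout",
            meso_shift = meso_shift, inner_ring_shift = inner_ring_shift,
            outer_ring_shift = outer_ring_shift,
            eval_ring_shift = eval_ring_shift)
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf(
    "<field_layout: %d macrocolumns + %d eval-ring mesocolumns, %d windows>\n",
    nrow(x$macro_centers), nrow(x$eval_centers), nrow(x$units)))
  invisible(x)
}

#' Number of macrocolumns in the modeled field
#' @param layout a [build_field()] layout.
#' @return integer count (19 at defaults).
#' @export
n_macrocolumns <- function(layout) nrow(layout$macro_centers)

#' Ids of the context mesocolumns
#'
#' The central mesocolumn of each of the 18 surrounding macrocolumns; these
#' supply the contextual (apical) input to the central mesocolumn's L3 cells.
#'
#' @param layout a [build_field()] layout.
#' @return integer row indices into `layout$units`.
#' @export
context_ids <- function(layout) which(layout$units$is_context_center)

#' Window center of one layout unit in image coordinates
#'
#' @param layout a [build_field()] layout.
#' @param unit_id row index into `layout$units`.
#' @param image_anchor 2-vector (x, y): where the field center is placed.
#' @return 2-vector (x, y).
#' @export
window_of <- function(layout, unit_id, image_anchor = c(0, 0)) {
  if (unit_id < 1 || unit_id > nrow(layout$units)) {
    stop("unknown unit id: ", unit_id)
  }
  c(image_anchor[1] + layout$units$x[unit_id],
    image_anchor[2] + layout$units$y[unit_id])
}

#' Window ids of one macrocolumn
#'
#' Row indices (into `layout$units`) of the 7 mesocolumn windows of
#' macrocolumn `macro`: the central mesocolumn first, then the 6 neighbors in
#' fixed angular order. The ordering is identical for every macrocolumn so
#' flattened afferent vectors are comparable across columns.
#'
#' @param layout a [build_field()] layout.
#' @param macro macrocolumn index (1 = central, 2-7 inner ring, 8-19 outer
#'   ring, 20-31 evaluation ring).
#' @return integer vector of 7 row indices.
#' @export
macro_unit_ids <- function(layout, macro) {
  which(layout$units$macro == macro)
}

#' Export the layout as CSV
#' @param layout a [build_field()] layout.
#' @param path output path (columns macro, meso, role, x, y).
#' @return invisibly, the path.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout$units, path, row.names = FALSE)
  invisible(path)
}
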