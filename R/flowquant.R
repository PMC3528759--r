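# ROI-based CSF flow quantification at the nine axial comparison levels:
# flow waveforms by pixelwise velocity integration, peak thru-plane systolic
# (caudal, negative) and diastolic (cranial, positive) velocities, stroke
# volume, and the vascular-pixel exclusion rule based on flow direction
# never changing over the cardiac cycle.

#' Axial-plane region of interest
#'
#' @param mask 2D logical matrix (`nx x ny`), non-empty.
#' @param z_index Voxel slice index the ROI lives on.
#' @param level_label Axial level.
#' @param pixel_area Pixel area in mm^2.
#' @param shape_kind `"ring"` (tips of the cuff touching) or `"cuff"`.
#' @export
axial_plane_roi <- function(mask, z_index, level_label, pixel_area,
                            shape_kind = c("ring", "cuff")) {
  shape_kind <- match.arg(shape_kind)
  stopifnot(is.matrix(mask), is.logical(mask), pixel_area > 0)
  if (!any(mask)) stop("ROI mask is empty")
  level_label <- match.arg(level_label, SECTION_LEVELS)
  structure(list(level_label = level_label, z_index = as.integer(z_index),
                 mask = mask, shape_kind = shape_kind,
                 pixel_area = pixel_area),
            class = "axial_plane_roi")
}

#' Rasterise an ROI from the geometry at a named level
#'
#' Marks voxel centres lying in the annular gap (between cord and dura) of
#' the section at the level's axial position; inclusion interiors are kept,
#' as an in-vivo reader tracing around the cord cannot exclude structures
#' below image resolution. The `"cuff"` variant removes a thin posterior
#' wedge where the two tips of the traced cuff meet.
#'
#' @param field A `velocity_field_4d` (supplies the voxel lattice).
#' @param geometry The `sss_geometry`.
#' @param level_label Level to quantify.
#' @param shape_kind `"ring"` or `"cuff"`.
#' @return An [axial_plane_roi()].
#' @export
roi_from_geometry <- function(field, geometry, level_label,
                              shape_kind = c("ring", "cuff")) {
  shape_kind <- match.arg(shape_kind)
  sec <- get_section(geometry, level_label)
  z_index <- which.min(abs(field$zs - sec$z_position))
  gx <- rep(field$xs, times = length(field$ys))
  gy <- rep(field$ys, each = length(field$xs))
  m <- points_in_polygon(gx, gy, sec$outer_contour) &
    !points_in_polygon(gx, gy, sec$inner_contour)
  if (shape_kind == "cuff") {
    c0 <- polygon_centroid(sec$inner_contour)
    th <- atan2(gy - c0[2L], gx - c0[1L])       # posterior = -y = -pi/2
    m <- m & !(abs(th + pi / 2) < 0.06)
  }
  axial_plane_roi(matrix(m, length(field$xs), length(field$ys)),
                  z_index, level_label, field$voxel_size^2, shape_kind)
}

roi_vz <- function(field, roi) {
  # n_pixels x n_phases matrix of thru-plane velocities inside the mask
  vz <- field$components$z[, , roi$z_index, , drop = FALSE]
  dim(vz) <- c(prod(field$dims[1:2]), field$cycle$n_phases)
  vz[as.vector(roi$mask), , drop = FALSE]
}

#' Integrate pixel velocities within an ROI into a flow waveform
#'
#' `Q(t_k) = sum_(pixels in mask) v_z * pixel_area`, converted to mL/s.
#'
#' @param field A `velocity_field_4d`.
#' @param roi An [axial_plane_roi()].
#' @return A `flow_waveform` (offset not applied).
#' @export
integrate_roi_flow <- function(field, roi) {
  v <- roi_vz(field, roi)                        # cm/s
  q <- colSums(v) * 10 * roi$pixel_area / 1000   # mm^3/s -> mL/s
  flow_waveform(q, field$cycle, roi$level_label)
}

#' Peak thru-plane systolic and diastolic velocities in an ROI
#'
#' Systolic is the most caudal (most negative) velocity over all mask
#' pixels and phases, diastolic the most cranial (most positive); when no
#' negative (resp. positive) velocity exists the corresponding peak is 0.
#'
#' @inheritParams integrate_roi_flow
#' @return Named vector `c(systolic = , diastolic = )` in cm/s.
#' @export
peak_velocities <- function(field, roi) {
  v <- roi_vz(field, roi)
  c(systolic = min(0, min(v)), diastolic = max(0, max(v)))
}

#' Remove vascular pixels from an ROI by flow-direction constancy
#'
#' Blood flow does not change direction over the cardiac cycle (venous
#' caudal, arterial cranial) whereas CSF alternates between caudal systolic
#' and cranial diastolic flow; pixels whose velocity magnitude exceeds
#' `magnitude_floor` and whose sign never changes are therefore excluded.
#'
#' @inheritParams integrate_roi_flow
#' @param magnitude_floor Minimum peak |v| (cm/s) for exclusion; defaults to
#'   `0.2 * venc`.
#' @return The pruned [axial_plane_roi()].
#' @export
exclude_vascular_pixels <- function(field, roi,
                                    magnitude_floor = 0.2 * field$venc) {
  stopifnot(field$cycle$n_phases >= 2L)
  v <- roi_vz(field, roi)
  high <- apply(abs(v), 1L, max) >= magnitude_floor
  constant_sign <- apply(v, 1L, function(row) all(row > 0) || all(row < 0))
  drop <- high & constant_sign
  keep <- which(roi$mask)[!drop]
  if (length(keep) == 0L) {
    stop("vascular exclusion removed every ROI pixel (over-pruning)")
  }
  m <- roi$mask & FALSE
  m[keep] <- TRUE
  axial_plane_roi(m, roi$z_index, roi$level_label, roi$pixel_area,
                  roi$shape_kind)
}

#' Quantify one axial level: waveform, offset, peaks, stroke volume
#'
#' Convenience wrapper running the full per-level MRI-arm quantification:
#' optional vascular exclusion, flow integration, zero-net-flow offset,
#' peak velocities and stroke volume (computed from the offset waveform).
#'
#' @inheritParams integrate_roi_flow
#' @param exclude_vascular Apply [exclude_vascular_pixels()] first.
#' @return List with `roi`, `waveform` (raw), `waveform_offset`, and
#'   `metrics` (one-row data.frame, `method = "mri"`).
#' @export
quantify_level <- function(field, roi, exclude_vascular = FALSE) {
  if (exclude_vascular) roi <- exclude_vascular_pixels(field, roi)
  wf <- integrate_roi_flow(field, roi)
  wfo <- offset_to_zero_net(wf)
  pk <- peak_velocities(field, roi)
  metrics <- data.frame(
    level_label = roi$level_label, method = "mri",
    peak_systolic = pk[["systolic"]], peak_diastolic = pk[["diastolic"]],
    stroke_volume = stroke_volume(wfo),
    offset_mL_s = wfo$applied_offset_value,
    offset_cm_s = wfo$applied_offset_value * 100 /
      (sum(roi$mask) * roi$pixel_area),  # flow offset over ROI area, cm/s
    stringsAsFactors = FALSE)
  list(roi = roi, waveform = wf, waveform_offset = wfo, metrics = metrics)
}
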