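# Parametric cervical spinal subarachnoid space (SSS) geometry.
#
# A geometry is an ordered stack (caudal -> cranial, increasing z) of planar
# annular cross-sections: dura outer contour, spinal-cord inner contour and
# optional inclusion polygons standing in for nerve roots / denticulate
# ligaments. Coordinates are mm; anterior is +y, cranial is +z.

SSS_LEVELS <- c("FM", "C1", "C2M", "C2P", "C3", "C4", "C5", "C6", "C7")
SECTION_LEVELS <- c(SSS_LEVELS, "INLET")

# caudal-to-cranial ordering used for tie-breaks ("more caudal" = smaller rank)
level_rank <- function(level) match(level, rev(c(SSS_LEVELS, "INLET")))

#' Construct and validate an SSS cross-section
#'
#' @param level_label One of FM, C1, C2M, C2P, C3, C4, C5, C6, C7, INLET.
#' @param z_position Axial position in mm (cranial positive).
#' @param outer_contour,inner_contour Closed simple polygons (n x 2, mm);
#'   the inner contour (spinal cord) must lie strictly inside the outer
#'   contour (dura).
#' @param inclusions Optional list of closed polygons inside the annular gap
#'   (nerve-root / ligament stand-ins), mutually disjoint.
#' @return Object of class `sss_section` with the luminal area
#'   (outer minus inner minus inclusions) precomputed.
#' @export
cross_section <- function(level_label, z_position, outer_contour, inner_contour,
                          inclusions = list()) {
  level_label <- match.arg(level_label, SECTION_LEVELS)
  outer <- ensure_ccw(outer_contour)
  inner <- ensure_ccw(inner_contour)
  if (!polygon_is_simple(outer)) stop("outer contour is self-intersecting")
  if (!polygon_is_simple(inner)) stop("inner contour is self-intersecting")
  if (!all(points_in_polygon(inner[, 1L], inner[, 2L], outer))) {
    stop("inner contour must lie strictly inside the outer contour")
  }
  inclusions <- lapply(inclusions, ensure_ccw)
  for (inc in inclusions) {
    if (!polygon_is_simple(inc)) stop("inclusion contour is self-intersecting")
    inside_outer <- all(points_in_polygon(inc[, 1L], inc[, 2L], outer))
    outside_inner <- !any(points_in_polygon(inc[, 1L], inc[, 2L], inner))
    if (!inside_outer || !outside_inner) {
      stop("inclusions must lie inside the annular gap")
    }
  }
  if (length(inclusions) > 1L) {
    for (i in seq_len(length(inclusions) - 1L)) {
      for (j in (i + 1L):length(inclusions)) {
        a <- inclusions[[i]]; b <- inclusions[[j]]
        if (any(points_in_polygon(a[, 1L], a[, 2L], b)) ||
            any(points_in_polygon(b[, 1L], b[, 2L], a))) {
          stop("inclusions must be mutually disjoint")
        }
      }
    }
  }
  area <- polygon_area(outer) - polygon_area(inner) -
    sum(vapply(inclusions, polygon_area, numeric(1)))
  if (area <= 0) stop("luminal area must be positive")
  structure(
    list(level_label = level_label, z_position = as.numeric(z_position),
         outer_contour = outer, inner_contour = inner,
         inclusions = inclusions, luminal_area = area),
    class = "sss_section")
}

#' Luminal cross-sectional area
#'
#' Area of the CSF lumen: outer contour minus inner contour minus inclusions,
#' each by the shoelace formula.
#'
#' @param section An `sss_section`.
#' @return Area in mm^2.
#' @export
section_area <- function(section) {
  stopifnot(inherits(section, "sss_section"))
  section$luminal_area
}

#' Assemble a validated SSS geometry from a list of sections
#'
#' @param sections List of `sss_section`, any order; sorted by z internally.
#' @param subject_class `"healthy_like"` or `"cm_like"`.
#' @param stenosis_severity Fractional area reduction applied near the
#'   foramen magnum for `cm_like` geometries, in `[0, 1]`.
#' @param caudal_extension_length Length (mm) of the inlet extension below C7.
#' @return Object of class `sss_geometry`.
#' @export
sss_geometry <- function(sections, subject_class = c("healthy_like", "cm_like"),
                         stenosis_severity = 0, caudal_extension_length = 50) {
  subject_class <- match.arg(subject_class)
  stopifnot(all(vapply(sections, inherits, logical(1), "sss_section")))
  z <- vapply(sections, `[[`, numeric(1), "z_position")
  sections <- sections[order(z)]
  z <- sort(z)
  if (any(diff(z) <= 0)) stop("section z positions must be strictly increasing")
  structure(
    list(sections = sections, subject_class = subject_class,
         stenosis_severity = as.numeric(stenosis_severity),
         caudal_extension_length = as.numeric(caudal_extension_length)),
    class = "sss_geometry")
}

#' @export
print.sss_geometry <- function(x, ...) {
  cat(sprintf("<sss_geometry> %s, %d sections, stenosis severity %.2f\n",
              x$subject_class, length(x$sections), x$stenosis_severity))
  a <- vapply(x$sections, section_area, numeric(1))
  lv <- vapply(x$sections, `[[`, character(1), "level_label")
  cat(sprintf("  z %.0f..%.0f mm; luminal area %.1f..%.1f mm^2 (FM: %.1f)\n",
              min(vapply(x$sections, `[[`, numeric(1), "z_position")),
              max(vapply(x$sections, `[[`, numeric(1), "z_position")),
              min(a), max(a), a[match("FM", lv)]))
  invisible(x)
}

get_section <- function(geometry, level) {
  lv <- vapply(geometry$sections, `[[`, character(1), "level_label")
  i <- match(level, lv)
  if (is.na(i)) stop(sprintf("level '%s' not present in geometry", level))
  geometry$sections[[i]]
}

#' Laplacian smoothing configuration
#'
#' @param iterations Non-negative integer; 0 iterations is the identity.
#' @param relaxation_factor Step toward the neighbour mean, in (0, 1].
#' @export
smoothing_config <- function(iterations = 10L, relaxation_factor = 0.5) {
  iterations <- as.integer(iterations)
  stopifnot(is.finite(iterations), iterations >= 0L,
            is.finite(relaxation_factor),
            relaxation_factor > 0, relaxation_factor <= 1)
  structure(list(iterations = iterations,
                 relaxation_factor = relaxation_factor),
            class = "smoothing_config")
}

#' Laplacian smoothing of a closed contour
#'
#' Each iteration moves every vertex toward the mean of its two neighbours by
#' the relaxation factor; the analogue for contours of the mesh smoothing
#' applied to segmented surfaces before CFD meshing.
#'
#' @param contour Closed simple polygon (>= 4 vertices).
#' @param config A [smoothing_config()].
#' @return Smoothed polygon; remains closed and simple.
#' @export
laplacian_smooth <- function(contour, config = smoothing_config()) {
  xy <- as_polygon(contour)
  if (nrow(xy) < 4L) stop("contour needs at least 4 vertices")
  if (polygon_area(xy) <= .Machine$double.eps) stop("degenerate (zero-area) contour")
  lam <- config$relaxation_factor
  for (it in seq_len(config$iterations)) {
    prev <- rbind(xy[nrow(xy), ], xy[-nrow(xy), , drop = FALSE])
    nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, ])
    xy <- xy + lam * ((prev + nxt) / 2 - xy)
  }
  if (!polygon_is_simple(xy)) stop("smoothing produced a self-intersecting contour")
  xy
}

#' Default template parameters for the parametric cervical geometry
#'
#' Elliptical cord inside an elliptical dura, cord set slightly posterior so
#' the anterior gap is wider; vertebral-level z spacing approximates a
#' cervical spine. Values are generator defaults, not anatomical claims.
#'
#' @param outer_semi_axes,cord_semi_axes Ellipse semi-axes (mm).
#' @param cord_offset_y Posterior (negative y) offset of the cord centre (mm).
#' @param n_vertices Vertices per contour.
#' @param perturb_amplitude SD-like amplitude (mm) of the smooth seeded radial
#'   perturbation that differentiates subjects.
#' @param perturb_modes Highest angular mode of the perturbation.
#' @param nerve_root_radius Radius (mm) of the paired lateral nerve-root
#'   inclusions placed at C2P to C7.
#' @param level_z Named numeric vector of axial positions (mm).
#' @param caudal_extension_length Inlet extension below C7 (mm).
#' @param smoothing A [smoothing_config()].
#' @export
sss_template <- function(outer_semi_axes = c(9, 8),
                         cord_semi_axes = c(4.5, 3.5),
                         cord_offset_y = -0.8,
                         n_vertices = 64L,
                         perturb_amplitude = 0.15,
                         perturb_modes = 3L,
                         nerve_root_radius = 0.8,
                         level_z = c(C7 = 0, C6 = 16, C5 = 32, C4 = 48,
                                     C3 = 64, C2P = 78, C2M = 88, C1 = 100,
                                     FM = 112),
                         caudal_extension_length = 50,
                         smoothing = smoothing_config()) {
  stopifnot(all(outer_semi_axes > 0), all(cord_semi_axes > 0),
            all(SSS_LEVELS %in% names(level_z)))
  as.list(environment())
}

# smooth seeded radial perturbation of an ellipse contour
perturbed_ellipse <- function(a, b, centre, n, amp, modes) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- 1
  if (amp > 0 && modes > 0L) {
    for (k in seq_len(modes)) {
      r <- r + amp / modes * (stats::rnorm(1) * cos(k * th) +
                              stats::rnorm(1) * sin(k * th)) /
        sqrt(max(a, b))
    }
  }
  cbind(centre[1L] + r * a * cos(th), centre[2L] + r * b * sin(th))
}

# blend outer toward inner (vertex-wise, matching theta parameterisation)
# until the plain annulus area hits `target`
narrow_outer_to_area <- function(outer, inner, target) {
  area_at <- function(t) {
    polygon_area(inner + t * (outer - inner)) - polygon_area(inner) - target
  }
  t <- stats::uniroot(area_at, lower = 1e-3, upper = 1, tol = 1e-10,
                      extendInt = "no")$root
  inner + t * (outer - inner)
}

#' Generate a parametric cervical SSS geometry
#'
#' Stands in for manual segmentation of subject anatomy: nine labelled
#' cervical sections (FM down to C7) plus a caudal inlet extension.
#' `cm_like` geometries narrow the annular gap over the FM-C1 span so that
#' the FM luminal area equals the healthy template area scaled by
#' `1 - stenosis_severity`. Deterministic for a fixed seed.
#'
#' @param template_params See [sss_template()].
#' @param subject_class `"healthy_like"` or `"cm_like"`.
#' @param stenosis_severity Fractional FM area reduction in `[0, 1]`
#'   (only used for `cm_like`).
#' @param seed Integer seed for the subject-specific contour perturbations.
#' @return An `sss_geometry`.
#' @export
make_geometry <- function(template_params = sss_template(),
                          subject_class = c("healthy_like", "cm_like"),
                          stenosis_severity = 0, seed = 1L) {
  subject_class <- match.arg(subject_class)
  tp <- template_params
  stopifnot(stenosis_severity >= 0, stenosis_severity <= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)

  healthy_fm_area <- pi * prod(tp$outer_semi_axes) - pi * prod(tp$cord_semi_axes)
  lv_order <- names(sort(tp$level_z))  # caudal -> cranial
  sections <- vector("list", length(lv_order) + 1L)

  # inlet extension: clean (unperturbed) copy of the C7 template
  inlet_z <- tp$level_z[["C7"]] - tp$caudal_extension_length
  sections[[1L]] <- cross_section(
    "INLET", inlet_z,
    ellipse_polygon(tp$outer_semi_axes[1L], tp$outer_semi_axes[2L], tp$n_vertices),
    ellipse_polygon(tp$cord_semi_axes[1L], tp$cord_semi_axes[2L], tp$n_vertices,
                    centre = c(0, tp$cord_offset_y)))

  for (i in seq_along(lv_order)) {
    lev <- lv_order[i]
    outer <- perturbed_ellipse(tp$outer_semi_axes[1L], tp$outer_semi_axes[2L],
                               c(0, 0), tp$n_vertices,
                               tp$perturb_amplitude, tp$perturb_modes)
    inner <- perturbed_ellipse(tp$cord_semi_axes[1L], tp$cord_semi_axes[2L],
                               c(0, tp$cord_offset_y), tp$n_vertices,
                               tp$perturb_amplitude, tp$perturb_modes)
    outer <- laplacian_smooth(outer, tp$smoothing)
    inner <- laplacian_smooth(inner, tp$smoothing)

    if (subject_class == "cm_like" && stenosis_severity > 0 &&
        lev %in% c("FM", "C1")) {
      # full severity at the FM, partial at C1: pin the annulus area to the
      # unperturbed healthy template area scaled by (1 - sev)
      sev <- if (lev == "FM") stenosis_severity else 0.6 * stenosis_severity
      target <- healthy_fm_area * (1 - sev)
      outer <- narrow_outer_to_area(outer, inner, target)
    }

    inclusions <- list()
    if (lev %in% c("C2P", "C3", "C4", "C5", "C6", "C7") &&
        (subject_class != "cm_like" || !lev %in% c("FM", "C1"))) {
      # paired lateral nerve-root stand-ins at mid-gap
      mid <- (tp$outer_semi_axes[1L] + tp$cord_semi_axes[1L]) / 2
      jit <- stats::runif(2L, -0.3, 0.3)
      inclusions <- list(
        circle_polygon(tp$nerve_root_radius, 24L, centre = c(-mid, jit[1L])),
        circle_polygon(tp$nerve_root_radius, 24L, centre = c(mid, jit[2L])))
    }
    sections[[i + 1L]] <- cross_section(lev, tp$level_z[[lev]], outer, inner,
                                        inclusions)
  }
  sss_geometry(sections, subject_class, stenosis_severity,
               tp$caudal_extension_length)
}

#' Interpolate a cross-section at an arbitrary axial position
#'
#' Outer and inner contours are interpolated linearly (vertex-wise) between
#' the bracketing sections; inclusions are taken from the nearest stored
#' section. Errors outside the geometry's z range.
#'
#' @param geometry An `sss_geometry`.
#' @param z Axial position (mm).
#' @return An `sss_section` (level label of the nearest stored section).
#' @export
section_at_z <- function(geometry, z) {
  zs <- vapply(geometry$sections, `[[`, numeric(1), "z_position")
  if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9) {
    stop(sprintf("z = %.2f mm outside the geometry range [%.2f, %.2f]",
                 z, min(zs), max(zs)))
  }
  z <- min(max(z, min(zs)), max(zs))
  i <- findInterval(z, zs, rightmost.closed = TRUE)
  lo <- geometry$sections[[i]]
  hi <- geometry$sections[[min(i + 1L, length(zs))]]
  if (identical(lo, hi) || hi$z_position == lo$z_position) return(lo)
  f <- (z - lo$z_position) / (hi$z_position - lo$z_position)
  if (nrow(lo$outer_contour) != nrow(hi$outer_contour)) {
    stop("sections must share vertex counts for interpolation")
  }
  near <- if (f < 0.5) lo else hi
  cross_section(near$level_label, z,
                (1 - f) * lo$outer_contour + f * hi$outer_contour,
                (1 - f) * lo$inner_contour + f * hi$inner_contour,
                near$inclusions)
}

# a copy of the geometry with inclusions removed (the CFD-arm view that
# mirrors segmentation without fine anatomical structures)
strip_inclusions <- function(geometry) {
  geometry$sections <- lapply(geometry$sections, function(s) {
    cross_section(s$level_label, s$z_position, s$outer_contour,
                  s$inner_contour, list())
  })
  geometry
}

#' Well-Known-Text export of a cross-section
#'
#' Lumen as a POLYGON with the cord and any inclusions as holes.
#'
#' @param section An `sss_section`.
#' @return Single WKT string.
#' @export
section_wkt <- function(section) {
  ring <- function(xy) {
    xy <- rbind(xy, xy[1L, ])
    paste0("(", paste(sprintf("%.6f %.6f", xy[, 1L], xy[, 2L]), collapse = ", "), ")")
  }
  holes <- c(list(section$inner_contour), section$inclusions)
  paste0("POLYGON (", paste(c(ring(section$outer_contour),
                              vapply(holes, ring, character(1))),
                            collapse = ", "), ")")
}

#' Write / read an SSS geometry as JSON
#'
#' Vertices are stored at full double precision so a write/read round trip
#' reproduces coordinates bit-exactly.
#'
#' @param geometry An `sss_geometry`.
#' @param path Output file.
#' @return `write_geometry_json` returns `path` invisibly;
#'   `read_geometry_json` returns an `sss_geometry`.
#' @export
write_geometry_json <- function(geometry, path) {
  obj <- list(
    subject_class = geometry$subject_class,
    stenosis_severity = geometry$stenosis_severity,
    caudal_extension_length = geometry$caudal_extension_length,
    sections = lapply(geometry$sections, function(s) list(
      level_label = s$level_label, z_position = s$z_position,
      outer_contour = s$outer_contour, inner_contour = s$inner_contour,
      inclusions = s$inclusions)))
  # I(17) significant digits makes the write/read round trip bit-exact
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  secs <- lapply(seq_len(nrow_df(obj$sections)), function(i) {
    s <- row_of(obj$sections, i)
    cross_section(s$level_label, s$z_position, s$outer_contour,
                  s$inner_contour, s$inclusions %||% list())
  })
  sss_geometry(secs, obj$subject_class, obj$stenosis_severity,
               obj$caudal_extension_length)
}

# jsonlite may simplify the section list into a data.frame-like list; these
# helpers read rows uniformly from either shape
nrow_df <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
row_of <- function(x, i) {
  if (is.data.frame(x)) {
    s <- lapply(x, function(col) if (is.list(col)) col[[i]] else col[i])
  } else {
    s <- x[[i]]
  }
  inc <- s$inclusions
  s$inclusions <- if (is.null(inc) || length(inc) == 0L) list()
    else if (is.matrix(inc)) list(inc)
    else if (is.array(inc) && length(dim(inc)) == 3L) {
      # several same-sized inclusions simplified into one k x n x 2 array
      lapply(seq_len(dim(inc)[1L]), function(k) inc[k, , ])
    } else inc
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the extruded geometry as a legacy-VTK polyline file
#'
#' Writes section contours stacked at their axial positions as POLYDATA
#' lines, loadable by VTK-compatible viewers.
#'
#' @param geometry An `sss_geometry`.
#' @param path Output `.vtk` file.
#' @export
write_geometry_vtk <- function(geometry, path) {
  pts <- list(); lines <- list(); off <- 0L
  for (s in geometry$sections) {
    for (xy in c(list(s$outer_contour, s$inner_contour), s$inclusions)) {
      n <- nrow(xy)
      pts[[length(pts) + 1L]] <- cbind(xy, s$z_position)
      lines[[length(lines) + 1L]] <- c(n + 1L, off + seq_len(n) - 1L, off)
      off <- off + n
    }
  }
  P <- do.call(rbind, pts)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sss geometry contours", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(P))), con)
  utils::write.table(P, con, row.names = FALSE, col.names = FALSE)
  nums <- vapply(lines, length, integer(1))
  writeLines(sprintf("LINES %d %d", length(lines), sum(nums)), con)
  for (l in lines) writeLines(paste(l, collapse = " "), con)
  invisible(path)
}
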