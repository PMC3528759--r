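# Forward simulation of 4D phase-contrast MRI CSF velocity data.
#
# A ground-truth velocity model is built on top of an SSS geometry and a
# prescribed flow waveform: a smooth in-gap axial profile, anterior-weighted,
# damped near nerve-root inclusions, with an optional stenotic jet for
# Chiari-like geometries, rescaled per slice so its areal integral matches
# the waveform. The encoder then samples it at voxel centres and applies
# the phase-contrast measurement map: phase = pi*v/VENC, additive phase
# noise, wrap-around to [-pi, pi), back to velocity, so velocities beyond
# +/-VENC alias exactly as in vivo. In-plane true velocity components are
# zero in this model; only noise appears there after encoding.

#' Phase-contrast MRI simulation configuration
#'
#' @param venc Velocity-encoding limit (cm/s); 10 is typical for healthy
#'   subjects, 20 for patients.
#' @param voxel_size Isotropic voxel size (mm).
#' @param noise_sd_phase SD of the additive phase noise (rad); the resulting
#'   velocity noise SD is `venc * noise_sd_phase / pi`.
#' @param include_vascular_confounders Insert small unidirectional
#'   high-velocity vascular regions outside the lumen near the foramen
#'   magnum.
#' @param nerve_root_deficit_factor Fractional velocity reduction near
#'   nerve-root inclusions, in `[0, 1]`.
#' @param nerve_root_sigma Gaussian length scale (mm) of the deficit
#'   neighbourhood.
#' @param anterior_weight Anterior-to-posterior weighting (>= 1) of the
#'   ground-truth profile; 1 is symmetric.
#' @param jet_peak_factor For `cm_like` geometries, the stenotic jet peak as
#'   a multiple of the section-mean profile.
#' @param velocity_offset_cm_s Constant thru-plane velocity bias (cm/s)
#'   added by the encoder across the image, emulating the residual
#'   eddy-current background offset that makes in-vivo net flow per cycle
#'   nonzero before the zero-net offset is applied.
#' @param seed Integer seed for the encoding noise.
#' @export
pcmri_config <- function(venc = 10, voxel_size = 1.5, noise_sd_phase = 0.1,
                         include_vascular_confounders = FALSE,
                         nerve_root_deficit_factor = 0.5,
                         nerve_root_sigma = 0.8,
                         anterior_weight = 2, jet_peak_factor = 2.5,
                         velocity_offset_cm_s = 0,
                         seed = 1L) {
  stopifnot(venc > 0, voxel_size > 0, noise_sd_phase >= 0,
            nerve_root_deficit_factor >= 0, nerve_root_deficit_factor <= 1,
            anterior_weight >= 1, jet_peak_factor >= 1)
  structure(list(venc = venc, voxel_size = voxel_size,
                 noise_sd_phase = noise_sd_phase,
                 include_vascular_confounders =
                   isTRUE(include_vascular_confounders),
                 nerve_root_deficit_factor = nerve_root_deficit_factor,
                 nerve_root_sigma = nerve_root_sigma,
                 anterior_weight = anterior_weight,
                 jet_peak_factor = jet_peak_factor,
                 velocity_offset_cm_s = velocity_offset_cm_s,
                 seed = as.integer(seed)),
            class = "pcmri_config")
}

# static profile shape of one slice: returns list(fun(x, y) -> shape [mm],
# norm [mm^3]) with norm the quadrature integral of the shape over the slice,
# so that v_z = shape/norm * Q gives areal flux Q exactly on that grid
slice_shape <- function(geometry, z, config, quad_mm = 0.1) {
  sec <- section_at_z(geometry, z)
  contours <- c(list(sec$outer_contour, sec$inner_contour), sec$inclusions)
  ybb <- range(sec$outer_contour[, 2L])

  jet <- NULL
  zs <- vapply(geometry$sections, `[[`, numeric(1), "z_position")
  lv <- vapply(geometry$sections, `[[`, character(1), "level_label")
  if (geometry$subject_class == "cm_like" && "C1" %in% lv &&
      z >= zs[match("C1", lv)]) {
    c0 <- polygon_centroid(sec$inner_contour)
    dir <- c(cos(pi / 4), sin(pi / 4))          # anterolateral
    d_in <- ray_boundary_distance(c0, dir, list(sec$inner_contour), 50)
    d_out <- ray_boundary_distance(c0, dir, list(sec$outer_contour), 50)
    jet <- list(centre = c0 + dir * (d_in + d_out) / 2, sigma = 1.2)
  }

  base_shape <- function(x, y) {
    inside <- points_in_polygon(x, y, sec$outer_contour) &
      !points_in_polygon(x, y, sec$inner_contour)
    for (inc in sec$inclusions) inside <- inside & !points_in_polygon(x, y, inc)
    s <- numeric(length(x))
    if (!any(inside)) return(s)
    xi <- x[inside]; yi <- y[inside]
    d <- dist_to_polygon(xi, yi, sec$outer_contour)
    d <- pmin(d, dist_to_polygon(xi, yi, sec$inner_contour))
    for (inc in sec$inclusions) d <- pmin(d, dist_to_polygon(xi, yi, inc))
    v <- d
    if (config$anterior_weight > 1) {
      yhat <- (yi - ybb[1L]) / max(ybb[2L] - ybb[1L], 1e-9)
      v <- v * config$anterior_weight^(2 * yhat - 1)
    }
    if (config$nerve_root_deficit_factor > 0) {
      for (inc in sec$inclusions) {
        di <- dist_to_polygon(xi, yi, inc)
        v <- v * (1 - config$nerve_root_deficit_factor *
                    exp(-(di / config$nerve_root_sigma)^2))
      }
    }
    s[inside] <- v
    s
  }

  # quadrature grid for normalisation (and for placing the jet amplitude)
  bb <- apply(sec$outer_contour, 2L, range)
  qx <- seq(bb[1L, 1L], bb[2L, 1L], by = quad_mm)
  qy <- seq(bb[1L, 2L], bb[2L, 2L], by = quad_mm)
  gx <- rep(qx, times = length(qy)); gy <- rep(qy, each = length(qx))
  s0 <- base_shape(gx, gy)
  in_lum <- s0 > 0

  jet_amp <- 0
  if (!is.null(jet)) {
    gj <- exp(-((gx - jet$centre[1L])^2 + (gy - jet$centre[2L])^2) / jet$sigma^2)
    m_s <- mean(s0[in_lum]); m_g <- mean(gj[in_lum])
    peak0 <- max(s0[in_lum])
    # choose the jet amplitude so peak = jet_peak_factor * section mean
    amp <- (config$jet_peak_factor * m_s - peak0) /
      max(1 - config$jet_peak_factor * m_g, 0.1)
    jet_amp <- max(amp, 0)
    s0 <- s0 + ifelse(in_lum, jet_amp * gj, 0)
  }
  norm <- sum(s0) * quad_mm^2

  fun <- function(x, y) {
    s <- base_shape(x, y)
    if (!is.null(jet) && jet_amp > 0) {
      g <- exp(-((x - jet$centre[1L])^2 + (y - jet$centre[2L])^2) / jet$sigma^2)
      s <- s + ifelse(s > 0, jet_amp * g, 0)
    }
    s
  }
  list(fun = fun, norm = norm, section = sec, quad_mm = quad_mm)
}

#' Ground-truth CSF velocity sampler
#'
#' Continuous velocity model over the geometry: the axial component is the
#' slice profile described above scaled so each slice's areal integral
#' (midpoint quadrature at the sampler's stated resolution) equals the
#' waveform value at the queried phase; in-plane components are zero.
#'
#' @param geometry An `sss_geometry`.
#' @param waveform A `flow_waveform` (mL/s) on the acquisition cycle.
#' @param config A [pcmri_config()].
#' @param quad_mm Quadrature resolution (mm) used for slice normalisation.
#' @return A `csf_velocity_sampler`: `$sample(points, phase)` maps an n x 3
#'   matrix of positions (mm) and a phase index (1-based) to an n x 3 matrix
#'   of velocities (cm/s); `$shape(z, x, y)` exposes the static profile.
#' @export
ground_truth_velocity <- function(geometry, waveform, config = pcmri_config(),
                                  quad_mm = 0.1) {
  stopifnot(inherits(geometry, "sss_geometry"),
            inherits(waveform, "flow_waveform"))
  cache <- new.env(parent = emptyenv())
  get_slice <- function(z) {
    key <- sprintf("z%.6f", z)
    if (is.null(cache[[key]])) {
      cache[[key]] <- slice_shape(geometry, z, config, quad_mm)
    }
    cache[[key]]
  }
  sample_fun <- function(points, phase) {
    points <- matrix(points, ncol = 3L)
    stopifnot(phase >= 1L, phase <= waveform$cycle$n_phases)
    q <- waveform$samples[phase]                 # mL/s
    out <- matrix(0, nrow(points), 3L)
    for (z in unique(points[, 3L])) {
      sl <- get_slice(z)
      i <- which(points[, 3L] == z)
      s <- sl$fun(points[i, 1L], points[i, 2L])
      # shape/norm * Q: (mm / mm^3) * 1000 mm^3/s = mm/s -> /10 cm/s
      out[i, 3L] <- s / sl$norm * q * 1000 / 10
    }
    out
  }
  structure(list(sample = sample_fun,
                 shape = function(z, x, y) get_slice(z)$fun(x, y),
                 slice = get_slice,
                 geometry = geometry, waveform = waveform, config = config,
                 quad_mm = quad_mm),
            class = "csf_velocity_sampler")
}

#' Phase-contrast velocity encoding with wrap-around aliasing
#'
#' Maps velocity to phase `pi*v/venc`, adds optional phase noise, wraps to
#' `[-pi, pi)` and maps back, so stored velocities lie in `[-venc, venc)`
#' and `encode(v + 2*venc) = encode(v)`.
#'
#' @param v Velocities (cm/s).
#' @param venc Encoding limit (cm/s).
#' @param noise_phase Optional additive phase noise (rad), same length as
#'   `v` or scalar 0.
#' @return Encoded velocities (cm/s).
#' @export
encode_velocity <- function(v, venc, noise_phase = 0) {
  ph <- pi * v / venc + noise_phase
  ph <- ((ph + pi) %% (2 * pi)) - pi
  ph * venc / pi
}

#' Simulate a 4D phase-contrast acquisition
#'
#' Samples the ground-truth model at voxel centres over one cardiac cycle,
#' optionally inserts unidirectional vascular confounder regions outside the
#' lumen near the FM, and applies the VENC phase-encoding map with additive
#' Gaussian phase noise to all three components. Deterministic for a fixed
#' `config$seed`.
#'
#' @param sampler A [ground_truth_velocity()] sampler.
#' @param geometry The `sss_geometry` the sampler was built on.
#' @param config A [pcmri_config()].
#' @param cycle A [cardiac_cycle()]; must match the sampler's waveform.
#' @return A `velocity_field_4d`: component arrays (`x`, `y`, `z`) of
#'   dimension `nx x ny x nz x n_phases` in cm/s, a magnitude array, voxel
#'   geometry, plus ground-truth lumen and confounder masks for validation.
#' @export
encode_pcmri <- function(sampler, geometry, config = sampler$config,
                         cycle = sampler$waveform$cycle) {
  stopifnot(inherits(sampler, "csf_velocity_sampler"),
            cycle$n_phases == sampler$waveform$cycle$n_phases)
  vs <- config$voxel_size
  bb <- apply(do.call(rbind, lapply(geometry$sections,
                                    `[[`, "outer_contour")), 2L, range)
  zs <- range(vapply(geometry$sections, `[[`, numeric(1), "z_position"))
  pad <- 4 * vs
  x <- seq(bb[1L, 1L] - pad, bb[2L, 1L] + pad, by = vs)
  y <- seq(bb[1L, 2L] - pad, bb[2L, 2L] + pad, by = vs)
  z <- seq(zs[1L] + vs / 2, zs[2L] - vs / 2, by = vs)
  nx <- length(x); ny <- length(y); nz <- length(z); np <- cycle$n_phases

  vz_true <- array(0, c(nx, ny, nz, np))
  lumen <- array(FALSE, c(nx, ny, nz))
  gx <- rep(x, times = ny); gy <- rep(y, each = nx)
  qs <- sampler$waveform$samples
  for (k in seq_len(nz)) {
    sl <- sampler$slice(z[k])
    s <- sl$fun(gx, gy)
    lumen[, , k] <- s > 0
    scale <- s / sl$norm * 1000 / 10
    for (p in seq_len(np)) vz_true[, , k, p] <- scale * qs[p]
  }

  conf <- array(FALSE, c(nx, ny, nz))
  if (config$include_vascular_confounders) {
    fm <- get_section(geometry, "FM")
    bbx <- range(fm$outer_contour[, 1L])
    zwin <- fm$z_position - c(12, 0)
    # left vertebral-like (venous, caudal) and right (arterial, cranial)
    sites <- list(list(c(bbx[1L] - 2.0, 1.5), -1), list(c(bbx[2L] + 2.0, 1.5), +1))
    t_idx <- seq_len(np)
    for (s in sites) {
      vox <- outer((gx - s[[1L]][1L])^2 + (gy - s[[1L]][2L])^2 <= 2^2,
                   z >= zwin[1L] & z <= zwin[2L], "&")
      dim(vox) <- c(nx, ny, nz)
      conf <- conf | vox
      mag <- 0.55 * config$venc *
        (1 + 0.25 * sin(2 * pi * (t_idx - 1L) / np + s[[2L]]))
      for (p in seq_len(np)) {
        sl4 <- vz_true[, , , p]; sl4[vox] <- s[[2L]] * mag[p]
        vz_true[, , , p] <- sl4
      }
    }
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  n_all <- length(vz_true)
  noise <- function() {
    if (config$noise_sd_phase > 0) {
      stats::rnorm(n_all, 0, config$noise_sd_phase)
    } else 0
  }
  comp <- list(
    x = array(encode_velocity(0, config$venc, noise()), dim(vz_true)),
    y = array(encode_velocity(0, config$venc, noise()), dim(vz_true)),
    z = array(encode_velocity(vz_true + config$velocity_offset_cm_s,
                              config$venc, noise()), dim(vz_true)))
  magnitude <- array(rep(20 + 80 * lumen, np), dim(vz_true))

  structure(list(components = comp, magnitude = magnitude,
                 dims = c(nx, ny, nz), voxel_size = vs,
                 origin = c(x[1L], y[1L], z[1L]),
                 xs = x, ys = y, zs = z,
                 cycle = cycle, venc = config$venc,
                 lumen_mask = lumen, confounder_mask = conf,
                 seed = config$seed),
            class = "velocity_field_4d")
}

#' @export
print.velocity_field_4d <- function(x, ...) {
  cat(sprintf("<velocity_field_4d> %d x %d x %d voxels (%.2g mm), %d phases, VENC %g cm/s\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size,
              x$cycle$n_phases, x$venc))
  invisible(x)
}

#' Paired cardiac-phase anatomical images with prescribed displacement
#'
#' Builds the maximum-rostral-displacement image and its maximum-caudal
#' counterpart: a tonsil-shaped (or rectangular-block) region rigidly
#' translated caudally (toward negative y) by `displacement`, evaluated
#' analytically so sub-pixel shifts are exact, over a constant background,
#' with optional additive image noise.
#'
#' @param displacement Caudal displacement in mm (>= 0).
#' @param pattern_params List: `shape` ("tonsil" or "block"), `fov` (mm,
#'   length 2), `pixel_size` (mm), `noise_sd` (intensity units), and shape
#'   geometry (`centre`, `semi_axes` for tonsil lobes; `block_size` for the
#'   block).
#' @param seed Seed for the image noise.
#' @return A `motion_image_pair` with the ground-truth displacement
#'   recorded.
#' @export
make_motion_pair <- function(displacement,
                             pattern_params = list(), seed = 1L) {
  p <- utils::modifyList(list(shape = "tonsil", fov = c(60, 60),
                              pixel_size = 0.4, noise_sd = 1,
                              centre = c(0, 12), semi_axes = c(6, 9),
                              lobe_offset = 4, block_size = c(10, 14)),
                         pattern_params)
  stopifnot(displacement >= 0)
  if (displacement >= p$fov[2L] / 2) {
    stop("displacement exceeds the image extent")
  }
  x <- seq(-p$fov[1L] / 2 + p$pixel_size / 2, p$fov[1L] / 2, by = p$pixel_size)
  y <- seq(-p$fov[2L] / 2 + p$pixel_size / 2, p$fov[2L] / 2, by = p$pixel_size)
  gx <- rep(x, times = length(y)); gy <- rep(y, each = length(x))

  blob <- switch(p$shape,
    tonsil = function(xx, yy) {
      # two smooth lobes, caudally rounded
      l1 <- ((xx - p$lobe_offset) / (p$semi_axes[1L] / 2))^2 +
        ((yy - p$centre[2L]) / p$semi_axes[2L])^2
      l2 <- ((xx + p$lobe_offset) / (p$semi_axes[1L] / 2))^2 +
        ((yy - p$centre[2L]) / p$semi_axes[2L])^2
      100 * pmax(exp(-l1^2), exp(-l2^2))
    },
    block = function(xx, yy) {
      100 * (abs(xx) < p$block_size[1L] / 2 &
               abs(yy - p$centre[2L]) < p$block_size[2L] / 2)
    },
    stop(sprintf("unknown pattern shape '%s'", p$shape)))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  bg <- 20
  img1 <- matrix(bg + blob(gx, gy), length(x), length(y))
  img2 <- matrix(bg + blob(gx, gy + displacement), length(x), length(y))
  if (p$noise_sd > 0) {
    img1 <- img1 + matrix(stats::rnorm(length(img1), 0, p$noise_sd), nrow(img1))
    img2 <- img2 + matrix(stats::rnorm(length(img2), 0, p$noise_sd), nrow(img2))
  }
  structure(list(image_rostral = img1, image_caudal = img2,
                 pixel_size = p$pixel_size,
                 true_displacement = displacement,
                 xs = x, ys = y, pattern = p, background = bg),
            class = "motion_image_pair")
}
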