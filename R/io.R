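# On-disk formats: NIfTI-1 velocity volumes (one 4D file per component plus
# magnitude, with a JSON sidecar for VENC / timing metadata), ROI masks,
# metrics CSV, run configuration, and the seed-splitting rule that makes
# every pipeline stage independently reproducible.
#
# Unit conventions everywhere: velocity cm/s, length mm, flow mL/s.

#' Split a global seed into a stage seed
#'
#' Deterministic rule `(seed * 9973 + hash(stage)) mod (2^31 - 1)` with a
#' polynomial string hash, so every pipeline stage draws from its own
#' reproducible stream.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (string).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1e6 * 9973 + h) %% 2147483646 + 1)
}

#' Write a 4D velocity field as NIfTI component files plus JSON sidecar
#'
#' One 4D NIfTI per velocity component (`<prefix>_vx/vy/vz.nii.gz`, cm/s)
#' plus magnitude and a `<prefix>.json` sidecar recording VENC, cycle
#' timing, voxel size, origin and seed.
#'
#' @param field A `velocity_field_4d`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Named vector of the written paths, invisibly.
#' @export
write_velocity_nifti <- function(field, dir, prefix = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- field$voxel_size
  paths <- c(vx = file.path(dir, paste0(prefix, "_vx.nii.gz")),
             vy = file.path(dir, paste0(prefix, "_vy.nii.gz")),
             vz = file.path(dir, paste0(prefix, "_vz.nii.gz")),
             mag = file.path(dir, paste0(prefix, "_mag.nii.gz")),
             sidecar = file.path(dir, paste0(prefix, ".json")))
  wr <- function(arr, path) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- c(vs, vs, vs,
                            field$cycle$period_T / field$cycle$n_phases)
    RNifti::writeNifti(im, path)
  }
  wr(field$components$x, paths[["vx"]])
  wr(field$components$y, paths[["vy"]])
  wr(field$components$z, paths[["vz"]])
  wr(field$magnitude, paths[["mag"]])
  jsonlite::write_json(
    list(venc = field$venc, period_T = field$cycle$period_T,
         n_phases = field$cycle$n_phases, voxel_size = vs,
         origin = field$origin, seed = field$seed),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a 4D velocity field from NIfTI component files
#'
#' @param vx,vy,vz Paths to the three component volumes.
#' @param sidecar Path to the JSON sidecar (venc, period_T, n_phases,
#'   voxel_size, origin); required.
#' @param magnitude Optional magnitude volume path.
#' @return A `velocity_field_4d`. Errors name the offending file on shape
#'   or metadata mismatch; anisotropic voxels are rejected (the acquisition
#'   model is isotropic).
#' @export
read_velocity_nifti <- function(vx, vy, vz, sidecar, magnitude = NULL) {
  for (p in c(vx, vy, vz, sidecar)) {
    if (!file.exists(p)) stop(sprintf("missing input file '%s'", p))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("venc", "period_T", "n_phases", "voxel_size")
  if (!all(need %in% names(meta))) {
    stop(sprintf("sidecar '%s' must provide %s", sidecar,
                 paste(need, collapse = ", ")))
  }
  rd <- function(p) {
    im <- RNifti::readNifti(p)
    sp <- RNifti::pixdim(im)[1:3]
    if (max(sp) - min(sp) > 1e-6 * max(sp)) {
      stop(sprintf("'%s' has anisotropic voxels (%s); isotropic data required",
                   p, paste(signif(sp, 4), collapse = " x ")))
    }
    unclass(as.array(im))
  }
  a <- list(x = rd(vx), y = rd(vy), z = rd(vz))
  dims <- dim(a$x)
  for (nm in c("y", "z")) {
    if (!identical(dim(a[[nm]]), dims)) {
      stop(sprintf("component file '%s' shape differs from '%s'",
                   c(y = vy, z = vz)[[nm]], vx))
    }
  }
  if (length(dims) != 4L || dims[4L] != meta$n_phases) {
    stop(sprintf("'%s': expected 4D with %d phases", vx, meta$n_phases))
  }
  mag <- if (!is.null(magnitude)) rd(magnitude) else array(0, dims)
  origin <- if (!is.null(meta$origin)) as.numeric(meta$origin) else c(0, 0, 0)
  vs <- meta$voxel_size
  structure(list(components = a, magnitude = mag, dims = dims[1:3],
                 voxel_size = vs, origin = origin,
                 xs = origin[1L] + (seq_len(dims[1L]) - 1L) * vs,
                 ys = origin[2L] + (seq_len(dims[2L]) - 1L) * vs,
                 zs = origin[3L] + (seq_len(dims[3L]) - 1L) * vs,
                 cycle = cardiac_cycle(meta$period_T, meta$n_phases),
                 venc = meta$venc,
                 lumen_mask = NULL, confounder_mask = NULL,
                 seed = meta$seed %||% NA_integer_),
            class = "velocity_field_4d")
}

#' Write / read an ROI
#'
#' NIfTI label map (0/1) plus a JSON descriptor, or pure JSON with the mask
#' run-length encoded.
#'
#' @param roi An [axial_plane_roi()].
#' @param path Base path; `.nii.gz` and `.json` files are derived from it.
#' @export
write_roi <- function(roi, path) {
  nii <- sub("\\.json$", "", path)
  nii <- paste0(sub("\\.nii(\\.gz)?$", "", nii), ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(roi$mask),
                                           dim(roi$mask))), nii)
  jsonlite::write_json(
    list(level_label = roi$level_label, z_index = roi$z_index,
         shape_kind = roi$shape_kind, pixel_area = roi$pixel_area,
         mask_file = basename(nii)),
    paste0(sub("\\.nii(\\.gz)?$", "", sub("\\.json$", "", path)), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", sub("\\.json$", "", path))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  m <- unclass(as.array(RNifti::readNifti(file.path(dirname(path),
                                                    meta$mask_file))))
  axial_plane_roi(matrix(m != 0, nrow(m), ncol(m)), meta$z_index,
                  meta$level_label, meta$pixel_area, meta$shape_kind)
}

#' Write per-level flow metrics as CSV
#'
#' Frozen header: `level,method,peak_sys_cm_s,peak_dia_cm_s,sv_mL`.
#'
#' @param metrics Data frame with columns `level_label`, `method`,
#'   `peak_systolic`, `peak_diastolic`, `stroke_volume`.
#' @param path CSV file.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- data.frame(level = metrics$level_label, method = metrics$method,
                    peak_sys_cm_s = metrics$peak_systolic,
                    peak_dia_cm_s = metrics$peak_diastolic,
                    sv_mL = metrics$stroke_volume)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(seed = 1L,
       fluid = list(density_rho = 1000, dynamic_viscosity_mu = 0.001),
       solver = list(grid_spacing = 0.15, time_step_divisor = 1000L,
                     n_cycles = 3L, time_scheme = "implicit_second_order",
                     linear_solve_tolerance = 1e-4,
                     initialization = "periodic", n_store = 100L),
       pcmri = list(voxel_size = 1.5, noise_sd_phase = 0.1,
                    include_vascular_confounders = TRUE,
                    nerve_root_deficit_factor = 0.5, nerve_root_sigma = 0.8,
                    anterior_weight = 2, jet_peak_factor = 2.5),
       smoothing = list(iterations = 10L, relaxation_factor = 0.5),
       cycle = list(period_T = 1, n_phases = 30L),
       output = list(write_nifti = FALSE, write_figures = TRUE))
}

#' Read a run configuration (JSON or YAML)
#'
#' Schema-validated against the documented defaults: unknown keys are
#' rejected, missing ones filled in.
#'
#' @param path `.json`, `.yaml` or `.yml` file; `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  check <- function(user, def, where) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) {
      stop(sprintf("unknown configuration key%s %s in %s",
                   if (length(bad) > 1) "s" else "",
                   paste(sQuote(bad), collapse = ", "), where))
    }
    for (nm in names(user)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- check(user[[nm]], def[[nm]], paste0(where, "$", nm))
      } else def[[nm]] <- user[[nm]]
    }
    def
  }
  check(cfg, defaults, "config")
}
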