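# Cardiac-cycle tissue-motion analysis: subtraction of the extreme rostral
# and caudal displacement images, threshold masking (the transparent overlay
# of the in-vivo visualisation), and a moving-area summary.

#' Threshold motion mask from a displacement image pair
#'
#' Pixels whose absolute rostral-caudal image difference is at or below the
#' threshold are masked as static; the remainder are moving tissue. The
#' default threshold is 3x the robust noise SD (median absolute deviation)
#' of the difference image.
#'
#' @param pair A `motion_image_pair`.
#' @param threshold Intensity threshold (>= 0); `NULL` for the robust
#'   default.
#' @param field_mask Optional logical matrix restricting the field of
#'   interest over which `moving_fraction` is computed.
#' @return A `motion_mask`: `mask` (TRUE = static), `moving_fraction`,
#'   `threshold`, `pixel_size`.
#' @export
motion_difference_mask <- function(pair, threshold = NULL, field_mask = NULL) {
  stopifnot(inherits(pair, "motion_image_pair"))
  d <- pair$image_rostral - pair$image_caudal
  if (!all(dim(pair$image_rostral) == dim(pair$image_caudal))) {
    stop("image pair shapes differ")
  }
  if (is.null(threshold)) {
    threshold <- 3 * stats::mad(as.vector(d))
    if (threshold == 0) threshold <- 1e-6 * max(abs(d), 1)
  }
  stopifnot(threshold >= 0)
  static <- abs(d) <= threshold
  fov <- if (is.null(field_mask)) rep(TRUE, length(static)) else {
    stopifnot(all(dim(field_mask) == dim(static)))
    as.vector(field_mask)
  }
  structure(list(mask = static,
                 moving_fraction = sum(!static[fov]) / sum(fov),
                 threshold = threshold, pixel_size = pair$pixel_size),
            class = "motion_mask")
}

#' Moving area of a motion mask
#' @param mask A `motion_mask`.
#' @return Area of moving (unmasked) pixels in mm^2.
#' @export
moving_area <- function(mask) sum(!mask$mask) * mask$pixel_size^2

#' Rank subjects by tissue motion
#'
#' @param masks Named list of `motion_mask` (names are subject ids).
#' @return Data frame ordered by decreasing `moving_fraction` (stable for
#'   ties).
#' @export
rank_by_motion <- function(masks) {
  if (length(masks) < 1L) stop("need at least one motion mask")
  d <- data.frame(subject_id = names(masks),
                  moving_fraction = vapply(masks, `[[`, numeric(1),
                                           "moving_fraction"),
                  row.names = NULL, stringsAsFactors = FALSE)
  d[order(-d$moving_fraction), , drop = FALSE]
}

#' Write a motion-overlay PNG
#'
#' Rostral image in grey with the static (masked) region tinted, mirroring
#' the transparent overlay used to visualise tonsillar motion.
#'
#' @param mask A `motion_mask`.
#' @param pair The `motion_image_pair` it was computed from.
#' @param path Output PNG path.
#' @export
write_motion_overlay <- function(mask, pair, path) {
  img <- pair$image_rostral
  g <- (img - min(img)) / max(max(img) - min(img), 1e-9)
  r <- g; gr <- g; b <- g
  r[mask$mask] <- 0.3 * g[mask$mask]
  gr[mask$mask] <- 0.6 * g[mask$mask] + 0.3
  b[mask$mask] <- 0.6 * g[mask$mask] + 0.4
  arr <- array(c(r, gr, b), c(nrow(img), ncol(img), 3L))
  # image rows run along x; transpose to raster orientation (y down)
  arr <- aperm(arr, c(2L, 1L, 3L))[rev(seq_len(ncol(img))), , , drop = FALSE]
  grDevices::png(path, width = nrow(img), height = ncol(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(arr, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
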