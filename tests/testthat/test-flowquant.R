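test_that("ROI flow integration is exact unit arithmetic", {
  # uniform 2 cm/s over 100 pixels of 1 mm^2 -> 2 mL/s
  cyc <- cardiac_cycle(1, 4L)
  vz <- array(0, c(12, 12, 1, 4))
  mask <- matrix(FALSE, 12, 12); mask[2:11, 2:11] <- TRUE
  vz[cbind(rep(2:11, 10), rep(2:11, each = 10), 1, 1)] <- 2
  field <- structure(list(components = list(z = vz), dims = c(12, 12, 1),
                          voxel_size = 1, cycle = cyc, venc = 10,
                          xs = 1:12, ys = 1:12, zs = 0),
                     class = "velocity_field_4d")
  roi <- axial_plane_roi(mask, 1L, "C3", pixel_area = 1)
  q <- integrate_roi_flow(field, roi)
  expect_equal(q$samples, c(2, 0, 0, 0))
  expect_false(q$offset_applied)
})

test_that("ROI integration matches the per-pixel oracle and is additive", {
  nf <- noiseless_field()
  f <- nf$field
  roi <- roi_from_geometry(f, nf$geometry, "C3")
  q <- integrate_roi_flow(f, roi)
  for (ph in c(1L, 6L)) {
    expect_equal(q$samples[ph], oracle_roi_flow(f, roi, ph),
                 tolerance = 1e-12)
  }
  # additivity over a disjoint partition of the mask
  m1 <- roi$mask; m1[, seq_len(ncol(m1) %/% 2)] <- FALSE
  m2 <- roi$mask & !m1
  q1 <- integrate_roi_flow(f, axial_plane_roi(m1, roi$z_index, "C3", roi$pixel_area))
  q2 <- integrate_roi_flow(f, axial_plane_roi(m2, roi$z_index, "C3", roi$pixel_area))
  expect_equal(q1$samples + q2$samples, q$samples, tolerance = 1e-12)

  expect_error(axial_plane_roi(matrix(FALSE, 3, 3), 1L, "C3", 1), "empty")
})

test_that("peak velocities report signed extremes with the zero convention", {
  cyc <- cardiac_cycle(1, 3L)
  vz <- array(rep(c(-4, 1, 3), each = 4), c(2, 2, 1, 3))
  field <- structure(list(components = list(z = vz), dims = c(2, 2, 1),
                          voxel_size = 1, cycle = cyc, venc = 10),
                     class = "velocity_field_4d")
  roi <- axial_plane_roi(matrix(TRUE, 2, 2), 1L, "FM", 1)
  pk <- peak_velocities(field, roi)
  expect_equal(unname(pk), c(-4, 3))

  vz_pos <- array(abs(vz) + 0.5, dim(vz))
  fp <- field; fp$components$z <- vz_pos
  expect_equal(unname(peak_velocities(fp, roi)), c(0, 4.5))
})

test_that("noiseless ROI peaks equal the generator ground truth exactly", {
  nf <- noiseless_field()
  f <- nf$field
  for (lv in c("FM", "C3", "C7")) {
    roi <- roi_from_geometry(f, nf$geometry, lv)
    pk <- peak_velocities(f, roi)
    pix <- which(roi$mask, arr.ind = TRUE)
    pts <- cbind(f$xs[pix[, 1L]], f$ys[pix[, 2L]], f$zs[roi$z_index])
    truth <- vapply(seq_len(f$cycle$n_phases), function(ph)
      range(nf$sampler$sample(pts, ph)[, 3L]), numeric(2))
    expect_equal(pk[["systolic"]], min(0, min(truth)), tolerance = 1e-12)
    expect_equal(pk[["diastolic"]], max(0, max(truth)), tolerance = 1e-12)
  }
})

test_that("vascular exclusion removes confounders and keeps CSF pixels", {
  cf <- confounded_field()
  f <- cf$field
  # an ROI deliberately spanning the whole FM slice, confounders included
  fm <- get_section_test(cf$geometry, "FM")
  zi <- which.min(abs(f$zs - fm$z_position))
  mask <- matrix(TRUE, f$dims[1L], f$dims[2L])
  roi <- axial_plane_roi(mask, zi, "FM", f$voxel_size^2)
  pruned <- exclude_vascular_pixels(f, roi)
  conf_slice <- f$confounder_mask[, , zi]
  lum_slice <- f$lumen_mask[, , zi]
  expect_true(all(!pruned$mask[conf_slice]))       # all confounders removed
  expect_gte(sum(pruned$mask[lum_slice]) / sum(lum_slice), 0.99)

  # pure alternating CSF flow: ROI unchanged
  nf <- noiseless_field()
  roi2 <- roi_from_geometry(nf$field, nf$geometry, "C3")
  expect_equal(exclude_vascular_pixels(nf$field, roi2)$mask, roi2$mask)

  # all-zero pixels are retained (below the magnitude floor)
  f0 <- nf$field
  f0$components$z[] <- 0
  expect_equal(exclude_vascular_pixels(f0, roi2)$mask, roi2$mask)
})

test_that("cuff ROIs drop the posterior wedge; ring ROIs are annular", {
  nf <- noiseless_field()
  ring <- roi_from_geometry(nf$field, nf$geometry, "C3", "ring")
  cuff <- roi_from_geometry(nf$field, nf$geometry, "C3", "cuff")
  expect_lt(sum(cuff$mask), sum(ring$mask))
  expect_true(all(ring$mask[cuff$mask]))
})

test_that("quantify_level assembles metrics with the offset bookkeeping", {
  cf <- confounded_field()
  q <- quantify_level(cf$field, roi_from_geometry(cf$field, cf$geometry, "C4"))
  expect_true(q$waveform_offset$offset_applied)
  expect_lte(abs(mean(q$waveform_offset$samples)),
             1e-9 * max(abs(q$waveform_offset$samples)))
  expect_lte(q$metrics$peak_systolic, 0)
  expect_gte(q$metrics$peak_diastolic, 0)
  expect_gte(q$metrics$stroke_volume, 0)
})
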