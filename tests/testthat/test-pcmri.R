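test_that("ground-truth slice flux matches the waveform (quadrature oracle)", {
  geom <- annulus_geometry()
  cyc <- cardiac_cycle(1, 10L)
  wf <- sine_waveform(2, cyc)
  cfg <- pcmri_config(venc = 10, noise_sd_phase = 0, anterior_weight = 1,
                      seed = 1L)
  s <- ground_truth_velocity(geom, wf, cfg, quad_mm = 0.1)
  # independent midpoint quadrature on the sampler's stated lattice
  sec <- section_at_z(geom, 30)
  bb <- apply(sec$outer_contour, 2L, range)
  qx <- seq(bb[1, 1], bb[2, 1], by = 0.1)
  qy <- seq(bb[1, 2], bb[2, 2], by = 0.1)
  pts <- cbind(rep(qx, times = length(qy)), rep(qy, each = length(qx)), 30)
  for (ph in c(3L, 8L)) {
    v <- s$sample(pts, ph)[, 3L]                # cm/s
    q_est <- sum(v) * 10 * 0.1^2 / 1000         # mL/s
    expect_equal(q_est, wf$samples[ph], tolerance = 1e-6)
  }
  # zero flow phase: identically zero field
  ph0 <- which(abs(wf$samples) < 1e-12)[1L]
  expect_equal(max(abs(s$sample(pts, ph0))), 0)
})

test_that("anterior weighting skews mid-gap speeds by the configured factor", {
  geom <- annulus_geometry()
  cyc <- cardiac_cycle(1, 10L)
  wf <- sine_waveform(2, cyc)
  s <- ground_truth_velocity(geom, wf,
                             pcmri_config(venc = 10, noise_sd_phase = 0,
                                          anterior_weight = 2, seed = 1L),
                             quad_mm = 0.25)
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  pts <- cbind(7 * cos(th), 7 * sin(th), 50)    # mid-gap ring
  v <- abs(s$sample(pts, 3L)[, 3L])
  ant <- mean(v[sin(th) > 0]); post <- mean(v[sin(th) < 0])
  expect_gte(ant / post, 1.5)
})

test_that("nerve-root inclusions carve local velocity deficits", {
  geom <- make_geometry(sss_template(perturb_amplitude = 0,
                                     smoothing = smoothing_config(0L)),
                        seed = 1L)
  cyc <- cardiac_cycle(1, 10L)
  wf <- sine_waveform(2, cyc)
  v_at <- function(f) {
    s <- ground_truth_velocity(geom, wf,
                               pcmri_config(venc = 10, noise_sd_phase = 0,
                                            anterior_weight = 1,
                                            nerve_root_deficit_factor = f,
                                            seed = 1L), quad_mm = 0.25)
    sec <- get_section_test(geom, "C5")
    inc <- sec$inclusions[[1L]]
    c0 <- colMeans(inc)
    # just outside the inclusion, inside its dilated neighbourhood
    abs(s$sample(cbind(c0[1L], c0[2L] + 1.2, sec$z_position), 3L)[, 3L])
  }
  expect_lt(v_at(0.8), v_at(0))
})

test_that("cm-like geometries carry a stenotic jet with the prescribed peak", {
  geom <- make_geometry(subject_class = "cm_like", stenosis_severity = 0.4,
                        seed = 3L)
  cyc <- cardiac_cycle(1, 10L)
  wf <- sine_waveform(2, cyc)
  cfg <- pcmri_config(venc = 20, noise_sd_phase = 0, anterior_weight = 1,
                      jet_peak_factor = 2.5, seed = 1L)
  s <- ground_truth_velocity(geom, wf, cfg, quad_mm = 0.1)
  fm <- get_section_test(geom, "FM")
  sl <- s$slice(fm$z_position)
  bb <- apply(fm$outer_contour, 2L, range)
  qx <- seq(bb[1, 1], bb[2, 1], by = 0.1)
  qy <- seq(bb[1, 2], bb[2, 2], by = 0.1)
  sh <- sl$fun(rep(qx, times = length(qy)), rep(qy, each = length(qx)))
  expect_equal(max(sh) / mean(sh[sh > 0]), 2.5, tolerance = 0.05)
})

test_that("velocity encoding is exact below VENC and aliases beyond it", {
  venc <- 10
  expect_equal(encode_velocity(0.5 * venc, venc), 0.5 * venc)
  expect_equal(encode_velocity(1.5 * venc, venc), -0.5 * venc)
  expect_equal(encode_velocity(-venc, venc), -venc)
  v <- seq(-0.99, 0.99, by = 0.03) * venc
  expect_equal(encode_velocity(v, venc), v, tolerance = 1e-12)
  # exact 2*VENC periodicity
  expect_equal(encode_velocity(v + 2 * venc, venc), encode_velocity(v, venc),
               tolerance = 1e-9)
  expect_equal(encode_velocity(v - 4 * venc, venc), encode_velocity(v, venc),
               tolerance = 1e-9)
})

test_that("phase noise maps to velocity noise with SD venc*sigma/pi", {
  venc <- 10; sigma <- 0.12
  set.seed(21)
  v <- encode_velocity(rep(0, 1e5), venc, stats::rnorm(1e5, 0, sigma))
  expect_equal(stats::sd(v), venc * sigma / pi, tolerance = 0.05)
  expect_true(all(v >= -venc & v < venc))
})

test_that("noiseless encoding is the identity on the sampled lumen", {
  nf <- noiseless_field()
  f <- nf$field
  ph <- 3L
  pts <- cbind(rep(f$xs, times = length(f$ys)),
               rep(f$ys, each = length(f$xs)),
               f$zs[10L])
  truth <- nf$sampler$sample(pts, ph)[, 3L]
  expect_equal(as.vector(f$components$z[, , 10L, ph]), truth,
               tolerance = 1e-12)
  expect_equal(max(abs(f$components$x)), 0)
})

test_that("vascular confounders are unidirectional; CSF alternates sign", {
  cf <- confounded_field()
  f <- cf$field
  vz <- f$components$z
  dim(vz) <- c(prod(f$dims), f$cycle$n_phases)
  conf <- which(as.vector(f$confounder_mask))
  expect_gt(length(conf), 0)
  sign_const <- apply(vz[conf, , drop = FALSE], 1L,
                      function(r) all(r > 0) || all(r < 0))
  expect_true(all(sign_const))
  # lumen pixels with appreciable flow change sign over the cycle
  lum <- which(as.vector(f$lumen_mask) & !as.vector(f$confounder_mask))
  vl <- vz[lum, , drop = FALSE]
  strong <- apply(abs(vl), 1L, max) > 1
  flips <- apply(vl[strong, , drop = FALSE], 1L,
                 function(r) min(r) < 0 && max(r) > 0)
  expect_gte(mean(flips), 0.99)
})

test_that("motion pairs realise exact sub-pixel displacement", {
  p0 <- make_motion_pair(0, list(noise_sd = 0), seed = 2L)
  expect_identical(p0$image_rostral, p0$image_caudal)

  p <- make_motion_pair(3, list(shape = "block", pixel_size = 1,
                                noise_sd = 0), seed = 2L)
  c1 <- oracle_centroid(p$image_rostral, p$xs, p$ys, p$background)
  c2 <- oracle_centroid(p$image_caudal, p$xs, p$ys, p$background)
  expect_equal(c1[2L] - c2[2L], 3, tolerance = 1e-9)   # 3 px at 1 mm pixels
  expect_equal(c1[1L], c2[1L], tolerance = 1e-9)

  pa <- make_motion_pair(1.4, seed = 5L)
  pb <- make_motion_pair(1.4, seed = 5L)
  expect_identical(pa$image_caudal, pb$image_caudal)
  expect_error(make_motion_pair(40), "extent")
})
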