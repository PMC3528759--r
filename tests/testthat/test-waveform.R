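test_that("zero-net-flow offset subtracts the periodic cycle mean", {
  cyc <- cardiac_cycle(1, 1000L)
  t <- phase_times(cyc)

  # already zero-mean: unchanged, offset 0
  w0 <- flow_waveform(sin(2 * pi * t), cyc, "C3")
  o0 <- offset_to_zero_net(w0)
  expect_equal(o0$samples, w0$samples)
  expect_equal(o0$applied_offset_value, 0, tolerance = 1e-15)

  # sin + 0.5: recorded offset is -0.5 (periodic trapezoid mean oracle)
  w <- flow_waveform(sin(2 * pi * t) + 0.5, cyc, "C3")
  o <- offset_to_zero_net(w)
  expect_equal(o$applied_offset_value, -0.5, tolerance = 1e-6)
  expect_equal(o$applied_offset_value, -oracle_cycle_mean(w$samples),
               tolerance = 1e-12)
  expect_lte(abs(mean(o$samples)), 1e-9 * max(abs(o$samples)))

  # constant flow offsets to identically zero
  wc <- offset_to_zero_net(flow_waveform(rep(3.2, 1000L), cyc, "C3"))
  expect_equal(wc$samples, rep(0, 1000L))
  expect_equal(wc$applied_offset_value, -3.2)

  # all-zero waveform: unchanged with offset 0
  wz <- offset_to_zero_net(flow_waveform(rep(0, 1000L), cyc, "C3"))
  expect_equal(wz$samples, rep(0, 1000L))
  expect_equal(wz$applied_offset_value, 0)
})

test_that("offset is idempotent and exactly shift-equivariant", {
  cyc <- cardiac_cycle(0.9, 30L)
  set.seed(8)
  q <- stats::rnorm(30L)
  w <- flow_waveform(q, cyc, "C2M")
  o1 <- offset_to_zero_net(w)
  o2 <- offset_to_zero_net(o1)
  expect_equal(o2$samples, o1$samples)
  expect_equal(o2$applied_offset_value, o1$applied_offset_value)
  for (c0 in c(-2, 0.7, 13)) {
    oc <- offset_to_zero_net(flow_waveform(q + c0, cyc, "C2M"))
    expect_equal(oc$samples, o1$samples, tolerance = 1e-12)
  }
})

test_that("stroke volume matches the sine closed form and is linear", {
  cyc <- cardiac_cycle(1, 1000L)
  t <- phase_times(cyc)
  expect_equal(stroke_volume(flow_waveform(rep(0, 1000L), cyc, "FM")), 0)
  w <- flow_waveform(2 * sin(2 * pi * t), cyc, "FM")
  expect_equal(stroke_volume(w), 2 / pi, tolerance = 1e-3)  # Q0*T/pi
  w3 <- flow_waveform(3 * w$samples, cyc, "FM")
  expect_equal(stroke_volume(w3), 3 * stroke_volume(w), tolerance = 1e-12)

  # invariance of SV(offset(Q)) under rotation of the cycle time origin
  set.seed(9)
  q <- stats::rnorm(30L)
  cyc30 <- cardiac_cycle(1, 30L)
  sv0 <- stroke_volume(offset_to_zero_net(flow_waveform(q, cyc30, "C5")))
  for (k in c(3L, 11L, 29L)) {
    qr <- c(q[-seq_len(k)], q[seq_len(k)])
    expect_equal(stroke_volume(offset_to_zero_net(
      flow_waveform(qr, cyc30, "C5"))), sv0, tolerance = 1e-12)
  }
})

test_that("inlet selection takes the greatest peak flow, caudal on ties", {
  cyc <- cardiac_cycle(1, 8L)
  mk <- function(peak, lv) flow_waveform(peak * sin(2 * pi * phase_times(cyc)),
                                         cyc, lv)
  sel <- select_inlet_waveform(list(mk(3, "FM"), mk(5, "C1"), mk(4, "C3")))
  expect_equal(sel$level_label, "C1")

  one <- mk(2, "C4")
  expect_equal(select_inlet_waveform(list(one))$waveform$samples, one$samples)

  tie <- select_inlet_waveform(list(mk(5, "C1"), mk(5, "C3")))
  expect_equal(tie$level_label, "C3")  # more caudal wins

  expect_error(select_inlet_waveform(list()), "at least one")
})

test_that("trigonometric interpolation reproduces band-limited signals", {
  cyc <- cardiac_cycle(1, 30L)
  t <- phase_times(cyc)
  w <- flow_waveform(1.7 * sin(2 * pi * t), cyc, "C1")
  d <- interpolate_waveform(w, 1000L)
  expect_equal(d$samples, 1.7 * sin(2 * pi * d$times), tolerance = 1e-10)

  # passes through the original samples; preserves zero mean
  f <- waveform_interpolant(w)
  expect_equal(f(t), w$samples, tolerance = 1e-12)
  set.seed(10)
  wz <- offset_to_zero_net(flow_waveform(stats::rnorm(30L), cyc, "C1"))
  dz <- interpolate_waveform(wz, 750L)
  expect_lte(abs(mean(dz$samples)), 1e-9 * max(abs(dz$samples)))
  expect_equal(waveform_interpolant(wz)(t), wz$samples, tolerance = 1e-12)

  d0 <- interpolate_waveform(flow_waveform(rep(0, 30L), cyc, "C1"), 500L)
  expect_equal(d0$samples, rep(0, 500L))
  expect_error(interpolate_waveform(w, 10L), "phases")
})

test_that("waveform CSV round trip preserves samples and levels", {
  cyc <- cardiac_cycle(0.8, 24L)
  w1 <- make_csf_waveform(cyc, amplitude = 2, level_label = "C1")
  w2 <- make_csf_waveform(cyc, amplitude = 1.1, level_label = "C6")
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(list(w1, w2), path)
  expect_equal(readLines(path, n = 1),
               "level,phase_index,time_s,flow_mL_per_s")
  back <- read_waveform_csv(path)
  expect_equal(back$C1$samples, w1$samples, tolerance = 1e-12)
  expect_equal(back$C6$samples, w2$samples, tolerance = 1e-12)
  expect_equal(back$C1$cycle$period_T, 0.8, tolerance = 1e-9)
})

test_that("the synthetic pulse has a dominant caudal (systolic) lobe", {
  w <- make_csf_waveform(amplitude = 2)
  expect_equal(min(w$samples), -2, tolerance = 1e-9)
  expect_lt(max(w$samples), 2)
  expect_lte(abs(mean(w$samples)), 1e-12)
})
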