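# Shared in-code fixtures. Everything is generated programmatically with
# fixed seeds; expensive objects are memoised for reuse across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# concentric 5/9 mm annulus section (finely polygonised benchmark)
annulus_section <- function(level = "INLET", z = 0, n = 720L) {
  cross_section(level, z, circle_polygon(9, n), circle_polygon(5, n))
}

# axially uniform annulus geometry spanning the labelled levels
annulus_geometry <- function(n = 256L) {
  mk <- function(lv, z) cross_section(lv, z, circle_polygon(9, n),
                                      circle_polygon(5, n))
  sss_geometry(list(mk("INLET", -50), mk("C7", 0), mk("C3", 64),
                    mk("C1", 100), mk("FM", 112)))
}

get_section_test <- function(g, lv) {
  g$sections[[which(vapply(g$sections, `[[`, character(1),
                           "level_label") == lv)]]
}

sine_waveform <- function(Q0 = 2, cycle = cardiac_cycle(1, 30),
                          level = "INLET") {
  flow_waveform(Q0 * sin(2 * pi * phase_times(cycle)), cycle, level)
}

# small noiseless encoded field on the default parametric geometry
noiseless_field <- function() {
  memo("noiseless_field", {
    geom <- make_geometry(seed = 7L)
    cyc <- cardiac_cycle(1, 10L)
    wf <- make_csf_waveform(cyc, amplitude = 2)
    cfg <- pcmri_config(venc = 10, noise_sd_phase = 0, seed = 3L)
    s <- ground_truth_velocity(geom, wf, cfg, quad_mm = 0.25)
    list(geometry = geom, waveform = wf, config = cfg, sampler = s,
         field = encode_pcmri(s, geom, cfg, cyc))
  })
}

# the same acquisition with noise and vascular confounders
confounded_field <- function() {
  memo("confounded_field", {
    geom <- make_geometry(seed = 7L)
    cyc <- cardiac_cycle(1, 10L)
    wf <- make_csf_waveform(cyc, amplitude = 2)
    cfg <- pcmri_config(venc = 10, noise_sd_phase = 0.05,
                        include_vascular_confounders = TRUE, seed = 3L)
    s <- ground_truth_velocity(geom, wf, cfg, quad_mm = 0.25)
    list(geometry = geom, waveform = wf, config = cfg, sampler = s,
         field = encode_pcmri(s, geom, cfg, cyc))
  })
}
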