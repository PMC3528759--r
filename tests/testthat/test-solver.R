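# Unit tests for the sectionwise pulsatile solver use reduced resolutions;
# the full-resolution oracle comparisons live in the acceptance suite.

fast_cfg <- function(...) {
  solver_config(grid_spacing = 0.4, time_step_divisor = 100L, n_cycles = 2L,
                time_scheme = "implicit_second_order", ...)
}

test_that("blunt inlet profile is Q/A and re-integrates to Q", {
  sec <- annulus_section()
  cyc <- cardiac_cycle(1, 20L)
  wf <- offset_to_zero_net(sine_waveform(2, cyc))
  bp <- build_inlet_profile(wf, sec)
  expect_equal(bp$velocity_cm_s, wf$samples * 1000 / section_area(sec) / 10)
  # uniform profile times area recovers the flow exactly
  expect_equal(bp$velocity_cm_s * 10 * bp$area_mm2 / 1000, wf$samples)
  # Q = 2 mL/s over 200 mm^2 is 1 cm/s
  sq <- cross_section("INLET", 0,
                      circle_polygon(sqrt(225 / pi), 720),
                      circle_polygon(sqrt(25 / pi), 720))
  expect_equal(section_area(sq), 200, tolerance = 1e-3)
  bp2 <- build_inlet_profile(
    flow_waveform(rep(2, 20L) - 2, cyc, "INLET", offset_applied = TRUE), sq)
  expect_equal(max(abs(bp2$velocity_cm_s)), 0)
  expect_error(build_inlet_profile(sine_waveform(2, cyc), sec), "offset")
})

test_that("zero forcing yields the zero solution", {
  sec <- annulus_section(n = 256L)
  cyc <- cardiac_cycle(1, 20L)
  d <- interpolate_waveform(flow_waveform(rep(0, 20L), cyc, "INLET"), 100L)
  sol <- solve_pulsatile_section(sec, d, fluid_properties(), fast_cfg())
  expect_equal(max(abs(sol$w)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sol$pressure_gradient_G)), 0, tolerance = 1e-9)
})

test_that("solver is linear in the forcing", {
  sec <- annulus_section(n = 256L)
  cyc <- cardiac_cycle(1, 20L)
  t <- phase_times(cyc)
  q1 <- sin(2 * pi * t); q2 <- 0.6 * sin(4 * pi * t) + 0.2 * cos(2 * pi * t) - 0.2
  cfg <- fast_cfg()
  run <- function(q) solve_pulsatile_section(
    sec, interpolate_waveform(flow_waveform(q, cyc, "INLET"), 100L),
    fluid_properties(), cfg)
  s1 <- run(q1); s2 <- run(q2); s12 <- run(2 * q1 - 3 * q2)
  expect_equal(s12$w, 2 * s1$w - 3 * s2$w, tolerance = 1e-8)
})

test_that("flux is matched at every step and no-slip holds on the lattice", {
  sec <- annulus_section(n = 256L)
  sol <- solve_pulsatile_section(
    sec, interpolate_waveform(sine_waveform(2, cardiac_cycle(1, 20L)), 200L),
    fluid_properties(), fast_cfg())
  expect_lt(sol$max_flux_rel_err, 1e-8)
  # outside-lumen lattice points are identically zero in exported maps
  m <- sample_solution_on_plane(sol)$map_systole
  expect_true(all(is.na(m[-sol$grid$idx])))
  expect_true(all(!is.na(m[sol$grid$idx])))
  # cycle-to-cycle periodicity with the periodic initialization
  expect_lt(sol$periodicity_rel, 1e-6)
})

test_that("zero-start marching decays toward the periodic orbit", {
  sec <- annulus_section(n = 256L)
  d <- interpolate_waveform(sine_waveform(2, cardiac_cycle(1, 20L)), 100L)
  cfg4 <- solver_config(grid_spacing = 0.4, time_step_divisor = 100L,
                        n_cycles = 4L, time_scheme = "implicit_second_order",
                        initialization = "zero")
  cfg2 <- cfg4; cfg2$n_cycles <- 2L
  s4 <- solve_pulsatile_section(sec, d, fluid_properties(), cfg4)
  s2 <- solve_pulsatile_section(sec, d, fluid_properties(), cfg2)
  expect_lt(s4$periodicity_rel, s2$periodicity_rel)
  ref <- solve_pulsatile_section(sec, d, fluid_properties(), fast_cfg())
  expect_lt(max(abs(s4$w - ref$w)) / max(abs(ref$w)), 0.05)
})

test_that("grid relative error formula and its edge cases", {
  expect_equal(grid_relative_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(grid_relative_error(c(1, -2, 0.5), 0.9 * c(1, -2, 0.5)), 10)
  set.seed(13)
  vf <- stats::rnorm(50); vc <- stats::rnorm(50)
  expect_equal(grid_relative_error(vf, vc), oracle_max_rel_err(vf, vc),
               tolerance = 1e-12)
  expect_error(grid_relative_error(rep(0, 5), stats::rnorm(5)), "zero")
})

test_that("plane sampling exposes metrics consistent with the stored field", {
  sec <- annulus_section(n = 256L, level = "C3")
  sol <- solve_pulsatile_section(
    sec, interpolate_waveform(sine_waveform(2, cardiac_cycle(1, 20L)), 100L),
    fluid_properties(), fast_cfg())
  pl <- sample_solution_on_plane(list(sol), "C3")
  all_w <- cbind(sol$w, sol$w_sys, sol$w_dia)
  expect_equal(pl$metrics$peak_systolic, min(all_w))
  expect_equal(pl$metrics$peak_diastolic, max(all_w))
  expect_equal(pl$metrics$method, "cfd")
  expect_error(sample_solution_on_plane(list(sol), "C5"), "no solution")
})

test_that("narrower sections at fixed flow give larger mean speeds", {
  cyc <- cardiac_cycle(1, 20L)
  d <- interpolate_waveform(sine_waveform(2, cyc), 100L)
  wide <- annulus_section(n = 256L)
  narrow <- cross_section("INLET", 0, circle_polygon(7.5, 256L),
                          circle_polygon(5, 256L))
  cfg <- solver_config(grid_spacing = 0.25, time_step_divisor = 100L,
                       n_cycles = 2L, time_scheme = "implicit_second_order")
  sw <- solve_pulsatile_section(wide, d, fluid_properties(), cfg)
  sn <- solve_pulsatile_section(narrow, d, fluid_properties(), cfg)
  expect_gt(mean(abs(sn$w_sys)), mean(abs(sw$w_sys)))
})

test_that("independence study rejects degenerate sweeps and reports e pairs", {
  sec <- annulus_section(n = 256L)
  wf <- sine_waveform(2, cardiac_cycle(1, 20L))
  expect_error(independence_study(list(sec), wf, fluid_properties(),
                                  fast_cfg(),
                                  grid_spacings = c(0.4, 0.4, 0.2),
                                  divisors = c(50L, 100L, 200L)),
               "strictly decreasing")
  expect_error(independence_study(list(sec), wf, fluid_properties(),
                                  fast_cfg(),
                                  grid_spacings = c(0.4, 0.3, 0.2),
                                  divisors = c(100L, 100L, 200L)),
               "strictly increasing")
  cr <- independence_study(list(sec), wf, fluid_properties(), fast_cfg(),
                           grid_spacings = c(0.4, 0.2, 0.1),
                           divisors = c(50L, 100L, 200L))
  expect_s3_class(cr, "convergence_result")
  expect_gte(cr$e_coarse_medium, 0)
  expect_gte(cr$e_medium_fine, 0)
  expect_lt(cr$e_medium_fine, cr$e_coarse_medium)
})

test_that("solver refuses grids that under-resolve the gap", {
  sec <- annulus_section(n = 256L)
  d <- interpolate_waveform(sine_waveform(2, cardiac_cycle(1, 20L)), 100L)
  expect_error(solve_pulsatile_section(sec, d, fluid_properties(),
                                       solver_config(grid_spacing = 0.8,
                                                     time_step_divisor = 100L)),
               "fewer than 10 points")
})

test_that("solution exports are readable VTK and CSV probe dumps", {
  sec <- annulus_section(n = 256L)
  sol <- solve_pulsatile_section(
    sec, interpolate_waveform(sine_waveform(2, cardiac_cycle(1, 20L)), 100L),
    fluid_properties(), fast_cfg())
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_solution_vtk(sol, vtk)
  head <- readLines(vtk, n = 8)
  expect_match(head[4], "STRUCTURED_POINTS")
  expect_match(head[5], sprintf("DIMENSIONS %d %d 1", sol$grid$nx, sol$grid$ny))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_probe_csv(sol, csv)
  d <- utils::read.csv(csv)
  expect_equal(names(d), c("x_mm", "y_mm", "w_cm_s"))
  expect_lt(min(d$w_cm_s), 0)   # systolic (caudal) flow along the probe
})
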