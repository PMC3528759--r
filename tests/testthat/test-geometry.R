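test_that("section areas match the annulus formula and the shoelace oracle", {
  sec <- annulus_section()
  expect_equal(section_area(sec), pi * (81 - 25), tolerance = 1e-4)

  # adding an inclusion of known area reduces the lumen by exactly that area
  inc <- circle_polygon(0.977, 48L, centre = c(7, 0))  # area ~ 3 mm^2
  sec2 <- cross_section("C3", 0, circle_polygon(9, 720),
                        circle_polygon(5, 720), list(inc))
  expect_equal(section_area(sec) - section_area(sec2), polygon_area(inc),
               tolerance = 1e-12)

  # random star-shaped polygons against the loop-based shoelace oracle
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    th <- sort(stats::runif(n, 0, 2 * pi))
    r <- stats::runif(n, 0.5, 3)
    xy <- cbind(r * cos(th), r * sin(th))
    expect_equal(polygon_area(xy), abs(oracle_shoelace(xy)),
                 tolerance = 1e-9)
  }
})

test_that("Laplacian smoothing matches per-vertex averaging and contracts", {
  hex <- circle_polygon(2, 17L)
  expect_equal(laplacian_smooth(hex, smoothing_config(0L, 0.5)), hex)

  # regular N-gon, one iteration at factor 1: every vertex lands on the
  # midpoint of its neighbours, which sit 2*(2*pi/N) apart, so radii
  # shrink by cos(2*pi/N); verified against the averaging oracle
  for (N in c(8L, 17L, 64L)) {
    poly <- circle_polygon(3, N)
    sm <- laplacian_smooth(poly, smoothing_config(1L, 1))
    expect_equal(sqrt(rowSums(sm^2)), rep(3 * cos(2 * pi / N), N),
                 tolerance = 1e-12)
    expect_equal(sm, oracle_smooth_once(poly, 1), tolerance = 1e-12)
  }

  # arbitrary factor against the oracle
  set.seed(4)
  wavy <- circle_polygon(5, 40L) * (1 + 0.05 * stats::rnorm(40))
  expect_equal(laplacian_smooth(wavy, smoothing_config(1L, 0.37)),
               oracle_smooth_once(wavy, 0.37), tolerance = 1e-12)

  # high-frequency zig-zag: perimeter strictly decreases every iteration
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  zig <- cbind((4 + 0.3 * (-1)^(1:64)) * cos(th),
               (4 + 0.3 * (-1)^(1:64)) * sin(th))
  per <- polygon_perimeter(zig)
  cur <- zig
  for (i in 1:5) {
    cur <- laplacian_smooth(cur, smoothing_config(1L, 0.5))
    p2 <- polygon_perimeter(cur)
    expect_lt(p2, per)
    per <- p2
  }

  # contractive on convex contours: enclosed area non-increasing
  a <- polygon_area(hex)
  cur <- hex
  for (i in 1:4) {
    cur <- laplacian_smooth(cur, smoothing_config(1L, 0.8))
    expect_lte(polygon_area(cur), a + 1e-12)
    a <- polygon_area(cur)
  }

  expect_error(laplacian_smooth(cbind(c(0, 1, 2), c(0, 0, 0))), "4 vertices")
})

test_that("make_geometry produces labelled sections with prescribed areas", {
  g <- make_geometry(sss_template(perturb_amplitude = 0,
                                  nerve_root_radius = 0.8,
                                  outer_semi_axes = c(9, 9),
                                  cord_semi_axes = c(5, 5),
                                  cord_offset_y = 0,
                                  smoothing = smoothing_config(0L)),
                     "healthy_like", 0, seed = 1L)
  lv <- vapply(g$sections, `[[`, character(1), "level_label")
  expect_setequal(lv, c("INLET", "FM", "C1", "C2M", "C2P",
                        "C3", "C4", "C5", "C6", "C7"))
  # unperturbed circular template: every section is the 5/9 annulus minus
  # any nerve-root inclusions (tolerance covers the 64-gon chord deficit)
  for (s in g$sections) {
    expect_equal(section_area(s),
                 pi * (81 - 25) - sum(vapply(s$inclusions, polygon_area,
                                             numeric(1))),
                 tolerance = 5e-3)
  }
})

test_that("stenosis severity controls the FM area as specified", {
  healthy_fm <- pi * prod(c(9, 8)) - pi * prod(c(4.5, 3.5))
  g <- make_geometry(subject_class = "cm_like", stenosis_severity = 0.5,
                     seed = 2L)
  fm <- g$sections[[which(vapply(g$sections, `[[`, character(1),
                                 "level_label") == "FM")]]
  expect_equal(section_area(fm), healthy_fm / 2, tolerance = 0.01)

  # monotonicity: increasing severity never increases the FM area
  areas <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(s) {
    gg <- make_geometry(subject_class = "cm_like", stenosis_severity = s,
                        seed = 2L)
    section_area(get_section_test(gg, "FM"))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("geometry generation is deterministic for a fixed seed", {
  g1 <- make_geometry(subject_class = "cm_like", stenosis_severity = 0.4,
                      seed = 42L)
  g2 <- make_geometry(subject_class = "cm_like", stenosis_severity = 0.4,
                      seed = 42L)
  expect_identical(g1, g2)
  g3 <- make_geometry(subject_class = "cm_like", stenosis_severity = 0.4,
                      seed = 43L)
  expect_false(identical(g1$sections[[3]]$outer_contour,
                         g3$sections[[3]]$outer_contour))
})

test_that("geometry JSON round trip is bit-exact and WKT/VTK export work", {
  g <- make_geometry(seed = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry_json(g, path)
  g2 <- read_geometry_json(path)
  for (i in seq_along(g$sections)) {
    expect_identical(g$sections[[i]]$outer_contour,
                     g2$sections[[i]]$outer_contour)
    expect_identical(g$sections[[i]]$inner_contour,
                     g2$sections[[i]]$inner_contour)
  }
  expect_match(section_wkt(g$sections[[2]]), "^POLYGON \\(\\(")
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_geometry_vtk(g, vtk)
  expect_match(readLines(vtk, n = 4)[4], "POLYDATA")
})

test_that("invalid sections are rejected with geometry-validity errors", {
  expect_error(cross_section("FM", 0, circle_polygon(5, 32),
                             circle_polygon(9, 32)), "inside")
  bow <- cbind(c(0, 2, 0, 2), c(0, 2, 2, 0))  # self-intersecting
  expect_error(cross_section("FM", 0, bow, circle_polygon(0.2, 16)),
               "self-intersecting")
  expect_error(cross_section("FM", 0, circle_polygon(9, 32),
                             circle_polygon(5, 32),
                             list(circle_polygon(1, 16, centre = c(0, 0)))),
               "annular gap")
})

test_that("section interpolation brackets z and errors outside the range", {
  g <- annulus_geometry()
  s <- section_at_z(g, 32)
  expect_equal(section_area(s), pi * 56, tolerance = 1e-2)
  expect_error(section_at_z(g, 500), "outside")
  expect_error(section_at_z(g, -80), "outside")
})
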