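# Sectionwise pulsatile flow solver.
#
# Rigid-wall, incompressible, Newtonian, laminar axial flow through a stack
# of cross-sections: on each section the fully developed momentum balance
#   rho dw/dt = G(t) + mu * Laplacian(w),   w = 0 on the walls,
# is discretised with masked 5-point finite differences (Shortley-Weller
# embedded Dirichlet boundaries) and marched implicitly, with the driving
# pressure gradient G(t) determined at every time step so the areal flux of
# w matches the prescribed flow waveform Q(t). For axially invariant lumens
# the advective term vanishes identically, so this is an exact reduction of
# the incompressible Navier-Stokes momentum balance.

#' CSF fluid properties
#'
#' Water at body temperature.
#'
#' @param density_rho Density in kg/m^3.
#' @param dynamic_viscosity_mu Dynamic viscosity in Pa s.
#' @export
fluid_properties <- function(density_rho = 1000, dynamic_viscosity_mu = 0.001) {
  stopifnot(density_rho > 0, dynamic_viscosity_mu > 0)
  structure(list(density_rho = density_rho,
                 dynamic_viscosity_mu = dynamic_viscosity_mu),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' @param grid_spacing Uniform lattice spacing in mm.
#' @param time_step_divisor Steps per cardiac cycle (time step `T/divisor`).
#' @param n_cycles Cycles to march; read-outs use the final cycle.
#' @param time_scheme `"implicit_first_order"` (backward Euler) or
#'   `"implicit_second_order"` (BDF2).
#' @param linear_solve_tolerance Relative RMS residual each implicit solve
#'   must satisfy.
#' @param initialization `"periodic"` starts from the harmonic-balance
#'   periodic state of the discrete stepping operator (no start-up
#'   transient); `"zero"` starts from rest.
#' @param n_store Number of evenly spaced final-cycle snapshots retained.
#' @export
solver_config <- function(grid_spacing = 0.15, time_step_divisor = 1000L,
                          n_cycles = 3L,
                          time_scheme = c("implicit_first_order",
                                          "implicit_second_order"),
                          linear_solve_tolerance = 1e-4,
                          initialization = c("periodic", "zero"),
                          n_store = 100L) {
  time_scheme <- match.arg(time_scheme)
  initialization <- match.arg(initialization)
  stopifnot(grid_spacing > 0, time_step_divisor >= 2L, n_cycles >= 1L,
            linear_solve_tolerance > 0, n_store >= 2L)
  structure(list(grid_spacing = grid_spacing,
                 time_step_divisor = as.integer(time_step_divisor),
                 n_cycles = as.integer(n_cycles), time_scheme = time_scheme,
                 linear_solve_tolerance = linear_solve_tolerance,
                 initialization = initialization,
                 n_store = as.integer(n_store)),
            class = "solver_config")
}

#' Blunt (spatially uniform) inlet velocity profile
#'
#' `v(t) = Q(t) / A` over the inlet lumen, the uniform profile imposed at
#' the caudal end of the model.
#'
#' @param waveform A `flow_waveform` with the zero-net-flow offset applied.
#' @param inlet_section The inlet `sss_section`.
#' @return List with `velocity_cm_s` (per phase), `area_mm2` and the phase
#'   times.
#' @export
build_inlet_profile <- function(waveform, inlet_section) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!waveform$offset_applied) {
    stop("inlet waveform must have the zero-net-flow offset applied")
  }
  a <- section_area(inlet_section)
  if (a <= 0) stop("inlet section has zero area")
  # mL/s over mm^2: 1000 mm^3/s / mm^2 = mm/s -> /10 cm/s
  list(velocity_cm_s = waveform$samples * 1000 / a / 10,
       area_mm2 = a, times = phase_times(waveform$cycle))
}

# crude but robust estimate of the narrowest annular gap of a section (mm)
min_gap <- function(section) {
  o <- section$outer_contour
  min(dist_to_polygon(o[, 1L], o[, 2L], section$inner_contour))
}

# ---- lattice / operator assembly ------------------------------------------

# Build the masked lattice and the Shortley-Weller Laplacian (SI units,
# 1/m^2) for one section. Returns node coordinates (mm), sparse L, flux
# quadrature weights (m^2) and bookkeeping needed to paint full-grid maps.
build_section_grid <- function(section, h_mm) {
  polys <- c(list(section$outer_contour, section$inner_contour),
             section$inclusions)
  bb <- apply(section$outer_contour, 2L, range)
  x <- seq(bb[1L, 1L] - h_mm, bb[2L, 1L] + h_mm, by = h_mm)
  y <- seq(bb[1L, 2L] - h_mm, bb[2L, 2L] + h_mm, by = h_mm)
  nx <- length(x); ny <- length(y)
  gx <- rep(x, times = ny); gy <- rep(y, each = nx)
  inside <- points_in_polygon(gx, gy, section$outer_contour) &
    !points_in_polygon(gx, gy, section$inner_contour)
  for (inc in section$inclusions) {
    inside <- inside & !points_in_polygon(gx, gy, inc)
  }
  idx <- which(inside)
  N <- length(idx)
  if (N < 25L) stop("grid too coarse for this section")
  node_of <- integer(nx * ny); node_of[idx] <- seq_len(N)

  # neighbour linear indices on the full lattice
  ie <- idx + 1L; iw <- idx - 1L; in_ <- idx + nx; is_ <- idx - nx
  nbr <- cbind(E = ie, W = iw, N = in_, S = is_)
  dirs <- list(E = c(1, 0), W = c(-1, 0), N = c(0, 1), S = c(0, -1))

  theta <- matrix(1, N, 4L, dimnames = list(NULL, c("E", "W", "N", "S")))
  nbr_node <- matrix(0L, N, 4L, dimnames = list(NULL, c("E", "W", "N", "S")))
  for (d in 1:4) {
    ok <- nbr[, d] >= 1L & nbr[, d] <= nx * ny
    has <- ok & inside[pmax(nbr[, d], 1L)]
    nbr_node[has, d] <- node_of[nbr[has, d]]
    cut <- which(!has)
    for (i in cut) {
      p <- c(gx[idx[i]], gy[idx[i]])
      th <- ray_boundary_distance(p, dirs[[d]], polys, h_mm) / h_mm
      # tiny floor only guards exact-on-wall nodes; a larger floor would
      # shift the wall by O(floor*h) and degrade convergence to first order
      theta[i, d] <- min(max(th, 1e-3), 1)
    }
  }

  h <- h_mm * 1e-3
  tE <- theta[, "E"]; tW <- theta[, "W"]; tN <- theta[, "N"]; tS <- theta[, "S"]
  dg <- -(2 / h^2) * (1 / (tE * tW) + 1 / (tN * tS))
  ii <- seq_len(N); jj <- ii; xx <- dg
  addc <- function(d, tA, tB) {
    has <- nbr_node[, d] > 0L
    ii <<- c(ii, which(has)); jj <<- c(jj, nbr_node[has, d])
    xx <<- c(xx, (2 / h^2) / (tA[has] * (tA[has] + tB[has])))
  }
  addc("E", tE, tW); addc("W", tW, tE); addc("N", tN, tS); addc("S", tS, tN)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))

  # cut-cell flux quadrature weights
  fx <- pmin(1, (tE + tW) / 2); fy <- pmin(1, (tN + tS) / 2)
  fw <- h^2 * fx * fy

  list(x = x, y = y, nx = nx, ny = ny, idx = idx, N = N,
       px = gx[idx], py = gy[idx], L = L, flux_w = fw, h_mm = h_mm)
}

# harmonic content of a dense forcing waveform
harmonics_of_dense <- function(dense_waveform) {
  if (!is.null(dense_waveform$harmonics)) return(dense_waveform$harmonics)
  n <- length(dense_waveform$samples)
  waveform_harmonics(flow_waveform(dense_waveform$samples,
                                   cardiac_cycle(dense_waveform$period_T, n)))
}

# solve (lambda I - mu L) u = 1 for complex lambda via the equivalent real
# 2N block system
complex_unit_solve <- function(L, mu, lambda, N) {
  Ar <- Matrix::Diagonal(N, Re(lambda)) - mu * L
  Ai <- Matrix::Diagonal(N, Im(lambda))
  A2 <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  u <- as.numeric(Matrix::solve(A2, c(rep(1, N), rep(0, N))))
  complex(real = u[seq_len(N)], imaginary = u[N + seq_len(N)])
}

# characteristic polynomial factor of the stepping scheme at z = e^{i w dt}:
# lambda(z) such that the discrete-periodic response solves
# (lambda I - mu L) w_hat = G_hat
scheme_lambda <- function(scheme, rho, dt, omega) {
  z <- exp(1i * omega * dt)
  if (scheme == "implicit_first_order") rho * (1 - 1 / z) / dt
  else rho * (1.5 - 2 / z + 0.5 / z^2) / dt
}

#' Solve pulsatile flow through one cross-section
#'
#' Implicit time marching of the flow-rate-constrained sectionwise momentum
#' balance. Each step performs one sparse solve with the prefactorised
#' implicit operator plus a scalar update of the pressure gradient `G(t)`
#' chosen so the areal flux equals the prescribed `Q(t)` (superposition with
#' a precomputed unit-forcing solution). With the default periodic
#' initialization the start state is the harmonic-balance solution of the
#' same discrete operator, so the march carries no start-up transient and
#' temporal periodicity holds to round-off.
#'
#' @param section An `sss_section`.
#' @param dense_waveform A `dense_waveform` from [interpolate_waveform()]
#'   (mL/s at `T/divisor` sampling).
#' @param fluid A [fluid_properties()].
#' @param config A [solver_config()]; the lattice must resolve the narrowest
#'   gap with at least 10 points.
#' @return A `section_flow_solution`: final-cycle velocity snapshots (cm/s)
#'   on the masked lattice, the pressure-gradient series `G` (Pa/m), the
#'   Womersley number `alpha`, the peak-systolic step `t_sys`, and the flux
#'   and periodicity diagnostics.
#' @export
solve_pulsatile_section <- function(section, dense_waveform,
                                    fluid = fluid_properties(),
                                    config = solver_config()) {
  stopifnot(inherits(section, "sss_section"),
            inherits(dense_waveform, "dense_waveform"))
  gap <- min_gap(section)
  # 5% slack absorbs the chord error of polygonised circular contours
  if (gap / config$grid_spacing < 9.5) {
    stop(sprintf(paste0("grid spacing %.3g mm resolves the %.2f mm gap with ",
                        "fewer than 10 points"),
                 config$grid_spacing, gap))
  }
  g <- build_section_grid(section, config$grid_spacing)
  rho <- fluid$density_rho; mu <- fluid$dynamic_viscosity_mu
  Tt <- dense_waveform$period_T
  Nd <- dense_waveform$divisor %||% length(dense_waveform$samples)
  dt <- Tt / Nd
  Q <- dense_waveform$samples * 1e-6            # mL/s -> m^3/s
  second <- config$time_scheme == "implicit_second_order"
  c0 <- if (second) 1.5 * rho / dt else rho / dt

  M <- Matrix::Diagonal(g$N, c0) - mu * g$L
  fact <- Matrix::lu(M)
  ones <- rep(1, g$N)
  w_unit <- as.numeric(Matrix::solve(fact, ones))
  F_unit <- sum(g$flux_w * w_unit)
  flux_of <- function(w) sum(g$flux_w * w)

  h <- harmonics_of_dense(dense_waveform)
  w1 <- 2 * pi / Tt

  # initial states (SI velocities) at steps -1 and 0
  if (config$initialization == "periodic") {
    state_at <- build_periodic_state(g, mu, rho, dt, h, config$time_scheme)
    w_prev2 <- state_at(-dt); w_prev <- state_at(0)
  } else {
    w_prev2 <- w_prev <- numeric(g$N)
  }

  n_steps <- config$n_cycles * Nd
  stride <- max(1L, Nd %/% min(config$n_store, Nd))
  keep_local <- seq(1L, Nd, by = stride)         # sample indices kept
  n_keep <- length(keep_local)
  snap_last <- matrix(0, g$N, n_keep)
  snap_prev <- matrix(0, g$N, n_keep)
  G_series <- numeric(Nd)
  t_sys <- which.min(Q); t_dia <- which.max(Q)
  w_sys <- w_dia <- NULL
  max_flux_err <- 0
  q_scale <- max(abs(Q), 1e-300)

  for (j in seq_len(n_steps)) {
    jc <- j %% Nd + 1L    # sample index of time j*dt (Q[i] is at (i-1)*dt)
    b <- if (second) (rho / dt) * (2 * w_prev - 0.5 * w_prev2) else c0 * w_prev
    w0 <- as.numeric(Matrix::solve(fact, b))
    G <- (Q[jc] - flux_of(w0)) / F_unit
    w <- w0 + G * w_unit

    max_flux_err <- max(max_flux_err, abs(flux_of(w) - Q[jc]) / q_scale)
    if (j %% 25L == 0L || j == n_steps) {
      r <- as.numeric(M %*% w) - b - G
      scale <- max(sqrt(mean((b + G)^2)), 1e-300)
      if (sqrt(mean(r^2)) > config$linear_solve_tolerance * scale) {
        stop(sprintf("implicit solve residual %.3g exceeds tolerance %.3g",
                     sqrt(mean(r^2)) / scale, config$linear_solve_tolerance))
      }
    }

    cyc <- (j - 1L) %/% Nd + 1L
    k <- match(jc, keep_local)  # slot by sample index; each cycle covers 1..Nd
    if (!is.na(k)) {
      if (cyc == config$n_cycles) snap_last[, k] <- w
      if (cyc == config$n_cycles - 1L) snap_prev[, k] <- w
    }
    if (cyc == config$n_cycles) {
      G_series[jc] <- G
      if (jc == t_sys) w_sys <- w
      if (jc == t_dia) w_dia <- w
    }
    w_prev2 <- w_prev; w_prev <- w
  }

  w_scale <- max(abs(snap_last), 1e-300)
  periodicity <- if (config$n_cycles >= 2L) {
    max(abs(snap_last - snap_prev)) / w_scale
  } else NA_real_
  area_m2 <- sum(g$flux_w)
  wetted <- polygon_perimeter(section$outer_contour) +
    polygon_perimeter(section$inner_contour) +
    sum(vapply(section$inclusions, polygon_perimeter, numeric(1)))
  L_gap <- 2 * section_area(section) / wetted    # mm; = gap width for a thin annulus

  structure(list(
    section = section, grid = g[c("x", "y", "nx", "ny", "idx", "N",
                                  "px", "py", "h_mm", "flux_w")],
    w = 100 * snap_last,                         # cm/s snapshots, final cycle
    snapshot_steps = keep_local,
    snapshot_times = (keep_local - 1L) * dt,
    w_sys = 100 * w_sys, w_dia = 100 * w_dia,
    pressure_gradient_G = G_series,
    t_sys = t_sys, t_dia = t_dia, dt = dt, period_T = Tt,
    womersley_alpha = womersley_number(L_gap, w1, rho, mu),
    Q_mL_s = dense_waveform$samples,
    max_flux_rel_err = max_flux_err,
    periodicity_rel = periodicity,
    fluid = fluid, config = config), class = "section_flow_solution")
}

# harmonic-balance periodic state of the discrete stepping operator:
# returns a function of time evaluating the periodic solution (SI m/s)
build_periodic_state <- function(g, mu, rho, dt, h, scheme) {
  N <- g$N
  modes <- list()
  if (abs(h$mean) > 0) {
    u0 <- as.numeric(Matrix::solve(-mu * g$L, rep(1, N)))
    modes$steady <- (h$mean * 1e-6 / sum(g$flux_w * u0)) * u0
  } else modes$steady <- numeric(N)
  w1 <- 2 * pi / h$period_T
  ks <- h$k; amps <- complex(real = h$a, imaginary = -h$b)
  if (!is.na(h$nyquist_k) && h$nyquist != 0) {
    ks <- c(ks, h$nyquist_k); amps <- c(amps, as.complex(h$nyquist))
  }
  keep <- Mod(amps) > 1e-13 * max(Mod(amps), 1e-300)
  ks <- ks[keep]; amps <- amps[keep] * 1e-6      # m^3/s
  osc <- lapply(seq_along(ks), function(i) {
    lam <- scheme_lambda(scheme, rho, dt, w1 * ks[i])
    u <- complex_unit_solve(g$L, mu, lam, N)
    (amps[i] / sum(g$flux_w * u)) * u
  })
  function(t) {
    w <- modes$steady
    for (i in seq_along(ks)) {
      w <- w + Re(osc[[i]] * exp(1i * w1 * ks[i] * t))
    }
    w
  }
}

# paint a full-lattice matrix (nx x ny) from node values; `fill` outside
solution_map <- function(solution, values, fill = NA_real_) {
  m <- matrix(fill, solution$grid$nx, solution$grid$ny)
  m[solution$grid$idx] <- values
  m
}

#' Thru-plane velocity maps and CFD metrics at an axial plane
#'
#' @param solutions A single `section_flow_solution` or a list of them (one
#'   per level).
#' @param level_label Level to extract when a list is given.
#' @return List with `map_systole` and `map_diastole` (full-lattice matrices,
#'   cm/s, `NA` outside the lumen), grid axes, and `metrics` (a one-row
#'   data.frame with `method = "cfd"` peak velocities and stroke volume).
#' @export
sample_solution_on_plane <- function(solutions, level_label = NULL) {
  sol <- if (inherits(solutions, "section_flow_solution")) solutions else {
    lv <- vapply(solutions, function(s) s$section$level_label, character(1))
    i <- match(level_label, lv)
    if (is.na(i)) stop(sprintf("no solution at level '%s'", level_label))
    solutions[[i]]
  }
  all_w <- cbind(sol$w, sol$w_sys, sol$w_dia)
  sv <- 0.5 * sol$period_T * mean(abs(sol$Q_mL_s))
  metrics <- data.frame(
    level_label = sol$section$level_label, method = "cfd",
    peak_systolic = min(0, min(all_w)), peak_diastolic = max(0, max(all_w)),
    stroke_volume = sv, stringsAsFactors = FALSE)
  list(map_systole = solution_map(sol, sol$w_sys),
       map_diastole = solution_map(sol, sol$w_dia),
       x = sol$grid$x, y = sol$grid$y, metrics = metrics)
}

#' Sample a solution along a probe vector
#'
#' Bilinear interpolation of the peak-systolic velocity field along a probe
#' (n x 2 matrix of points, mm).
#'
#' @param solution A `section_flow_solution`.
#' @param probe n x 2 matrix of in-plane points (mm).
#' @return Velocities in cm/s (0 outside the lumen).
#' @export
probe_velocity <- function(solution, probe) {
  Z <- solution_map(solution, solution$w_sys, fill = 0)
  # interp2 expects Z with rows indexed by y
  v <- pracma::interp2(solution$grid$x, solution$grid$y, t(Z),
                       pmin(pmax(probe[, 1L], min(solution$grid$x)),
                            max(solution$grid$x)),
                       pmin(pmax(probe[, 2L], min(solution$grid$y)),
                            max(solution$grid$y)))
  v[is.na(v)] <- 0
  v
}

#' Probe vector across the anterior gap of a section
#'
#' A line of points from the cord boundary to the dura along +y (anterior)
#' through the cord centroid.
#'
#' @param section An `sss_section`.
#' @param n Number of probe points.
#' @export
default_probe <- function(section, n = 101L) {
  c0 <- polygon_centroid(section$inner_contour)
  d_in <- ray_boundary_distance(c0, c(0, 1), list(section$inner_contour), 50)
  d_out <- ray_boundary_distance(c0, c(0, 1), list(section$outer_contour), 50)
  y <- seq(c0[2L] + d_in + 1e-6, c0[2L] + d_out - 1e-6, length.out = n)
  cbind(rep(c0[1L], n), y)
}

#' Maximum relative error between two probe samples
#'
#' `e = 100 * max_x |V_fine(x) - V_coarse(x)| / max_x |V_fine(x)|`, the
#' grid-comparison metric used for the independence studies.
#'
#' @param V_fine,V_coarse Velocities sampled at co-located probe points.
#' @return `e` in percent.
#' @export
grid_relative_error <- function(V_fine, V_coarse) {
  stopifnot(length(V_fine) == length(V_coarse))
  denom <- max(abs(V_fine))
  if (denom == 0) stop("reference probe velocities are identically zero")
  100 * max(abs(V_fine - V_coarse)) / denom
}

#' Grid and time-step independence study
#'
#' Solves the given sections at three strictly refining grid spacings and
#' compares peak-systolic probe velocities pairwise (coarse-medium and
#' medium-fine), then sweeps three time-step divisors at the middle grid and
#' reports the successive solution differences.
#'
#' @param sections Named list of `sss_section` (e.g. the FM, C3 and C7
#'   planes).
#' @param waveform A `flow_waveform` driving the flow.
#' @param fluid A [fluid_properties()].
#' @param config Base [solver_config()]; its divisor is used for the grid
#'   sweep.
#' @param grid_spacings Three strictly decreasing spacings (mm).
#' @param divisors Three strictly increasing time-step divisors.
#' @return A `convergence_result` with per-plane `e` values (percent), node
#'   counts, time-sweep differences and the probes used.
#' @export
independence_study <- function(sections, waveform,
                               fluid = fluid_properties(),
                               config = solver_config(),
                               grid_spacings = c(0.4, 0.2, 0.1),
                               divisors = c(100L, 1000L, 10000L)) {
  if (inherits(sections, "sss_section")) sections <- list(sections)
  stopifnot(length(grid_spacings) == 3L, length(divisors) == 3L)
  if (any(diff(grid_spacings) >= 0)) {
    stop("grid spacings must be strictly decreasing (refining)")
  }
  if (any(diff(divisors) <= 0)) stop("divisors must be strictly increasing")
  dense <- interpolate_waveform(waveform, config$time_step_divisor)

  per_plane <- lapply(sections, function(sec) {
    probe <- default_probe(sec)
    V <- list(); sizes <- integer(3L)
    for (i in 1:3) {
      cf <- config; cf$grid_spacing <- grid_spacings[i]
      sol <- solve_pulsatile_section(sec, dense, fluid, cf)
      V[[i]] <- probe_velocity(sol, probe)
      sizes[i] <- sol$grid$N
    }
    # time sweep at the middle grid
    cf <- config; cf$grid_spacing <- grid_spacings[2L]
    Vt <- lapply(divisors, function(d) {
      probe_velocity(solve_pulsatile_section(
        sec, interpolate_waveform(waveform, d), fluid, cf), probe)
    })
    list(level = sec$level_label, probe = probe, grid_sizes = sizes,
         e_coarse_medium = grid_relative_error(V[[2L]], V[[1L]]),
         e_medium_fine = grid_relative_error(V[[3L]], V[[2L]]),
         time_diff_12 = max(abs(Vt[[2L]] - Vt[[1L]])),
         time_diff_23 = max(abs(Vt[[3L]] - Vt[[2L]])))
  })
  e_cm <- vapply(per_plane, `[[`, numeric(1), "e_coarse_medium")
  e_mf <- vapply(per_plane, `[[`, numeric(1), "e_medium_fine")
  structure(list(
    plane_labels = vapply(per_plane, `[[`, character(1), "level"),
    per_plane = per_plane,
    e_coarse_medium = max(e_cm), e_medium_fine = max(e_mf),
    grid_spacings = grid_spacings, divisors = divisors,
    time_monotone = all(vapply(per_plane, function(p)
      p$time_diff_23 < p$time_diff_12, logical(1)))),
    class = "convergence_result")
}

#' Export a section solution as a legacy-VTK structured grid
#'
#' Writes the peak-systolic and peak-diastolic thru-plane velocity fields
#' (cm/s, 0 outside the lumen) on the solver lattice as STRUCTURED_POINTS
#' scalars readable by VTK-compatible viewers.
#'
#' @param solution A `section_flow_solution`.
#' @param path Output `.vtk` file.
#' @export
write_solution_vtk <- function(solution, path) {
  g <- solution$grid
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("sectionwise solution, level %s",
                       solution$section$level_label),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               sprintf("ORIGIN %g %g 0", g$x[1L], g$y[1L]),
               sprintf("SPACING %g %g 1", g$h_mm, g$h_mm),
               sprintf("POINT_DATA %d", g$nx * g$ny)), con)
  for (nm in c("w_sys", "w_dia")) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(as.vector(solution_map(solution, solution[[nm]],
                                             fill = 0)),
                      digits = 7, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Dump probe velocities as CSV
#'
#' Columns `x_mm`, `y_mm`, `w_cm_s`: peak-systolic thru-plane velocity
#' along a probe vector.
#'
#' @param solution A `section_flow_solution`.
#' @param probe n x 2 probe points (mm); default the anterior-gap probe.
#' @param path Output CSV.
#' @export
write_probe_csv <- function(solution, path,
                            probe = default_probe(solution$section)) {
  utils::write.csv(data.frame(x_mm = probe[, 1L], y_mm = probe[, 2L],
                              w_cm_s = probe_velocity(solution, probe)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
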