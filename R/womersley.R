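# Analytic references for pulsatile axial flow in a concentric circular
# annulus: steady (Poiseuille) and oscillatory (Womersley-type, assembled
# from modified Bessel functions of complex argument). These closed forms
# are independent of the finite-difference solver and serve as its
# verification oracles.

# ---- modified Bessel functions of complex argument ------------------------
#
# I0 and K0 for complex z with Re(z) >= 0. Power series for |z| <= 10,
# large-argument asymptotic expansions beyond. For the arguments arising
# here (arg z = pi/4 from sqrt(i)) the worst-case relative accuracy is
# ~1e-8 at the switch radius and better elsewhere; ample for solver
# verification at the percent level.

#' Modified Bessel functions I0 and K0 for complex argument
#'
#' Valid for `Re(z) >= 0`; vectorised over `z`.
#'
#' @param z Complex vector.
#' @return Complex vector.
#' @export
bessel_I0 <- function(z) vapply(z, bessel_I0_one, complex(1))

#' @rdname bessel_I0
#' @export
bessel_K0 <- function(z) vapply(z, bessel_K0_one, complex(1))

bessel_I0_one <- function(z) {
  z <- as.complex(z)
  if (Mod(z) <= 10) {
    term <- 1 + 0i; s <- term; q <- z * z / 4
    for (m in 1:60) {
      term <- term * q / (m * m)
      s <- s + term
      if (Mod(term) < 1e-17 * Mod(s)) break
    }
    s
  } else {
    bessel_asym(z, kind = "I")
  }
}

bessel_K0_one <- function(z) {
  z <- as.complex(z)
  if (Mod(z) <= 10) {
    gamma_e <- 0.57721566490153286
    term <- 1 + 0i; i0 <- term; s <- 0 + 0i; h <- 0
    q <- z * z / 4
    for (m in 1:60) {
      term <- term * q / (m * m)
      h <- h + 1 / m
      i0 <- i0 + term
      s <- s + term * h
      if (Mod(term) < 1e-17 * max(Mod(i0), 1)) break
    }
    -(log(z / 2) + gamma_e) * i0 + s
  } else {
    bessel_asym(z, kind = "K")
  }
}

# large-|z| expansions:
#   I0(z) ~ e^z / sqrt(2 pi z) * sum_k (-1)^k u_k / z^k
#   K0(z) ~ sqrt(pi/(2 z)) e^-z * sum_k u_k / z^k
# with u_k = prod_{j=1..k} -(2j-1)^2 / (8 k!) cumulatively; truncated at the
# smallest term.
bessel_asym <- function(z, kind) {
  s <- 1 + 0i; term <- 1 + 0i; prev <- Inf
  sgn <- if (kind == "I") 1 else -1
  for (k in 1:40) {
    term <- term * sgn * (2 * k - 1)^2 / (8 * k * z)
    if (Mod(term) >= prev) break  # divergence point of the asymptotic series
    s <- s + term
    prev <- Mod(term)
    if (prev < 1e-17 * Mod(s)) break
  }
  if (kind == "I") exp(z) / sqrt(2 * pi * z) * s
  else sqrt(pi / (2 * z)) * exp(-z) * s
}

# ---- steady annulus (Poiseuille) ------------------------------------------

#' Steady pressure-driven axial flow in a concentric annulus
#'
#' Closed-form profile
#' `w(r) = G/(4 mu) * (r_o^2 - r^2 + (r_o^2 - r_i^2) ln(r/r_o)/ln(r_o/r_i))`
#' for driving pressure gradient `G = -dp/dz`.
#'
#' @param r Radii (mm) at which to evaluate.
#' @param r_i,r_o Inner and outer radii (mm), `0 < r_i < r_o`.
#' @param G Driving pressure gradient in Pa/m.
#' @param mu Dynamic viscosity in Pa s.
#' @return Axial velocity in cm/s at `r` (0 outside `[r_i, r_o]`).
#' @export
poiseuille_annulus <- function(r, r_i, r_o, G = 1, mu = 1e-3) {
  stopifnot(r_i > 0, r_o > r_i)
  rm <- r * 1e-3; ri <- r_i * 1e-3; ro <- r_o * 1e-3
  w <- G / (4 * mu) * (ro^2 - rm^2 + (ro^2 - ri^2) * log(rm / ro) / log(ro / ri))
  w[r < r_i | r > r_o] <- 0
  100 * w  # m/s -> cm/s
}

#' @rdname poiseuille_annulus
#' @param Q Target volumetric flow (mL/s); `G` is scaled to deliver it.
#' @export
poiseuille_annulus_flow <- function(r, r_i, r_o, Q, mu = 1e-3) {
  q_unit <- annulus_profile_flux(function(rr) poiseuille_annulus(rr, r_i, r_o, 1, mu),
                                 r_i, r_o)
  poiseuille_annulus(r, r_i, r_o, G = Q / q_unit, mu = mu)
}

# flux (mL/s) of a radial profile w(r) [cm/s] over the annulus [r_i, r_o] mm,
# by composite Simpson quadrature on a fine radial grid
annulus_profile_flux <- function(wfun, r_i, r_o, n = 2001L) {
  if (n %% 2L == 0L) n <- n + 1L
  r <- seq(r_i, r_o, length.out = n)
  f <- 2 * pi * r * wfun(r)            # mm * cm/s = 10 mm^2/s per mm
  h <- (r_o - r_i) / (n - 1L)
  wts <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  integral <- h / 3 * sum(wts * f)     # mm * (mm * cm/s) = 10 mm^3/s
  integral * 10 / 1000                 # -> mm^3/s -> mL/s
}

# ---- oscillatory annulus (Womersley-type) ---------------------------------

# complex profile for unit driving gradient amplitude G = 1 Pa/m at angular
# frequency omega: w_hat(r) = 1/(i omega rho) [1 - C1 I0(kr) - C2 K0(kr)],
# k = sqrt(i omega rho / mu), no-slip at r_i and r_o. r in mm, result m/s.
# Assembled from exponentially scaled Bessel factors so that high Womersley
# numbers (large |k r|) neither overflow nor lose the boundary layers.
womersley_mode_profile <- function(r, r_i, r_o, omega, rho, mu) {
  k <- sqrt(1i * omega * rho / mu)     # arg pi/4, Re > 0
  zi <- k * (r_i * 1e-3); zo <- k * (r_o * 1e-3)
  i0s <- function(z) vapply(z, function(zz) bessel_I0_one(zz) * exp(-zz),
                            complex(1))
  k0s <- function(z) vapply(z, function(zz) bessel_K0_one(zz) * exp(zz),
                            complex(1))
  # phi_I(r) = I0(kr)/I0(k r_o), phi_K(r) = K0(kr)/K0(k r_i): both bounded
  # by 1 in modulus on [r_i, r_o]
  phi_I <- function(z) i0s(z) / i0s(zo) * exp(z - zo)
  phi_K <- function(z) k0s(z) / k0s(zi) * exp(zi - z)
  e1 <- phi_I(zi); e2 <- phi_K(zo)
  M <- matrix(c(e1, 1 + 0i, 1 + 0i, e2), 2, 2)
  C <- solve(M, c(1 + 0i, 1 + 0i))     # well conditioned: off-diagonal 1s
  z <- k * (r * 1e-3)
  (1 - C[1L] * phi_I(z) - C[2L] * phi_K(z)) / (1i * omega * rho)
}

#' Oscillatory (Womersley-type) axial flow in a concentric annulus
#'
#' Analytic flow-driven solution for a prescribed periodic flow waveform:
#' the waveform is decomposed into Fourier harmonics; the steady part uses
#' the Poiseuille closed form and each oscillatory harmonic the modified
#' Bessel-function (I0, K0 of complex argument) profile, with the complex
#' pressure-gradient amplitude of every harmonic scaled so its areal flux
#' matches the corresponding flow harmonic.
#'
#' @param waveform A `flow_waveform` (mL/s) prescribing the areal flux.
#' @param r_i,r_o Annulus radii (mm).
#' @param fluid A [fluid_properties()].
#' @return Object of class `womersley_annulus` with `$velocity(r, t)`
#'   (mm, s -> cm/s, vectorised over `r`), the per-harmonic complex
#'   pressure-gradient amplitudes `$G_hat` (Pa/m) and the Womersley number
#'   `$alpha` of the fundamental based on the gap width `r_o - r_i`.
#' @export
womersley_annulus <- function(waveform, r_i, r_o, fluid = fluid_properties()) {
  stopifnot(inherits(waveform, "flow_waveform"), r_i > 0, r_o > r_i)
  h <- waveform_harmonics(waveform)
  rho <- fluid$density_rho; mu <- fluid$dynamic_viscosity_mu
  w1 <- 2 * pi / h$period_T

  ks <- h$k
  amps <- complex(real = h$a, imaginary = -h$b)   # Q(t)=Re[amp e^{i w k t}]
  if (!is.na(h$nyquist_k) && h$nyquist != 0) {
    ks <- c(ks, h$nyquist_k)
    amps <- c(amps, complex(real = h$nyquist, imaginary = 0))
  }
  keep <- Mod(amps) > 1e-12 * max(Mod(amps), 1e-300)
  ks <- ks[keep]; amps <- amps[keep]

  # unit-gradient profiles and their fluxes, per harmonic
  modes <- lapply(seq_along(ks), function(i) {
    om <- w1 * ks[i]
    prof <- function(r) womersley_mode_profile(r, r_i, r_o, om, rho, mu)
    qc <- annulus_complex_flux(prof, r_i, r_o)    # mL/s per unit G
    G <- amps[i] / qc
    list(k = ks[i], omega = om, G = G, prof = prof)
  })
  G0 <- if (abs(h$mean) > 0) {
    q_unit <- annulus_profile_flux(function(rr)
      poiseuille_annulus(rr, r_i, r_o, 1, mu), r_i, r_o)
    h$mean / q_unit
  } else 0

  velocity <- function(r, t) {
    stopifnot(length(t) == 1L)
    w <- if (G0 != 0) poiseuille_annulus(r, r_i, r_o, G0, mu) else numeric(length(r))
    for (m in modes) {
      wm <- m$prof(r) * 100   # m/s -> cm/s
      w <- w + Re(m$G * wm * exp(1i * m$omega * t))
      w[r < r_i | r > r_o] <- 0
    }
    w
  }
  gap <- r_o - r_i
  structure(list(velocity = velocity, r_i = r_i, r_o = r_o,
                 G0 = G0, G_hat = vapply(modes, `[[`, complex(1), "G"),
                 harmonic_k = ks,
                 alpha = womersley_number(gap, w1, rho, mu),
                 period_T = h$period_T),
            class = "womersley_annulus")
}

# complex areal flux (mL/s) of a complex radial profile [m/s]
annulus_complex_flux <- function(prof, r_i, r_o, n = 2001L) {
  if (n %% 2L == 0L) n <- n + 1L
  r <- seq(r_i, r_o, length.out = n)
  f <- 2 * pi * (r * 1e-3) * prof(r)   # m * m/s
  h <- (r_o - r_i) * 1e-3 / (n - 1L)
  wts <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  (h / 3 * sum(wts * f)) * 1e6         # m^3/s -> mL/s
}

#' Womersley number
#'
#' `alpha = L * sqrt(omega * rho / mu)` for characteristic length `L`.
#'
#' @param L_mm Characteristic length in mm (here: the annular gap width).
#' @param omega Angular frequency (rad/s).
#' @param rho Density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @export
womersley_number <- function(L_mm, omega, rho, mu) {
  (L_mm * 1e-3) * sqrt(omega * rho / mu)
}
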