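# Cardiac cycle and volumetric flow waveforms.
#
# A waveform holds the volumetric CSF flow rate (mL/s) at the uniformly
# spaced phase times t_k = k*T/n of one cardiac cycle [0, T). Caudal
# (systolic, foot-directed) flow is negative, cranial (diastolic) positive.
# On a uniform periodic grid the trapezoidal cycle mean reduces to the plain
# sample mean, which is what all cycle integrals below use.

#' Cardiac cycle timing
#'
#' @param period_T Cycle length in seconds.
#' @param n_phases Number of reconstructed phases (>= 2); phase times are
#'   `k * period_T / n_phases`, `k = 0, ..., n_phases - 1`.
#' @export
cardiac_cycle <- function(period_T = 1, n_phases = 30L) {
  stopifnot(period_T > 0, n_phases >= 2L)
  structure(list(period_T = as.numeric(period_T),
                 n_phases = as.integer(n_phases)),
            class = "cardiac_cycle")
}

#' Phase times of a cardiac cycle
#' @param cycle A [cardiac_cycle()].
#' @return Times `k * T / n`, `k = 0, ..., n - 1`, in seconds.
#' @export
phase_times <- function(cycle) {
  cycle$period_T * (seq_len(cycle$n_phases) - 1L) / cycle$n_phases
}

#' Construct a flow waveform
#'
#' @param samples Flow rate (mL/s) at the cycle phase times.
#' @param cycle A [cardiac_cycle()]; `n_phases` must equal `length(samples)`.
#' @param level_label Axial level the waveform was measured at.
#' @param offset_applied,applied_offset_value Zero-net-flow offset bookkeeping
#'   (see [offset_to_zero_net()]).
#' @export
flow_waveform <- function(samples, cycle, level_label = "INLET",
                          offset_applied = FALSE, applied_offset_value = 0) {
  samples <- as.numeric(samples)
  stopifnot(inherits(cycle, "cardiac_cycle"),
            length(samples) == cycle$n_phases, all(is.finite(samples)))
  level_label <- match.arg(level_label, SECTION_LEVELS)
  structure(list(level_label = level_label, samples = samples, cycle = cycle,
                 offset_applied = isTRUE(offset_applied),
                 applied_offset_value = as.numeric(applied_offset_value)),
            class = "flow_waveform")
}

#' Periodic-trapezoid cycle mean of a waveform
#' @param waveform A `flow_waveform`.
#' @return Mean flow in mL/s.
#' @export
cycle_mean <- function(waveform) mean(waveform$samples)

#' Offset a flow waveform to zero net flow per cycle
#'
#' Subtracts the periodic cycle mean (a constant) from every sample so the
#' net CSF flow over one cardiac cycle vanishes, recording the offset that
#' was added. Applying the offset twice is a no-op.
#'
#' @param waveform A `flow_waveform`.
#' @return The offset waveform with `offset_applied = TRUE`.
#' @export
offset_to_zero_net <- function(waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  off <- -cycle_mean(waveform)
  # a mean at round-off level is treated as zero so that re-offsetting an
  # already balanced waveform is exactly the identity
  if (abs(off) <= 1e-15 * max(abs(waveform$samples), 1e-300)) off <- 0
  flow_waveform(waveform$samples + off, waveform$cycle, waveform$level_label,
                offset_applied = TRUE,
                applied_offset_value = waveform$applied_offset_value + off)
}

#' Peak flow magnitude of a waveform
#' @param waveform A `flow_waveform`.
#' @return `max |Q|` in mL/s.
#' @export
peak_flow <- function(waveform) max(abs(waveform$samples))

#' Select the inlet boundary-condition waveform
#'
#' Returns the waveform with the greatest peak flow rate `max |Q(t)|`;
#' exact ties are broken in favour of the more caudal level.
#'
#' @param waveforms Non-empty list of `flow_waveform`.
#' @return List with elements `level_label` and `waveform`.
#' @export
select_inlet_waveform <- function(waveforms) {
  if (length(waveforms) < 1L) stop("need at least one waveform")
  stopifnot(all(vapply(waveforms, inherits, logical(1), "flow_waveform")))
  peaks <- vapply(waveforms, peak_flow, numeric(1))
  ranks <- vapply(waveforms, function(w) level_rank(w$level_label), numeric(1))
  best <- which(peaks == max(peaks))
  pick <- best[which.min(ranks[best])]
  list(level_label = waveforms[[pick]]$level_label,
       waveform = waveforms[[pick]])
}

#' Stroke volume of a CSF flow waveform
#'
#' Half the cycle integral of the absolute flow rate (periodic trapezoid):
#' the oscillatory volume traversing the plane per cardiac cycle.
#'
#' @param waveform A `flow_waveform` (mL/s).
#' @return Stroke volume in mL.
#' @export
stroke_volume <- function(waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  0.5 * waveform$cycle$period_T * mean(abs(waveform$samples))
}

# Real Fourier coefficients of the waveform samples: Q(t) ~ a0/2? No --
# returns list(mean, k, a, b, nyquist) such that
#   Q(t) = mean + sum_k [a_k cos(w_k t) + b_k sin(w_k t)] (+ Nyquist cosine)
# with w_k = 2*pi*k/T. The Nyquist term (even n only) is a pure cosine.
waveform_harmonics <- function(waveform) {
  q <- waveform$samples
  n <- length(q)
  Tt <- waveform$cycle$period_T
  X <- stats::fft(q) / n
  kmax <- floor((n - 1) / 2)
  k <- seq_len(kmax)
  out <- list(mean = Re(X[1L]), period_T = Tt, k = k,
              a = 2 * Re(X[k + 1L]), b = -2 * Im(X[k + 1L]),
              nyquist = if (n %% 2L == 0L) Re(X[n / 2 + 1L]) else 0,
              nyquist_k = if (n %% 2L == 0L) n / 2 else NA_integer_)
  out
}

eval_harmonics <- function(h, t) {
  w <- 2 * pi / h$period_T
  q <- rep(h$mean, length(t))
  for (i in seq_along(h$k)) {
    q <- q + h$a[i] * cos(w * h$k[i] * t) + h$b[i] * sin(w * h$k[i] * t)
  }
  if (!is.na(h$nyquist_k) && h$nyquist != 0) {
    q <- q + h$nyquist * cos(w * h$nyquist_k * t)
  }
  q
}

#' Band-limited (trigonometric) interpolant of a waveform
#'
#' @param waveform A `flow_waveform`.
#' @return A function of time (s), vectorised, evaluating the periodic
#'   trigonometric interpolant; it passes through the original samples and
#'   preserves the cycle mean exactly.
#' @export
waveform_interpolant <- function(waveform) {
  h <- waveform_harmonics(waveform)
  function(t) eval_harmonics(h, t)
}

#' Resample a waveform on a dense periodic time grid
#'
#' Trigonometric interpolation from `n_phases` samples to `divisor` samples
#' per cycle (time step `T/divisor`), as used to drive the pulsatile solver.
#' Preserves the cycle mean (hence zero-net-flow status) exactly.
#'
#' @param waveform A `flow_waveform`.
#' @param divisor Number of dense samples per cycle; must be at least
#'   `n_phases`.
#' @return A `dense_waveform`: list with `samples`, `times`, `period_T`,
#'   `divisor`, the source `harmonics` and the offset bookkeeping.
#' @export
interpolate_waveform <- function(waveform, divisor) {
  stopifnot(inherits(waveform, "flow_waveform"))
  divisor <- as.integer(divisor)
  if (divisor < waveform$cycle$n_phases) {
    stop("divisor must be >= the number of cycle phases")
  }
  h <- waveform_harmonics(waveform)
  times <- waveform$cycle$period_T * (seq_len(divisor) - 1L) / divisor
  structure(list(samples = eval_harmonics(h, times), times = times,
                 period_T = waveform$cycle$period_T, divisor = divisor,
                 harmonics = h, level_label = waveform$level_label,
                 offset_applied = waveform$offset_applied),
            class = "dense_waveform")
}

#' Two-harmonic synthetic CSF flow waveform
#'
#' Caudal-first pulse: a sharper systolic (negative, foot-directed) peak and
#' a broader diastolic return, built from the fundamental plus one second
#' harmonic, optionally with a constant baseline bias emulating the small
#' nonzero net flow that in-vivo quantification shows before the zero-net
#' offset is applied.
#'
#' @param cycle A [cardiac_cycle()].
#' @param amplitude Peak flow magnitude (mL/s) of the zero-mean pulse.
#' @param second_harmonic Relative amplitude of the second harmonic.
#' @param phase2 Phase (rad) of the second harmonic.
#' @param baseline Constant bias (mL/s) added to the pulse; 0 keeps the
#'   physiological zero-net cycle.
#' @param level_label Level tag for the returned waveform.
#' @export
make_csf_waveform <- function(cycle = cardiac_cycle(), amplitude = 2,
                              second_harmonic = 0.4, phase2 = -0.9,
                              baseline = 0, level_label = "INLET") {
  t <- phase_times(cycle)
  w <- 2 * pi / cycle$period_T
  pulse <- -(sin(w * t) + second_harmonic * sin(2 * w * t + phase2))
  pulse <- pulse - mean(pulse)
  pulse <- pulse * amplitude / max(abs(pulse))
  flow_waveform(pulse + baseline, cycle, level_label)
}

#' Write / read flow waveforms as CSV
#'
#' Columns: `level`, `phase_index`, `time_s`, `flow_mL_per_s` (frozen header).
#'
#' @param waveforms A `flow_waveform` or list thereof.
#' @param path CSV file.
#' @export
write_waveform_csv <- function(waveforms, path) {
  if (inherits(waveforms, "flow_waveform")) waveforms <- list(waveforms)
  rows <- do.call(rbind, lapply(waveforms, function(w) {
    data.frame(level = w$level_label,
               phase_index = seq_along(w$samples) - 1L,
               time_s = phase_times(w$cycle),
               flow_mL_per_s = w$samples)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param period_T Cycle length (s) used to rebuild the cycle on read.
#' @export
read_waveform_csv <- function(path, period_T = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "phase_index", "time_s", "flow_mL_per_s")
  if (!all(need %in% names(d))) {
    stop("waveform CSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(d, d$level), function(g) {
    g <- g[order(g$phase_index), ]
    n <- nrow(g)
    Tt <- period_T %||% (g$time_s[2L] - g$time_s[1L]) * n
    flow_waveform(g$flow_mL_per_s, cardiac_cycle(Tt, n), g$level[1L])
  })
}
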