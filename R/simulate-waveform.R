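#' Simulate a transmitral velocity waveform
#'
#' Forward model for a retrospectively-gated phase-contrast transmitral
#' inflow curve over one RR interval. The E wave is built as a fast
#' sinusoidal rise followed by a strictly linear descent whose extrapolation
#' reaches zero velocity exactly \code{DT} ms after the peak, so the
#' deceleration time is analytic ground truth. The A wave is a raised-cosine
#' pulse. Peak times are snapped to the nearest sample (frame mid-point) so
#' that, noise-free, the sampled maxima equal \code{peak_E} and
#' \code{peak_A} exactly. Additive i.i.d. Gaussian frame noise; no baseline
#' drift unless requested.
#'
#' @param peak_E E-wave peak velocity, cm/s (> 0).
#' @param peak_A A-wave peak velocity, cm/s (>= 0; 0 suppresses the A wave).
#' @param t_E,t_A E- and A-peak times, ms (0 < t_E < t_A < rr_interval).
#' @param DT intended E-wave deceleration time, ms.
#' @param rr_interval RR interval, ms.
#' @param dt_frame temporal resolution, ms (default 36, the acquisition
#'   frame spacing emulated by the generator).
#' @param noise_sd per-frame Gaussian noise sd, cm/s.
#' @param e_rise_ms duration of the sinusoidal E upstroke, ms.
#' @param a_width_ms full width of the raised-cosine A pulse, ms.
#' @param drift_cms peak-to-peak amplitude of an optional slow sinusoidal
#'   baseline drift, cm/s (default 0, i.e. off).
#' @param seed integer seed; every call uses its own RNG stream and leaves
#'   the global RNG state untouched.
#' @return An object of class \code{velocity_waveform}: list with
#'   \code{times} (frame mid-points, ms), \code{velocities} (cm/s),
#'   \code{rr_interval} and a \code{truth} list holding the snapped peak
#'   times and the generating parameters.
#' @examples
#' w <- simulate_waveform(peak_E = 80, peak_A = 60, DT = 200, seed = 1)
#' extract_transmitral(w)
#' @export
simulate_waveform <- function(peak_E, peak_A = 0, t_E = 450, t_A = 850,
                              DT = 200, rr_interval = 1000, dt_frame = 36,
                              noise_sd = 0, e_rise_ms = 100, a_width_ms = 160,
                              drift_cms = 0, seed = NULL) {
  assert_num(peak_E, "peak_E", positive = TRUE)
  assert_num(peak_A, "peak_A", nonneg = TRUE)
  assert_num(DT, "DT", positive = TRUE)
  assert_num(dt_frame, "dt_frame", positive = TRUE)
  assert_num(rr_interval, "rr_interval", positive = TRUE)
  assert_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (!(t_E > 0 && t_E < t_A && t_A < rr_interval))
    stopf("need 0 < t_E < t_A < rr_interval (got t_E=%g, t_A=%g, rr=%g)",
          t_E, t_A, rr_interval)

  times <- seq(dt_frame / 2, rr_interval - dt_frame / 2, by = dt_frame)
  snap <- function(t) times[which.min(abs(times - t))]
  t_E <- snap(t_E)
  t_A <- snap(t_A)

  a_onset <- t_A - a_width_ms / 2
  # the E descent must be observable: >= 3 samples between the E peak and
  # whichever comes first, the zero crossing or the A onset
  desc_end <- min(t_E + DT, if (peak_A > 0) a_onset else Inf)
  n_desc <- sum(times > t_E & times < desc_end)
  if (n_desc < 3L)
    stopf(paste0("E and A pulses overlap too much: only %d samples on the E",
                 " descent before the A onset (need >= 3); increase DT, the",
                 " E-A separation, or the temporal resolution"), n_desc)

  e_pulse <- numeric(length(times))
  up <- times >= (t_E - e_rise_ms) & times <= t_E
  e_pulse[up] <- peak_E * sin(pi / 2 * (times[up] - (t_E - e_rise_ms)) / e_rise_ms)
  dn <- times > t_E & times < t_E + DT
  e_pulse[dn] <- peak_E * (1 - (times[dn] - t_E) / DT)

  a_pulse <- numeric(length(times))
  if (peak_A > 0) {
    inA <- times >= a_onset & times <= t_A + a_width_ms / 2
    a_pulse[inA] <- peak_A / 2 * (1 - cos(2 * pi * (times[inA] - a_onset) / a_width_ms))
  }

  v <- pmax(e_pulse, a_pulse)
  if (drift_cms != 0)
    v <- v + drift_cms / 2 * sin(2 * pi * times / rr_interval)
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_sd))

  structure(
    list(times = times, velocities = v, rr_interval = rr_interval,
         truth = list(peak_E = peak_E, peak_A = peak_A, t_E = t_E, t_A = t_A,
                      DT = DT, dt_frame = dt_frame, noise_sd = noise_sd)),
    class = "velocity_waveform")
}

# evaluate expr under a private RNG stream; the caller's RNG state (if any)
# is restored on exit, so generators never disturb global reproducibility
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> %d frames, RR %g ms, dt %g ms\n",
              length(x$times), x$rr_interval,
              if (length(x$times) > 1) diff(x$times[1:2]) else NA))
  cat(sprintf("  velocity range [%.1f, %.1f] cm/s\n",
              min(x$velocities), max(x$velocities)))
  invisible(x)
}

#' @export
plot.velocity_waveform <- function(x, ...) {
  graphics::plot(x$times, x$velocities, type = "b", pch = 16, cex = 0.6,
                 xlab = "time (ms)", ylab = "velocity (cm/s)", ...)
  invisible(x)
}
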