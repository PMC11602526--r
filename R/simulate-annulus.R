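#' Simulate a tracked mitral annulus trajectory
#'
#' Forward model for the septal and lateral mitral-valve insertion points on
#' a 4-chamber cine, as produced by an external valve tracker. Each wall
#' moves along the ventricular long axis: a raised-cosine systolic descent of
#' \code{systolic_excursion} mm toward the apex, an early-diastolic return
#' whose velocity is a trapezoid with plateau exactly at the wall's true e'
#' (so the peak early-diastolic annular velocity is analytic ground truth),
#' a diastasis, and a late (atrial) raised-cosine return that closes the loop
#' back to the end-diastolic position. Gaussian positional noise is added
#' per coordinate.
#'
#' @param e_septal,e_lateral true peak early-diastolic annular velocity per
#'   wall, cm/s (>= 0; at least one wall is usually > 0).
#' @param systolic_excursion systolic long-axis excursion, mm.
#' @param rr_interval RR interval, ms.
#' @param dt_frame frame spacing, ms; must be < rr_interval / 4.
#' @param noise_sd positional noise sd per coordinate, mm.
#' @param t_end_systole time of maximal systolic excursion, ms.
#' @param e_onset onset of the early-diastolic velocity trapezoid, ms.
#' @param e_rise,e_plateau rise/fall and plateau durations of the
#'   early-diastolic velocity trapezoid, ms. The plateau must exceed twice
#'   the frame spacing for the sampled track to retain the true peak rate.
#' @param a_center,a_width centre and full width of the atrial return
#'   velocity pulse, ms.
#' @param seed integer seed for the positional noise.
#' @return An object of class \code{annulus_track}: \code{times} (ms),
#'   \code{septal_xy} and \code{lateral_xy} (n x 2 matrices, mm),
#'   \code{apex_xy}, and a \code{truth} list with the generating parameters
#'   and the latent (noise-free) displacement curves.
#' @examples
#' tr <- simulate_annulus_track(e_septal = 8, e_lateral = 10)
#' e_prime(tr)
#' @export
simulate_annulus_track <- function(e_septal = 8, e_lateral = 10,
                                   systolic_excursion = 15,
                                   rr_interval = 1000, dt_frame = 36,
                                   noise_sd = 0, t_end_systole = 350,
                                   e_onset = 430, e_rise = 70, e_plateau = 110,
                                   a_center = 890, a_width = 120,
                                   seed = NULL) {
  assert_num(e_septal, "e_septal", nonneg = TRUE)
  assert_num(e_lateral, "e_lateral", nonneg = TRUE)
  assert_num(systolic_excursion, "systolic_excursion", nonneg = TRUE)
  assert_num(dt_frame, "dt_frame", positive = TRUE)
  assert_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (dt_frame >= rr_interval / 4)
    stopf("undersampled track: dt_frame (%g ms) must be < rr_interval/4 (%g ms)",
          dt_frame, rr_interval / 4)
  e_end <- e_onset + 2 * e_rise + e_plateau
  if (e_end > a_center - a_width / 2)
    stopf("early-diastolic wave overlaps the atrial return pulse")

  times <- seq(dt_frame / 2, rr_interval - dt_frame / 2, by = dt_frame)

  # latent long-axis displacement (mm, positive toward the base, 0 at t = 0)
  disp_curve <- function(t, ep_cms) {
    vp <- ep_cms * 0.01                      # cm/s -> mm/ms
    S <- systolic_excursion
    r <- e_rise; p <- e_plateau; t0 <- e_onset
    e_area <- vp * (r + p)
    wa <- a_width; ta0 <- a_center - wa / 2
    va <- 2 * (S - e_area) / wa              # closes displacement back to 0
    d <- numeric(length(t))
    seg <- t <= t_end_systole
    d[seg] <- -S / 2 * (1 - cos(pi * t[seg] / t_end_systole))
    seg <- t > t_end_systole & t <= t0
    d[seg] <- -S
    seg <- t > t0 & t <= t0 + r
    d[seg] <- -S + vp * (t[seg] - t0)^2 / (2 * r)
    seg <- t > t0 + r & t <= t0 + r + p
    d[seg] <- -S + vp * r / 2 + vp * (t[seg] - t0 - r)
    seg <- t > t0 + r + p & t <= t0 + 2 * r + p
    tt <- t[seg] - (t0 + r + p)
    d[seg] <- -S + vp * r / 2 + vp * p + vp * tt - vp * tt^2 / (2 * r)
    seg <- t > t0 + 2 * r + p & t <= ta0
    d[seg] <- -S + e_area
    seg <- t > ta0 & t <= ta0 + wa
    tt <- t[seg] - ta0
    d[seg] <- -S + e_area + va / 2 * (tt - wa / (2 * pi) * sin(2 * pi * tt / wa))
    seg <- t > ta0 + wa
    d[seg] <- -S + e_area + va * wa / 2
    d
  }

  d_sep <- disp_curve(times, e_septal)
  d_lat <- disp_curve(times, e_lateral)

  u <- c(0, 1)                               # basal direction
  apex <- c(0, -80)
  base_sep <- c(-15, 0)
  base_lat <- c(15, 0)
  septal_xy <- cbind(base_sep[1] + d_sep * u[1], base_sep[2] + d_sep * u[2])
  lateral_xy <- cbind(base_lat[1] + d_lat * u[1], base_lat[2] + d_lat * u[2])
  if (noise_sd > 0) {
    n <- length(times)
    eps <- with_seed(seed, matrix(stats::rnorm(4 * n, 0, noise_sd), ncol = 4))
    septal_xy <- septal_xy + eps[, 1:2]
    lateral_xy <- lateral_xy + eps[, 3:4]
  }
  colnames(septal_xy) <- colnames(lateral_xy) <- c("x", "y")

  structure(
    list(times = times, septal_xy = septal_xy, lateral_xy = lateral_xy,
         apex_xy = apex,
         truth = list(e_septal = e_septal, e_lateral = e_lateral,
                      systolic_excursion = systolic_excursion,
                      dt_frame = dt_frame, noise_sd = noise_sd,
                      disp_septal = d_sep, disp_lateral = d_lat)),
    class = "annulus_track")
}

#' @export
print.annulus_track <- function(x, ...) {
  cat(sprintf("<annulus_track> %d frames, dt %g ms\n", length(x$times),
              if (length(x$times) > 1) diff(x$times[1:2]) else NA))
  invisible(x)
}
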