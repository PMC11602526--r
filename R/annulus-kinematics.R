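#' Project annulus insertion points onto the long axis
#'
#' Reduces tracked septal and lateral mitral-annulus insertion-point
#' coordinates to scalar long-axis displacement curves. The long axis is the
#' unit vector from the apex reference to the valve midpoint at the first
#' frame and is held fixed over the cycle; displacement is positive toward
#' the base and zeroed at the first frame (end-diastole).
#'
#' @param track an \code{annulus_track} (see
#'   \code{\link{simulate_annulus_track}} or \code{\link{read_annulus_track_csv}}).
#' @return Object of class \code{annulus_displacement}: list with
#'   \code{times} (ms) and per-wall displacement vectors \code{septal},
#'   \code{lateral} (mm).
#' @export
project_displacement <- function(track) {
  stopifnot(inherits(track, "annulus_track"))
  mid0 <- (track$septal_xy[1, ] + track$lateral_xy[1, ]) / 2
  axis <- mid0 - track$apex_xy
  len <- sqrt(sum(axis^2))
  if (len < 1e-6)
    stopf("degenerate long axis: apex coincides with the valve midpoint")
  u <- axis / len                                 # points apex -> base
  proj <- function(xy) as.numeric((xy - matrix(xy[1, ], nrow(xy), 2, byrow = TRUE)) %*% u)
  structure(list(times = track$times,
                 septal = proj(track$septal_xy),
                 lateral = proj(track$lateral_xy)),
            class = "annulus_displacement")
}

#' Early-diastolic mitral annular velocities (e')
#'
#' Computes septal, lateral and average e' from a tracked annulus. Long-axis
#' displacement is differentiated by central differences; e' per wall is the
#' peak basal-directed velocity inside the early-diastolic window, which
#' runs from the time of maximal systolic (apical) excursion to
#' \code{early_frac} of the remaining cycle, excluding the atrial wave.
#' Velocities are reported as positive magnitudes (cm/s), matching clinical
#' convention.
#'
#' @param track an \code{annulus_track}.
#' @param early_frac fraction of the post-systolic interval searched for the
#'   early-diastolic peak (default 0.75; the atrial wave falls beyond it).
#' @param smooth logical; apply a 5-point quadratic Savitzky-Golay smoother
#'   to the displacement curves before differencing (off by default).
#' @return Object of class \code{annulus_velocities}: \code{e_septal},
#'   \code{e_lateral}, \code{e_average} (cm/s), peak times \code{t_e_septal},
#'   \code{t_e_lateral} (ms) and \code{qc_flags}.
#' @examples
#' e_prime(simulate_annulus_track(e_septal = 8, e_lateral = 10))
#' @export
e_prime <- function(track, early_frac = 0.75, smooth = FALSE) {
  stopifnot(inherits(track, "annulus_track"))
  if (length(track$times) < 8L)
    stopf("track too short: need >= 8 frames over the cycle, got %d",
          length(track$times))
  disp <- project_displacement(track)
  qc <- character(0)

  wall <- function(d) {
    t <- disp$times
    if (smooth) d <- sg5(d)
    n <- length(d)
    v <- (d[3:n] - d[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]) * 100  # mm/ms -> cm/s
    tv <- t[2:(n - 1)]
    t_min <- t[which.min(d)]
    hi <- t_min + early_frac * (t[n] - t_min)
    in_win <- tv >= t_min & tv <= hi
    if (!any(in_win))
      stopf("early-diastolic window is empty (systolic excursion at cycle end)")
    vw <- v[in_win]
    i <- which.max(vw)
    list(e = max(vw[i], 0), t = tv[in_win][i], clipped = vw[i] < 0)
  }

  s <- wall(disp$septal)
  l <- wall(disp$lateral)
  if (s$clipped) qc <- c(qc, "septal: no basal-directed early-diastolic motion")
  if (l$clipped) qc <- c(qc, "lateral: no basal-directed early-diastolic motion")

  structure(list(e_septal = s$e, e_lateral = l$e,
                 e_average = (s$e + l$e) / 2,
                 t_e_septal = s$t, t_e_lateral = l$t,
                 qc_flags = qc),
            class = "annulus_velocities")
}

# 5-point quadratic Savitzky-Golay smoother; endpoints kept as observed
sg5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  w <- c(-3, 12, 17, 12, -3) / 35
  y <- x
  for (i in 3:(n - 2)) y[i] <- sum(w * x[(i - 2):(i + 2)])
  y
}

#' @export
print.annulus_velocities <- function(x, ...) {
  cat(sprintf("e' septal %.2f cm/s (t = %g ms), lateral %.2f cm/s (t = %g ms), average %.2f cm/s\n",
              x$e_septal, x$t_e_septal, x$e_lateral, x$t_e_lateral, x$e_average))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}
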