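#' Reduce a stack of 2D velocity frames to an ROI-peak waveform
#'
#' Emulates the clinical reading of in-plane phase-contrast images: a
#' circular region of interest is placed at the level of the mitral valve
#' and, per frame, the peak velocity within the ROI is taken. The inflow
#' sign is auto-detected from the dominant direction over the cycle (the
#' side with the larger total absolute velocity inside the ROI) and the
#' series is reported positive toward the LV apex; set \code{sign} to
#' override.
#'
#' @param frames list of 2D velocity matrices (cm/s), one per time point.
#' @param times frame times, ms (strictly increasing, length = frames).
#' @param pixel_spacing pixel size, mm.
#' @param roi_center ROI centre \code{c(x, y)} in mm (pixel centres are at
#'   \code{(j - 0.5) * pixel_spacing}, \code{(i - 0.5) * pixel_spacing}).
#' @param roi_radius ROI radius, mm (default 20, i.e. the conventional 2 cm).
#' @param rr_interval RR interval, ms; defaults to the spanned time range
#'   plus one frame.
#' @param sign optional +1/-1 overriding the auto-detected inflow sign.
#' @return A \code{velocity_waveform} whose \code{velocities} are the
#'   per-frame ROI peaks (cm/s, positive toward the apex). Frames that are
#'   entirely NaN are excluded and flagged in \code{attr(, "qc_flags")}.
#' @export
roi_peak_series <- function(frames, times, pixel_spacing, roi_center,
                            roi_radius = 20, rr_interval = NULL, sign = NULL) {
  if (!is.list(frames) || !length(frames))
    stopf("'frames' must be a non-empty list of matrices")
  if (length(times) != length(frames))
    stopf("'times' must have one entry per frame")
  if (any(diff(times) <= 0)) stopf("'times' must be strictly increasing")
  if (length(frames) < 8L)
    stopf("need >= 8 frames per cycle, got %d", length(frames))
  dm <- dim(frames[[1]])
  xs <- (seq_len(dm[2]) - 0.5) * pixel_spacing
  ys <- (seq_len(dm[1]) - 0.5) * pixel_spacing
  mask <- outer(ys, xs, function(y, x)
    (x - roi_center[1])^2 + (y - roi_center[2])^2 <= roi_radius^2)
  if (!any(mask))
    stopf("ROI contains no pixels (center %g,%g mm, radius %g mm)",
          roi_center[1], roi_center[2], roi_radius)

  vals <- lapply(frames, function(f) f[mask])
  qc <- character(0)
  keep <- vapply(vals, function(v) !all(is.nan(v)), logical(1))
  if (!all(keep))
    qc <- c(qc, sprintf("excluded %d all-NaN frame(s)", sum(!keep)))
  vals <- vals[keep]

  if (is.null(sign)) {
    pos <- sum(vapply(vals, function(v) sum(pmax(v, 0), na.rm = TRUE), 0))
    neg <- sum(vapply(vals, function(v) sum(pmax(-v, 0), na.rm = TRUE), 0))
    sign <- if (neg > pos) -1 else 1
  }
  series <- vapply(vals, function(v) max(sign * v, na.rm = TRUE), 0)
  tt <- times[keep]
  if (is.null(rr_interval))
    rr_interval <- max(times) - min(times) + stats::median(diff(times))

  structure(list(times = tt, velocities = series, rr_interval = rr_interval,
                 truth = NULL, inflow_sign = sign, qc_flags = qc),
            class = "velocity_waveform")
}

#' Detect the E and A peaks of a transmitral waveform
#'
#' E is the highest diastolic peak in the early window, A the last distinct
#' peak before the end of the cycle. Peaks are discrete local maxima (no
#' sub-frame interpolation) that clear a noise floor; a fused single-peak
#' inflow reports A as absent with a qc flag. Diastole is taken to start at
#' \code{end_systole_hint} when given, otherwise at the global minimum of
#' the early-cycle flow; E is searched in the first 60\% of diastole and A
#' in the remainder.
#'
#' @param w a \code{velocity_waveform}.
#' @param end_systole_hint optional end-systolic time, ms.
#' @param early_frac fraction of diastole searched for E (default 0.6).
#' @param min_sep minimum E-A separation in frames (default 2).
#' @return List of class \code{transmitral_result} with \code{E}, \code{A}
#'   (cm/s, \code{NA} if absent), \code{E_over_A}, \code{t_E}, \code{t_A}
#'   (ms) and \code{qc_flags}. \code{DT} is \code{NA} until
#'   \code{\link{deceleration_time}} fills it (see
#'   \code{\link{extract_transmitral}}).
#' @export
detect_E_A <- function(w, end_systole_hint = NULL, early_frac = 0.6,
                       min_sep = 2L) {
  stopifnot(inherits(w, "velocity_waveform"))
  t <- w$times; v <- w$velocities; n <- length(v)
  if (n < 8L) stopf("waveform too short to cover a cycle (%d samples)", n)
  qc <- character(0)

  if (!is.null(end_systole_hint)) {
    d_start <- end_systole_hint
  } else {
    half <- t <= t[1] + 0.5 * (t[n] - t[1])
    d_start <- t[half][which.min(v[half])]
  }
  d_dur <- t[n] - d_start
  if (d_dur <= 0) stopf("no diastolic interval after the assumed end of systole")

  vmax <- max(v)
  floor_v <- max(0.15 * vmax, 4 * noise_sigma_est(v))
  is_peak <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    is_peak[i] <- v[i] == max(v[lo:hi]) && v[i] > v[i - 1] && v[i] >= v[i + 1] &&
      v[i] >= floor_v
  }
  pk <- which(is_peak & t >= d_start)
  if (!length(pk))
    stopf("no diastolic peak found (max %.1f cm/s below noise floor %.1f)",
          vmax, floor_v)

  early <- pk[t[pk] <= d_start + early_frac * d_dur]
  late <- pk[t[pk] > d_start + early_frac * d_dur]
  if (!length(early)) {          # all inflow late: still take the highest as E
    early <- pk[which.max(v[pk])]
    late <- setdiff(late, early)
    qc <- c(qc, "E peak found outside the early window")
  }
  iE <- early[which.max(v[early])]
  late <- late[late - iE >= min_sep]
  iA <- if (length(late)) late[length(late)] else NA_integer_

  if (is.na(iA)) qc <- c(qc, "single-peak (fused or absent A) inflow")
  E <- v[iE]
  A <- if (is.na(iA)) NA_real_ else v[iA]
  structure(list(E = E, A = A,
                 E_over_A = if (is.na(iA)) NA_real_ else E / A,
                 DT = NA_real_, t_E = t[iE],
                 t_A = if (is.na(iA)) NA_real_ else t[iA],
                 qc_flags = qc),
            class = "transmitral_result")
}

#' E-wave deceleration time by slope extrapolation
#'
#' Fits a straight line to the initial descending limb of the E wave and
#' returns the time from the peak to the line's zero crossing:
#' \code{DT = v_fit(t_E) / |slope|}. The fit window holds the descending
#' samples between 90\% and 50\% of the peak; if fewer than 3 fall there it
#' extends toward 30\%. A descent truncated by the A onset is fitted on the
#' available samples with a qc flag.
#'
#' @param w a \code{velocity_waveform}.
#' @param t_E E-peak time, ms (from \code{\link{detect_E_A}}).
#' @return \code{DT} in ms, with attribute \code{qc_flags}.
#' @export
deceleration_time <- function(w, t_E) {
  stopifnot(inherits(w, "velocity_waveform"))
  t <- w$times; v <- w$velocities
  iE <- which.min(abs(t - t_E))
  peak <- v[iE]
  qc <- character(0)

  # descending limb: from the peak until velocity rises again or crosses zero
  i <- iE
  n <- length(v)
  while (i < n && v[i + 1] <= v[i] && v[i + 1] > 0) i <- i + 1
  limb <- if (i > iE) (iE + 1):i else integer(0)
  limb <- limb[v[limb] > 0]
  if (i < n && length(limb) && v[i] > 0.3 * peak)
    qc <- c(qc, "descent truncated by A onset; fit on available samples")
  if (length(limb) < 3L)
    stopf("need >= 3 samples on the descending limb after t_E, got %d",
          length(limb))

  frac <- v[limb] / peak
  win <- limb[frac <= 0.9 & frac >= 0.5]
  if (length(win) < 3L) win <- limb[frac <= 0.9 & frac >= 0.3]
  if (length(win) < 3L) win <- limb[seq_len(min(length(limb), 5L))]

  fit <- stats::lm(v[win] ~ t[win])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stopf("non-negative slope on the E descent (no decay); cannot extrapolate")
  v_at_peak <- unname(stats::coef(fit)[1] + slope * t[iE])
  dt <- v_at_peak / abs(slope)
  attr(dt, "qc_flags") <- qc
  dt
}

#' Full transmitral analysis of one waveform
#'
#' Convenience wrapper running \code{\link{detect_E_A}} then
#' \code{\link{deceleration_time}} and returning the completed
#' \code{transmitral_result}.
#'
#' @inheritParams detect_E_A
#' @return A \code{transmitral_result} with \code{E}, \code{A},
#'   \code{E_over_A}, \code{DT}, peak times and qc flags.
#' @examples
#' extract_transmitral(simulate_waveform(peak_E = 79, peak_A = 62, seed = 2))
#' @export
extract_transmitral <- function(w, end_systole_hint = NULL) {
  res <- detect_E_A(w, end_systole_hint)
  dt <- deceleration_time(w, res$t_E)
  res$DT <- as.numeric(dt)
  res$qc_flags <- c(res$qc_flags, attr(dt, "qc_flags"))
  res
}

#' @export
print.transmitral_result <- function(x, ...) {
  cat(sprintf("E %.1f cm/s (t = %g ms)", x$E, x$t_E))
  if (!is.na(x$A))
    cat(sprintf(", A %.1f cm/s (t = %g ms), E/A %.2f", x$A, x$t_A, x$E_over_A))
  else cat(", A absent")
  if (!is.na(x$DT)) cat(sprintf(", DT %.0f ms", x$DT))
  cat("\n")
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}
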