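make_stack <- function(curve, nr = 32, nc = 32, spacing = 2,
                       center = c(31, 31), sigma = 6) {
  xs <- (seq_len(nc) - 0.5) * spacing
  ys <- (seq_len(nr) - 0.5) * spacing
  prof <- outer(ys, xs, function(y, x)
    exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma^2)))
  lapply(curve, function(v) v * prof)
}

test_that("roi_peak_series takes the per-frame peak inside the circular ROI", {
  frames <- replicate(10, matrix(0, 16, 16), simplify = FALSE)
  frames[[4]][8, 8] <- 80                       # pixel centre (15, 15) mm
  t <- seq(0, 324, by = 36)
  w <- roi_peak_series(frames, t, pixel_spacing = 2, roi_center = c(15, 15))
  expect_equal(w$velocities[4], 80)
  expect_equal(w$velocities[-4], rep(0, 9))
  # ROI far away from the hot pixel sees nothing
  w0 <- roi_peak_series(frames, t, pixel_spacing = 2, roi_center = c(28, 28),
                        roi_radius = 3)
  expect_equal(w0$velocities, rep(0, 10))
})

test_that("a Gaussian-spread synthetic stack returns the generator's curve", {
  w <- simulate_waveform(peak_E = 75, peak_A = 55, DT = 210, noise_sd = 0)
  stack <- make_stack(w$velocities)
  rec <- roi_peak_series(stack, w$times, pixel_spacing = 2,
                         roi_center = c(31, 31), rr_interval = w$rr_interval)
  expect_lt(max(abs(rec$velocities - w$velocities)), 1)
  # flipped sign convention is auto-detected and reported positive
  neg <- lapply(stack, function(f) -f)
  rec2 <- roi_peak_series(neg, w$times, pixel_spacing = 2,
                          roi_center = c(31, 31))
  expect_lt(max(abs(rec2$velocities - w$velocities)), 1)
  expect_equal(rec2$inflow_sign, -1)
})

test_that("roi_peak_series rejects empty ROIs and flags all-NaN frames", {
  frames <- replicate(10, matrix(1, 16, 16), simplify = FALSE)
  t <- seq(0, 324, by = 36)
  expect_error(roi_peak_series(frames, t, 2, roi_center = c(200, 200),
                               roi_radius = 3), "no pixels")
  frames[[5]][] <- NaN
  w <- roi_peak_series(frames, t, 2, roi_center = c(15, 15))
  expect_length(w$velocities, 9)
  expect_match(w$qc_flags, "NaN")
})

test_that("E and A detection matches generator ground truth", {
  w <- simulate_waveform(peak_E = 79, peak_A = 62, noise_sd = 0)
  r <- detect_E_A(w)
  expect_equal(r$E, 79)
  expect_equal(r$A, 62)
  expect_equal(round(r$E_over_A, 2), 1.27)
  expect_equal(r$t_E, w$truth$t_E)
  expect_equal(r$t_A, w$truth$t_A)
})

test_that("an absent A wave is reported absent with a qc flag", {
  w <- simulate_waveform(peak_E = 80, peak_A = 0, noise_sd = 0)
  r <- detect_E_A(w)
  expect_true(is.na(r$A))
  expect_true(is.na(r$E_over_A))
  expect_match(r$qc_flags, "fused|absent", all = FALSE)
})

test_that("reported E/A ratios round to their 1-decimal clinical values", {
  expect_equal(round(55 / 37, 1), 1.5)
  w <- simulate_waveform(peak_E = 55, peak_A = 37, noise_sd = 0)
  r <- detect_E_A(w)
  expect_equal(round(r$E_over_A, 1), 1.5)
})

test_that("deceleration time is exact on a noise-free triangular E wave", {
  t <- seq(18, 990, by = 36)
  v <- numeric(length(t))
  up <- t >= 300 & t <= 414
  v[up] <- 80 * (t[up] - 300) / 114
  dn <- t > 414 & t < 714
  v[dn] <- pmax(80 * (1 - (t[dn] - 414) / 300), 0)  # zero crossing 300 ms after peak
  w <- structure(list(times = t, velocities = v, rr_interval = 1000),
                 class = "velocity_waveform")
  expect_equal(as.numeric(deceleration_time(w, 414)), 300, tolerance = 1e-12)
  # doubling the descent slope halves DT
  v2 <- v
  v2[dn] <- pmax(80 * (1 - (t[dn] - 414) / 150), 0)
  w2 <- structure(list(times = t, velocities = v2, rr_interval = 1000),
                  class = "velocity_waveform")
  expect_equal(as.numeric(deceleration_time(w2, 414)), 150, tolerance = 1e-12)
})

test_that("a non-decaying descent is rejected", {
  t <- seq(18, 990, by = 36)
  v <- rep(50, length(t))
  w <- structure(list(times = t, velocities = v, rr_interval = 1000),
                 class = "velocity_waveform")
  expect_error(deceleration_time(w, 414), "descending limb|slope")
})

test_that("extraction is shift-invariant in time and equivariant in amplitude", {
  for (s in 1:20) {
    w <- simulate_waveform(peak_E = 70 + s, peak_A = 50, DT = 180 + s,
                           noise_sd = 1, seed = s)
    r <- extract_transmitral(w)
    shifted <- w
    shifted$times <- w$times + 500
    r_sh <- extract_transmitral(shifted)
    expect_equal(r_sh$E, r$E)
    expect_equal(r_sh$A, r$A)
    expect_equal(r_sh$DT, r$DT, tolerance = 1e-9)

    scaled <- w
    scaled$velocities <- 2.5 * w$velocities
    r_sc <- extract_transmitral(scaled)
    expect_equal(r_sc$E, 2.5 * r$E)
    expect_equal(r_sc$A, 2.5 * r$A)
    expect_equal(r_sc$DT, r$DT, tolerance = 1e-9)
  }
})
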