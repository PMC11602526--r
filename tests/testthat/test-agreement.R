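test_that("pearson_with_label applies the stated strength bands", {
  x <- 1:20
  r1 <- pearson_with_label(x, x)
  expect_equal(r1$r, 1)
  expect_equal(r1$label, "very strong")

  # constructed orthogonal pair: r exactly 0, below any band
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  x0 <- rep(c(2, 2, 0, 0), length.out = 10)
  y0 <- y - mean(y)
  x0 <- x0 - mean(x0)
  y0 <- y0 - x0 * sum(x0 * y0) / sum(x0^2)     # residualize: cor = 0
  r0 <- pearson_with_label(x0, y0 + 10)
  expect_equal(r0$r, 0, tolerance = 1e-12)
  expect_true(is.na(r0$label))

  expect_error(pearson_with_label(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_label(1:2, 1:2), ">= 3")
})

test_that("bland_altman handles exact and constant-difference cases", {
  x <- c(3, 5, 9, 11)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  bac <- bland_altman(x + 2.5, x)
  expect_equal(bac$bias, 2.5)
  expect_equal(bac$loa_low, 2.5)
  expect_equal(bac$loa_high, 2.5)
  expect_error(bland_altman(1, 1), ">= 2")
})

test_that("limits of agreement span 2 * 1.96 * sd and cover ~95% of differences", {
  set.seed(604)
  x <- rnorm(1e4, 10, 2)
  y <- x + rnorm(1e4, -1, 1.5)
  ba <- bland_altman(y, x)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("cohort generator reproduces its configured bias and spread", {
  spec <- cohort_spec(n_subjects = 1e4, seed = 2024)
  cohort <- simulate_paired_cohort(spec)
  ba_e <- bland_altman(cohort$cmr_e_average, cohort$tte_e_average)
  # configured e'-average bias: mean of the per-wall biases
  expect_lt(abs(ba_e$bias - (-2.2 - 3.1) / 2), 0.08)
  # analytic spread of the e'-average difference under the wall-noise model
  s_sep <- spec$noise_sd[["e_septal"]]; s_lat <- spec$noise_sd[["e_lateral"]]
  rho <- spec$noise_wall_cor
  var_avg <- (2 * s_sep^2 + 2 * s_lat^2 + 2 * 2 * rho * s_sep * s_lat) / 4
  expect_lt(abs(1.96 * ba_e$sd_diff - 1.96 * sqrt(var_avg)),
            0.05 * 1.96 * sqrt(var_avg))

  ba_E <- bland_altman(cohort$cmr_E, cohort$tte_E)
  expect_lt(abs(ba_E$bias - (-4.9)), 0.4)
  expect_lt(abs(1.96 * ba_E$sd_diff - 25), 0.05 * 25)
})

test_that("paired-modality correlation matches the generator's analytic value", {
  spec <- cohort_spec(n_subjects = 1e4, seed = 55)
  cohort <- simulate_paired_cohort(spec)
  r_hat <- pearson_with_label(cohort$cmr_E, cohort$tte_E)
  # shared-latent model: r = var_latent / (var_latent + var_noise)
  f <- spec$dd_fraction
  mu <- c(spec$mean_no_dd[["E"]], spec$mean_dd[["E"]])
  sg <- c(spec$sd_no_dd[["E"]], spec$sd_dd[["E"]])
  mbar <- (1 - f) * mu[1] + f * mu[2]
  v_lat <- (1 - f) * (sg[1]^2 + (mu[1] - mbar)^2) + f * (sg[2]^2 + (mu[2] - mbar)^2)
  r_true <- v_lat / (v_lat + spec$noise_sd[["E"]]^2)
  expect_equal(r_hat$r, r_true, tolerance = 0.03)
  expect_true(r_hat$label %in% c("strong", "very strong"))
})

test_that("cohens_kappa matches hand and library computations", {
  diagonal <- diag(c(4, 6, 2))
  expect_equal(cohens_kappa(diagonal), 1)

  indep <- outer(c(2, 4), c(3, 6)) / 1          # rank-1: independence
  expect_equal(cohens_kappa(indep), 0, tolerance = 1e-12)

  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:20) {
    tab <- random_table(sample(2:5, 1))
    expect_equal(cohens_kappa(tab),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa never exceeds observed accuracy", {
  set.seed(10)
  for (i in 1:200) {
    tab <- random_table(sample(2:5, 1))
    po <- sum(diag(tab)) / sum(tab)
    k <- tryCatch(cohens_kappa(tab), error = function(e) NA)
    if (!is.na(k)) expect_lte(k, po + 1e-12)
  }
})

test_that("diagnostic_accuracy reports exact intervals and edge cases", {
  rep28 <- diagnostic_accuracy(collapse_presence(reported_grade_table()))
  expect_equal(rep28$sensitivity$estimate, 1)
  expect_equal(rep28$sensitivity$ci_low, 0.025^(1 / 8), tolerance = 1e-9)

  perfect <- matrix(c(10, 0, 0, 15), 2, byrow = TRUE)
  p <- diagnostic_accuracy(perfect)
  expect_equal(p$accuracy$estimate, 1)
  expect_equal(p$sensitivity$ci_high, 1)
  expect_equal(p$specificity$estimate, 1)

  empty_margin <- matrix(c(0, 0, 5, 15), 2, byrow = TRUE)
  em <- diagnostic_accuracy(empty_margin)
  expect_true(is.na(em$sensitivity$estimate))
  expect_false(is.na(em$specificity$estimate))
})

test_that("Clopper-Pearson intervals cover >= 95% (exact enumeration, n = 28)", {
  n <- 28
  for (p in c(0.1, 0.3, 0.5, 0.6, 0.82, 0.95)) {
    covered <- 0
    for (k in 0:n) {
      ci <- stats::binom.test(k, n)$conf.int
      if (ci[1] <= p && p <= ci[2]) covered <- covered + stats::dbinom(k, n, p)
    }
    expect_gte(covered, 0.95)
  }
})

test_that("ICC(2,1) matches the aov oracle and penalizes systematic offsets", {
  set.seed(21)
  subj <- rnorm(15, 10, 3)
  r1 <- subj + rnorm(15, 0, 1)
  r2 <- subj + rnorm(15, 0, 1)
  expect_equal(as.numeric(icc_scan_rescan(r1, r2)), aov_icc21(r1, r2),
               tolerance = 1e-10)
  expect_equal(as.numeric(icc_scan_rescan(r1, r1)), 1)

  shifted <- r1 + 8
  icc_off <- as.numeric(icc_scan_rescan(r1, shifted))
  r_pearson <- cor(r1, shifted)
  expect_lt(icc_off, r_pearson)
  expect_error(icc_scan_rescan(rep(1, 5), rep(1, 5)), "between-subject")
})

test_that("simulated scan-rescan ICC converges to the variance-component value", {
  sigma_b <- 13
  sigma_w <- 13.2 / (1.96 * sqrt(2))
  icc_true <- sigma_b^2 / (sigma_b^2 + sigma_w^2)
  set.seed(31)
  subj <- rnorm(4000, 73, sigma_b)
  r1 <- subj + rnorm(4000, 0, sigma_w)
  r2 <- subj + rnorm(4000, 0, sigma_w)
  expect_equal(as.numeric(icc_scan_rescan(r1, r2)), icc_true, tolerance = 0.02)
})
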