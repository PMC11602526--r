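#' Specification of a paired TTE/CMR cohort
#'
#' Bundles the population and modality parameters used by
#' \code{\link{simulate_paired_cohort}}. Each subject carries a latent true
#' diastolic panel drawn from either a normal-function or a
#' dysfunction-range distribution; the TTE measurement adds zero-mean noise
#' and the CMR measurement adds a signed modality bias plus noise, so the
#' configured bias and spread of CMR-minus-TTE differences are recovered in
#' the limit. Defaults emulate the reported group means/SDs and
#' between-modality biases of a preserved-EF referral population: e.g. a
#' CMR e' bias of -2.2 (septal) and -3.1 cm/s (lateral), hence -2.65 cm/s
#' for the e' average, and a +12 mL/m2 LAVi bias.
#'
#' @param n_subjects number of subjects.
#' @param dd_fraction proportion of subjects drawn from the
#'   dysfunction-range distribution (default 9/31).
#' @param mean_no_dd,sd_no_dd,mean_dd,sd_dd named vectors of latent means
#'   and SDs per parameter (names \code{E, A, DT, e_septal, e_lateral,
#'   lavi, lvmi, tr_velocity, lvef}; units cm/s, ms, mL/m2, g/m2, \%).
#' @param bias named vector of signed CMR-minus-TTE offsets.
#' @param noise_sd named vector of per-modality measurement noise SDs
#'   (applied to TTE and CMR alike; the SD of paired differences is
#'   \code{sqrt(2)} times this, up to the wall-noise correlation).
#' @param latent_wall_cor correlation between latent septal and lateral e'.
#' @param noise_wall_cor correlation between septal and lateral measurement
#'   noise within a modality (raises the spread of the e'-average
#'   difference toward its reported value).
#' @param seed integer seed.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 31,
                        dd_fraction = 9 / 31,
                        mean_no_dd = c(E = 76, A = 62, DT = 200, e_septal = 9.9,
                                       e_lateral = 13.0, lavi = 29, lvmi = 52,
                                       tr_velocity = 208, lvef = 58),
                        sd_no_dd = c(E = 17, A = 18, DT = 66, e_septal = 3.3,
                                     e_lateral = 4.4, lavi = 10, lvmi = 17,
                                     tr_velocity = 28, lvef = 4),
                        mean_dd = c(E = 80, A = 72, DT = 230, e_septal = 6.1,
                                    e_lateral = 8.3, lavi = 36, lvmi = 57,
                                    tr_velocity = 272, lvef = 59),
                        sd_dd = c(E = 28, A = 18, DT = 89, e_septal = 1.9,
                                  e_lateral = 2.5, lavi = 12, lvmi = 13,
                                  tr_velocity = 26, lvef = 5),
                        bias = c(E = -4.9, A = -2.6, DT = -35, e_septal = -2.2,
                                 e_lateral = -3.1, lavi = 12, lvmi = 0,
                                 tr_velocity = 0, lvef = 0),
                        noise_sd = c(E = 25, A = 31, DT = 118, e_septal = 4.9,
                                     e_lateral = 7.5, lavi = 27, lvmi = 0,
                                     tr_velocity = 0, lvef = 0) / (1.96 * sqrt(2)),
                        latent_wall_cor = 0.6,
                        noise_wall_cor = 0.5,
                        seed = NULL) {
  if (n_subjects < 1) stopf("'n_subjects' must be >= 1")
  if (dd_fraction < 0 || dd_fraction > 1)
    stopf("'dd_fraction' must be in [0, 1]")
  pars <- names(mean_no_dd)
  for (v in list(sd_no_dd, mean_dd, sd_dd, bias, noise_sd))
    if (!setequal(names(v), pars))
      stopf("all parameter vectors must share the same names")
  if (any(sd_no_dd < 0) || any(sd_dd < 0) || any(noise_sd < 0))
    stopf("SDs must be >= 0")
  structure(list(n_subjects = n_subjects, dd_fraction = dd_fraction,
                 mean_no_dd = mean_no_dd, sd_no_dd = sd_no_dd,
                 mean_dd = mean_dd, sd_dd = sd_dd,
                 bias = bias, noise_sd = noise_sd,
                 latent_wall_cor = latent_wall_cor,
                 noise_wall_cor = noise_wall_cor, seed = seed),
            class = "cohort_spec")
}

#' Simulate a paired TTE/CMR cohort with known ground truth
#'
#' Draws one latent diastolic panel per subject and measures it with both
#' modalities under the configured bias/noise model. Derived quantities
#' (\code{E_over_A}, \code{e_average}, \code{E_over_e_avg}) are computed
#' from the per-modality component values. The CMR TR velocity is copied
#' from TTE (it is not measured by CMR). Velocities and volumes are floored
#' at small positive values.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with one row per subject: \code{subject}, \code{dd}
#'   (latent dysfunction-range indicator) and \code{true_*}, \code{tte_*},
#'   \code{cmr_*} columns for every panel parameter.
#' @examples
#' head(simulate_paired_cohort(cohort_spec(n_subjects = 5, seed = 1)))
#' @export
simulate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  pars <- names(spec$mean_no_dd)

  out <- with_seed(spec$seed, {
    dd <- stats::rbinom(n, 1, spec$dd_fraction) == 1

    # latent truth; septal/lateral e' share a correlated component
    truth <- matrix(NA_real_, n, length(pars), dimnames = list(NULL, pars))
    z_shared <- stats::rnorm(n)
    r <- spec$latent_wall_cor
    for (p in pars) {
      mu <- ifelse(dd, spec$mean_dd[p], spec$mean_no_dd[p])
      sg <- ifelse(dd, spec$sd_dd[p], spec$sd_no_dd[p])
      # sqrt(r) loadings on the shared factor give pairwise correlation r
      z <- if (p %in% c("e_septal", "e_lateral"))
        sqrt(r) * z_shared + sqrt(1 - r) * stats::rnorm(n)
      else stats::rnorm(n)
      truth[, p] <- mu + sg * z
    }

    measure <- function(shift) {
      m <- truth
      rw <- spec$noise_wall_cor
      w_shared <- stats::rnorm(n)
      for (p in pars) {
        eps <- if (p %in% c("e_septal", "e_lateral"))
          sqrt(rw) * w_shared + sqrt(1 - rw) * stats::rnorm(n)
        else stats::rnorm(n)
        m[, p] <- truth[, p] + shift[p] + spec$noise_sd[p] * eps
      }
      m
    }
    tte <- measure(stats::setNames(rep(0, length(pars)), pars))
    cmr <- measure(spec$bias)
    cmr[, "tr_velocity"] <- tte[, "tr_velocity"]
    list(dd = dd, truth = truth, tte = tte, cmr = cmr)
  })

  # physiologic floors apply to the latent truth only (they essentially never
  # bind at the default parameters); measured values stay exactly additive in
  # truth + bias + noise so the configured difference moments are recovered
  floors <- c(E = 5, A = 5, DT = 60, e_septal = 0.5, e_lateral = 0.5,
              lavi = 5, lvmi = 20, tr_velocity = 100, lvef = 20)
  truth <- out$truth
  for (p in intersect(pars, names(floors)))
    truth[, p] <- pmax(truth[, p], floors[p])
  shift_t <- truth - out$truth
  panels <- lapply(list(true = truth, tte = out$tte + shift_t,
                        cmr = out$cmr + shift_t), function(m) {
    d <- as.data.frame(m)
    d$e_average <- (d$e_septal + d$e_lateral) / 2
    d$E_over_A <- ifelse(d$A > 0, d$E / d$A, NA_real_)
    d$E_over_e_avg <- ifelse(d$e_average > 0, d$E / d$e_average, NA_real_)
    d
  })

  res <- data.frame(subject = seq_len(spec$n_subjects), dd = out$dd)
  for (tag in names(panels)) {
    p <- panels[[tag]]
    names(p) <- paste(tag, names(p), sep = "_")
    res <- cbind(res, p)
  }
  attr(res, "cohort_spec") <- spec
  res
}

#' Extract one modality's panels from a paired cohort
#'
#' @param cohort data.frame from \code{\link{simulate_paired_cohort}}.
#' @param modality \code{"tte"} or \code{"cmr"}.
#' @return data.frame of panel columns (prefix stripped) with a
#'   \code{modality} column, suitable for \code{\link{grade_panels}}.
#' @export
cohort_panels <- function(cohort, modality = c("tte", "cmr")) {
  modality <- match.arg(modality)
  pre <- paste0(modality, "_")
  cols <- grep(paste0("^", pre), names(cohort), value = TRUE)
  p <- cohort[cols]
  names(p) <- sub(pre, "", names(p))
  p$modality <- toupper(modality)
  p
}
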