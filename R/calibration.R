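#' Calibrate a CMR-analog cutoff by ROC analysis
#'
#' Scans every candidate threshold (midpoints between sorted unique values,
#' plus open extremes) of a CMR variable against a binary TTE criterion and
#' returns the cutoff maximizing Youden's J (sensitivity + specificity - 1),
#' the trapezoidal AUC, and the operating characteristics at the chosen
#' cutoff. Ties in J are broken toward the more specific cutoff. Subjects
#' are called positive when the value falls on the abnormal side of the
#' candidate: \code{>= cutoff} for \code{direction = "high_abnormal"},
#' \code{<= cutoff} for \code{"low_abnormal"}.
#'
#' @param cmr_values numeric vector of CMR measurements.
#' @param labels logical (or 0/1) vector: the TTE criterion per subject.
#' @param direction which side of the cutoff is abnormal.
#' @return Object of class \code{cutoff_calibration}: \code{cutoff},
#'   \code{auc}, \code{sensitivity}, \code{specificity}, \code{youden_j},
#'   \code{direction}, \code{n}.
#' @examples
#' calibrate_cutoff(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
#' @export
calibrate_cutoff <- function(cmr_values, labels,
                             direction = c("high_abnormal", "low_abnormal")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(cmr_values) & !is.na(labels)
  x <- cmr_values[ok]; y <- labels[ok]
  if (!any(y) || all(y))
    stopf("both classes must be represented in 'labels'")

  s <- if (direction == "high_abnormal") 1 else -1
  xs <- s * x                                  # larger always = more abnormal
  u <- sort(unique(xs))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(cc) mean(xs[y] >= cc), 0)
  spec <- vapply(cand, function(cc) mean(xs[!y] < cc), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]          # tie -> more specific

  # trapezoidal AUC over the full ROC curve (equals the Mann-Whitney
  # statistic with 0.5 credit for ties)
  fpr <- 1 - spec; tpr <- sens
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  structure(list(cutoff = s * cand[best], auc = auc,
                 sensitivity = sens[best], specificity = spec[best],
                 youden_j = j[best], direction = direction, n = length(x)),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf("cutoff %s %.4g (AUC %.3f, sens %.0f%%, spec %.0f%%, n = %d)\n",
              if (x$direction == "high_abnormal") ">=" else "<=",
              x$cutoff, x$auc, 100 * x$sensitivity, 100 * x$specificity, x$n))
  invisible(x)
}

#' Linear-fit CMR analog of a TTE cutoff
#'
#' Ordinary least-squares fit of CMR on TTE; returns the fitted CMR value
#' at the TTE cutoff (the "linear analog" to the guideline threshold).
#'
#' @param cmr_values,tte_values paired measurements (n >= 3).
#' @param tte_cutoff the TTE guideline cutoff.
#' @return The fitted CMR-equivalent cutoff, with the regression slope and
#'   intercept as attributes.
#' @export
linear_analog_cutoff <- function(cmr_values, tte_values, tte_cutoff) {
  ok <- is.finite(cmr_values) & is.finite(tte_values)
  if (sum(ok) < 3L) stopf("need >= 3 paired values, got %d", sum(ok))
  if (stats::sd(tte_values[ok]) == 0)
    stopf("zero variance in TTE values; fit is degenerate")
  fit <- stats::lm(cmr_values[ok] ~ tte_values[ok])
  co <- unname(stats::coef(fit))
  out <- co[1] + co[2] * tte_cutoff
  attr(out, "intercept") <- co[1]
  attr(out, "slope") <- co[2]
  out
}
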