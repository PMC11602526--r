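#' Pearson correlation with a strength label
#'
#' Two-sided Pearson correlation (p-value via the t transform) labelled by
#' the absolute value of r: 0.2-0.39 weak, 0.40-0.59 moderate, 0.6-0.79
#' strong, 0.8-1 very strong; below 0.2 no band applies and the label is
#' \code{NA}.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with \code{r}, \code{p}, \code{label}, \code{n}.
#' @export
pearson_with_label <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  a <- abs(r)
  label <- if (a >= 0.8) "very strong" else if (a >= 0.6) "strong"
    else if (a >= 0.4) "moderate" else if (a >= 0.2) "weak" else NA_character_
  list(r = r, p = ct$p.value, label = label, n = length(x))
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are \code{x - y} (conventionally CMR minus TTE); the bias is
#' their mean and the limits of agreement the bias +/- 1.96 times their SD
#' (n - 1 denominator).
#'
#' @param x_cmr,y_tte paired measurements, n >= 2.
#' @return Object of class \code{bland_altman}: \code{bias}, \code{sd_diff},
#'   \code{loa_low}, \code{loa_high}, \code{n}, plus the means and
#'   differences for plotting.
#' @examples
#' ba <- bland_altman(rnorm(50, 1), rnorm(50))
#' ba
#' plot(ba)
#' @export
bland_altman <- function(x_cmr, y_tte) {
  ok <- is.finite(x_cmr) & is.finite(y_tte)
  x <- x_cmr[ok]; y <- y_tte[ok]
  if (length(x) < 2L) stopf("need >= 2 complete pairs, got %d", length(x))
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g +/- %.3g (LoA [%.3g, %.3g], n = %d)\n",
              x$bias, 1.96 * x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference (CMR - TTE)", ...) {
  graphics::plot(x$means, x$diffs, pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Cohen's kappa for a square contingency table
#'
#' Unweighted kappa \code{(p_o - p_e) / (1 - p_e)} with the expected
#' agreement from the row/column marginals. A degenerate table whose
#' marginals force \code{p_e = 1} returns 1 when observed agreement is also
#' perfect and errors otherwise.
#'
#' @param tab square count matrix (rows = rater 1, columns = rater 2).
#' @return kappa (numeric scalar).
#' @examples
#' cohens_kappa(collapse_presence(reported_grade_table()))
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stopf("'tab' must be square")
  n <- sum(tab)
  if (n < 1) stopf("empty table")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) return(1)
    stopf("degenerate marginals (p_e = 1) with imperfect agreement")
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic accuracy with exact binomial confidence intervals
#'
#' Accuracy, sensitivity and specificity of a 2x2 presence/absence table
#' (rows = reference, i.e. TTE, ordered present then absent; columns = test,
#' i.e. CMR), each with a two-sided 95\% Clopper-Pearson exact interval.
#' An empty margin leaves the affected statistic \code{NA}.
#'
#' @param tab2x2 2x2 count matrix, e.g. from \code{\link{collapse_presence}}.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class \code{agreement_report}: per-statistic list with
#'   \code{estimate}, \code{ci_low}, \code{ci_high}, \code{k} (successes),
#'   \code{n}; plus \code{kappa} and \code{n} for the table.
#' @examples
#' diagnostic_accuracy(collapse_presence(reported_grade_table()))
#' @export
diagnostic_accuracy <- function(tab2x2, conf_level = 0.95) {
  tab2x2 <- as.matrix(tab2x2)
  if (!all(dim(tab2x2) == 2L)) stopf("'tab2x2' must be 2x2")
  n <- sum(tab2x2)
  prop <- function(k, m) {
    if (m == 0) return(list(estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, k = k, n = m))
    bt <- stats::binom.test(k, m, conf.level = conf_level)
    list(estimate = k / m, ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
         k = k, n = m)
  }
  structure(list(
    accuracy = prop(tab2x2[1, 1] + tab2x2[2, 2], n),
    sensitivity = prop(tab2x2[1, 1], sum(tab2x2[1, ])),
    specificity = prop(tab2x2[2, 2], sum(tab2x2[2, ])),
    kappa = cohens_kappa(tab2x2),
    n = n, conf_level = conf_level),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  f <- function(nm) {
    s <- x[[nm]]
    if (is.na(s$estimate))
      return(cat(sprintf("  %-12s NA (empty margin)\n", nm)))
    cat(sprintf("  %-12s %.0f%% (%d/%d), %g%% CI [%.1f%%, %.1f%%]\n", nm,
                100 * s$estimate, s$k, s$n, 100 * x$conf_level,
                100 * s$ci_low, 100 * s$ci_high))
  }
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  f("accuracy"); f("sensitivity"); f("specificity")
  cat(sprintf("  kappa        %.2f\n", x$kappa))
  invisible(x)
}

#' Scan-rescan intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' Shrout-Fleiss mean squares of the subject-by-measurement table.
#'
#' @param rep1,rep2 paired replicate measurements, n >= 3.
#' @return ICC estimate (numeric scalar) with the variance-component mean
#'   squares as attributes.
#' @export
icc_scan_rescan <- function(rep1, rep2) {
  ok <- is.finite(rep1) & is.finite(rep2)
  x <- cbind(rep1[ok], rep2[ok])
  n <- nrow(x); k <- 2
  if (n < 3L) stopf("need >= 3 paired replicates, got %d", n)
  if (stats::var(rowMeans(x)) == 0)
    stopf("zero between-subject variance; ICC undefined")
  grand <- mean(x)
  msr <- k * stats::var(rowMeans(x))                       # rows (subjects)
  msc <- n * stats::var(colMeans(x))                       # columns (scans)
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  attr(icc, "ms") <- c(msr = msr, msc = msc, mse = mse)
  icc
}
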