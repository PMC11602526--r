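grade_levels <- function() c("normal", "indeterminate", "grade1", "grade2", "grade3")

# apply one stored comparator; ratios (E/A, E/e') are compared at 1-decimal
# reporting precision, the precision at which their cutoffs are stated;
# velocities and volumes are compared raw
fire <- function(value, cutoff, ratio = FALSE) {
  if (is.null(value) || is.na(value)) return(NA)
  v <- if (ratio) round(value, 1) else value
  switch(cutoff$op,
         "<" = v < cutoff$value, "<=" = v <= cutoff$value,
         ">" = v > cutoff$value, ">=" = v >= cutoff$value,
         stopf("unknown comparator '%s'", cutoff$op))
}

#' Grade diastolic function from one panel
#'
#' Implements the 2016 ASE/EACVI decision logic with a configurable cutoff
#' set (\code{\link{dd_thresholds}}). With preserved EF and no known
#' myocardial disease the screening branch evaluates four criteria
#' \{e' low (either wall), E/e' high, TR-velocity high, LAVi high\} over
#' those available: more than half positive proceeds to grading, exactly
#' half is indeterminate, fewer is normal. The grading branch (entered
#' directly when \code{assume_myocardial_disease = TRUE}) assigns grade 1
#' when E/A is at or below the low cutoff with E low, grade 3 when E/A is
#' at or above the high cutoff, and otherwise counts \{E/e' high, TR high,
#' LAVi high\} over those available: majority positive is grade 2, majority
#' negative grade 1, a tie (or nothing available) indeterminate. E/A
#' boundaries are inclusive in both sets so the ratio axis is fully
#' partitioned; ratios are compared at the 1-decimal precision of their
#' cutoffs.
#'
#' @param panel named list or one-row data.frame with (any of) \code{E},
#'   \code{A}, \code{e_septal}, \code{e_lateral}, \code{e_average},
#'   \code{E_over_e_avg}, \code{lavi}, \code{tr_velocity}; missing entries
#'   are \code{NA}. \code{E_over_A} and \code{E_over_e_avg} are recomputed
#'   from raw components when those are present.
#' @param thresholds a \code{\link{dd_thresholds}} cutoff set.
#' @param assume_myocardial_disease logical; skip the screening branch and
#'   grade directly (the guideline's depressed-EF / known-disease pathway).
#' @return Object of class \code{dd_grade}: \code{grade} (factor over
#'   normal/indeterminate/grade1/grade2/grade3), \code{dd_present}
#'   (indeterminate counts as present), \code{criteria_fired} (data.frame
#'   audit trail of every comparison with operand values) and
#'   \code{qc_flags}.
#' @examples
#' p <- list(E = 80, A = 40, e_average = 9, tr_velocity = 300)
#' dd_grade(p, dd_thresholds("TTE-2016"), assume_myocardial_disease = TRUE)
#' @export
dd_grade <- function(panel, thresholds = dd_thresholds("TTE-2016"),
                     assume_myocardial_disease = FALSE) {
  stopifnot(inherits(thresholds, "dd_thresholds"))
  g <- function(nm) {
    v <- panel[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }
  E <- g("E"); A <- g("A")
  e_sep <- g("e_septal"); e_lat <- g("e_lateral")
  e_avg <- g("e_average")
  if (is.na(e_avg) && !is.na(e_sep) && !is.na(e_lat)) e_avg <- (e_sep + e_lat) / 2
  ea <- if (!is.na(E) && !is.na(A)) E / A else g("E_over_A")
  ee <- if (!is.na(E) && !is.na(e_avg)) E / e_avg else g("E_over_e_avg")
  lavi <- g("lavi"); tr <- g("tr_velocity")

  if (all(is.na(c(E, A, e_sep, e_lat, e_avg, ea, ee, lavi, tr))))
    stopf("all grading inputs are missing")

  qc <- character(0)
  trail <- list()
  note <- function(criterion, value, cutoff, result) {
    trail[[length(trail) + 1L]] <<- data.frame(
      criterion = criterion, value = value,
      comparison = paste(cutoff$op, cutoff$value), fired = result)
    result
  }

  # the e'-low screening criterion is positive if either wall fires
  e_low <- {
    fs <- note("e_septal_low", e_sep, thresholds$e_septal_low, fire(e_sep, thresholds$e_septal_low))
    fl <- note("e_lateral_low", e_lat, thresholds$e_lateral_low, fire(e_lat, thresholds$e_lateral_low))
    if (is.na(fs) && is.na(fl)) NA else isTRUE(fs) || isTRUE(fl)
  }
  ee_high <- note("E_over_e_high", ee, thresholds$E_over_e_high, fire(ee, thresholds$E_over_e_high, ratio = TRUE))
  tr_high <- note("tr_velocity_high", tr, thresholds$tr_velocity_high, fire(tr, thresholds$tr_velocity_high))
  lavi_high <- note("lavi_high", lavi, thresholds$lavi_high, fire(lavi, thresholds$lavi_high))
  if (is.na(tr)) qc <- c(qc, "TR velocity missing; criterion skipped")
  if (is.na(lavi)) qc <- c(qc, "LAVi missing; criterion skipped")

  grade <- NULL
  if (!assume_myocardial_disease) {
    screen <- c(e_low, ee_high, tr_high, lavi_high)
    avail <- sum(!is.na(screen))
    if (avail == 0L) stopf("no screening criteria evaluable")
    if (avail < 4L) qc <- c(qc, sprintf("screening on %d of 4 criteria", avail))
    pos <- sum(screen, na.rm = TRUE)
    if (pos < avail / 2) grade <- "normal"
    else if (pos == avail / 2) grade <- "indeterminate"
    # > half positive: dysfunction present; fall through to grading
  }

  if (is.null(grade)) {
    if (is.na(ea)) stopf("grading branch requires E and A (or E/A)")
    ea_r <- round(ea, 1)
    low_fired <- note("E_over_A_low_grade1", ea,
                      list(value = thresholds$E_over_A_low$value, op = "<="),
                      ea_r <= thresholds$E_over_A_low$value)
    high_fired <- note("E_over_A_high_grade3", ea,
                       list(value = thresholds$E_over_A_high$value, op = ">="),
                       ea_r >= thresholds$E_over_A_high$value)
    E_low_fired <- note("E_low", E, thresholds$E_low, fire(E, thresholds$E_low))
    if (isTRUE(low_fired) && isTRUE(E_low_fired)) {
      grade <- "grade1"
    } else if (isTRUE(high_fired)) {
      grade <- "grade3"
    } else {
      mid <- c(ee_high, tr_high, lavi_high)
      avail <- sum(!is.na(mid))
      pos <- sum(mid, na.rm = TRUE)
      if (avail == 0L) {
        grade <- "indeterminate"
        qc <- c(qc, "no pressure criteria available in grading branch")
      } else if (pos > avail / 2) grade <- "grade2"
      else if (pos < avail / 2) grade <- "grade1"
      else grade <- "indeterminate"
    }
  }

  structure(list(
    grade = factor(grade, levels = grade_levels()),
    dd_present = grade != "normal",
    criteria_fired = do.call(rbind, trail),
    qc_flags = qc,
    thresholds_label = thresholds$label),
    class = "dd_grade")
}

#' Presence of diastolic dysfunction
#'
#' Collapses a grade to the presence/absence super-category; indeterminate
#' counts as present.
#'
#' @param gr a \code{dd_grade}, or a factor/character vector of grade labels.
#' @return logical.
#' @export
presence <- function(gr) {
  if (inherits(gr, "dd_grade")) return(gr$dd_present)
  as.character(gr) != "normal"
}

#' Grade a table of panels
#'
#' @param panels data.frame, one row per subject, columns as in
#'   \code{\link{dd_grade}}.
#' @inheritParams dd_grade
#' @return data.frame with \code{grade}, \code{dd_present} and
#'   \code{n_qc_flags} per row.
#' @export
grade_panels <- function(panels, thresholds = dd_thresholds("TTE-2016"),
                         assume_myocardial_disease = FALSE) {
  res <- lapply(seq_len(nrow(panels)), function(i)
    dd_grade(as.list(panels[i, , drop = FALSE]), thresholds,
             assume_myocardial_disease))
  data.frame(grade = factor(vapply(res, function(r) as.character(r$grade), ""),
                            levels = grade_levels()),
             dd_present = vapply(res, function(r) r$dd_present, logical(1)),
             n_qc_flags = vapply(res, function(r) length(r$qc_flags), 0L))
}

#' @export
print.dd_grade <- function(x, ...) {
  cat(sprintf("<dd_grade> %s (DD %s) under %s\n", as.character(x$grade),
              if (x$dd_present) "present" else "absent", x$thresholds_label))
  print(x$criteria_fired, row.names = FALSE)
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}
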