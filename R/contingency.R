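#' Cross-tabulate paired TTE and CMR grades
#'
#' @param grades_tte,grades_cmr equal-length vectors of grade labels
#'   (factor or character over normal/indeterminate/grade1/grade2/grade3).
#' @return Object of class \code{grade_contingency}: a 5x5 integer matrix,
#'   rows = TTE grade, columns = CMR grade, in the fixed order normal,
#'   indeterminate, grade1, grade2, grade3; \code{attr(, "n_total")} holds
#'   the total count.
#' @export
cross_tabulate <- function(grades_tte, grades_cmr) {
  if (length(grades_tte) != length(grades_cmr))
    stopf("grade vectors differ in length (%d vs %d)",
          length(grades_tte), length(grades_cmr))
  lv <- grade_levels()
  f <- function(g) factor(as.character(g), levels = lv)
  bad <- !is.na(grades_tte) & is.na(f(grades_tte))
  if (any(bad)) stopf("unknown grade label '%s'", as.character(grades_tte)[bad][1])
  tab <- table(TTE = f(grades_tte), CMR = f(grades_cmr))
  m <- matrix(as.integer(tab), 5, 5, dimnames = dimnames(tab))
  structure(m, n_total = sum(m), class = c("grade_contingency", "matrix"))
}

#' Expand a contingency table back into paired grade vectors
#'
#' @param tab a \code{grade_contingency} (or any labelled square count
#'   matrix).
#' @return data.frame with one row per subject: \code{tte}, \code{cmr}.
#' @export
contingency_pairs <- function(tab) {
  rn <- rownames(tab); cn <- colnames(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  tte <- rep(rn[idx[, 1]], tab[idx])
  cmr <- rep(cn[idx[, 2]], tab[idx])
  data.frame(tte = factor(tte, levels = rn), cmr = factor(cmr, levels = cn))
}

#' Collapse a 5x5 grade table to 2x2 presence/absence
#'
#' Indeterminate and all grades count as dysfunction present. Rows keep the
#' TTE reference, ordered present then absent.
#'
#' @param tab a \code{grade_contingency}.
#' @return 2x2 integer matrix, rows = TTE (present, absent), columns = CMR.
#' @export
collapse_presence <- function(tab) {
  pres <- rownames(tab) != "normal"
  m <- rbind(present = colSums(tab[pres, , drop = FALSE]),
             absent = tab["normal", ])
  cbind(present = rowSums(m[, colnames(tab) != "normal", drop = FALSE]),
        absent = m[, "normal"])
}

#' The published TTE-by-CMR grading contingency table
#'
#' The 5x5 cross-tabulation of diastolic-function grades in the 28 subjects
#' with complete paired studies, as printed in the source comparison study
#' (rows = TTE, columns = CMR).
#'
#' @return A \code{grade_contingency}.
#' @examples
#' cohens_kappa(collapse_presence(reported_grade_table()))
#' @export
reported_grade_table <- function() {
  lv <- grade_levels()
  m <- matrix(c(15, 4, 1, 0, 0,
                0, 1, 1, 1, 1,
                0, 0, 1, 0, 0,
                0, 0, 0, 2, 0,
                0, 0, 0, 0, 1),
              nrow = 5, byrow = TRUE, dimnames = list(TTE = lv, CMR = lv))
  structure(m, n_total = sum(m), class = c("grade_contingency", "matrix"))
}

#' @export
print.grade_contingency <- function(x, ...) {
  cat(sprintf("<grade_contingency> n = %d (rows TTE, columns CMR)\n",
              attr(x, "n_total")))
  print(unclass(x))
  invisible(x)
}
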