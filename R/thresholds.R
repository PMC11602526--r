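#' Named diastolic grading threshold sets
#'
#' Returns a cutoff set for \code{\link{dd_grade}}. Two sets ship with the
#' package:
#' \describe{
#'   \item{\code{"TTE-2016"}}{the 2016 ASE/EACVI guideline cutoffs:
#'     e' septal < 7, e' lateral < 10 cm/s, E <= 50 cm/s, E/e' > 14,
#'     E/A > 2 (high) and < 0.8 (low), LAVi > 34 mL/m2.}
#'   \item{\code{"CMR-paper"}}{CMR-analog cutoffs calibrated by ROC against
#'     the TTE criteria: e' septal <= 4, e' lateral <= 9 cm/s, E <= 57 cm/s,
#'     E/e' >= 12, E/A >= 1.5 (high) and <= 0.9 (low), LAVi >= 34 mL/m2.}
#' }
#' Both sets use a TR-velocity cutoff of > 280 cm/s (the guideline
#' convention; TR is measured by TTE in either case). Each cutoff stores
#' its own comparator, so strict vs. inclusive boundaries are preserved per
#' set. Custom sets can be loaded from JSON via
#' \code{\link{read_thresholds_json}}.
#'
#' @param label \code{"TTE-2016"} or \code{"CMR-paper"}.
#' @return Object of class \code{dd_thresholds}: a named list of
#'   \code{list(value, op)} cutoffs plus a \code{label}. Criterion names:
#'   \code{e_septal_low, e_lateral_low, E_low, E_over_e_high, E_over_A_high,
#'   E_over_A_low, lavi_high, tr_velocity_high}.
#' @examples
#' dd_thresholds("CMR-paper")
#' @export
dd_thresholds <- function(label = c("TTE-2016", "CMR-paper")) {
  label <- match.arg(label)
  cut <- function(value, op) list(value = value, op = op)
  th <- if (label == "TTE-2016") list(
    e_septal_low    = cut(7,  "<"),
    e_lateral_low   = cut(10, "<"),
    E_low           = cut(50, "<="),
    E_over_e_high   = cut(14, ">"),
    E_over_A_high   = cut(2,  ">"),
    E_over_A_low    = cut(0.8, "<"),
    lavi_high       = cut(34, ">"),
    tr_velocity_high = cut(280, ">")
  ) else list(
    e_septal_low    = cut(4,  "<="),
    e_lateral_low   = cut(9,  "<="),
    E_low           = cut(57, "<="),
    E_over_e_high   = cut(12, ">="),
    E_over_A_high   = cut(1.5, ">="),
    E_over_A_low    = cut(0.9, "<="),
    lavi_high       = cut(34, ">="),
    tr_velocity_high = cut(280, ">")
  )
  structure(c(th, list(label = label)), class = "dd_thresholds")
}

#' Build a custom threshold set
#'
#' @param label set name.
#' @param ... named cutoffs, each a \code{list(value =, op =)} with op one
#'   of \code{"<", "<=", ">", ">="}; unspecified criteria inherit from
#'   \code{base}.
#' @param base threshold set supplying defaults (default \code{"TTE-2016"}).
#' @return A \code{dd_thresholds} object.
#' @export
dd_thresholds_custom <- function(label, ..., base = dd_thresholds("TTE-2016")) {
  mods <- list(...)
  th <- unclass(base)
  for (nm in names(mods)) {
    m <- mods[[nm]]
    if (!is.list(m) || !all(c("value", "op") %in% names(m)))
      stopf("cutoff '%s' must be list(value =, op =)", nm)
    if (!m$op %in% c("<", "<=", ">", ">="))
      stopf("cutoff '%s': unknown comparator '%s'", nm, m$op)
    th[[nm]] <- m[c("value", "op")]
  }
  th$label <- label
  if (th$E_over_A_low$value >= th$E_over_A_high$value)
    stopf("E/A low cutoff must be below the high cutoff")
  structure(th, class = "dd_thresholds")
}

threshold_names <- function() c(
  "e_septal_low", "e_lateral_low", "E_low", "E_over_e_high",
  "E_over_A_high", "E_over_A_low", "lavi_high", "tr_velocity_high")

#' @export
print.dd_thresholds <- function(x, ...) {
  cat(sprintf("<dd_thresholds> %s\n", x$label))
  for (nm in threshold_names())
    cat(sprintf("  %-16s %s %g\n", nm, x[[nm]]$op, x[[nm]]$value))
  invisible(x)
}

#' Write / read threshold sets as JSON
#'
#' @param thresholds a \code{dd_thresholds} object.
#' @param path file path.
#' @return \code{read_thresholds_json} returns a \code{dd_thresholds}.
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "dd_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  th <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(dd_thresholds_custom,
          c(list(label = th$label), th[threshold_names()]))
}
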