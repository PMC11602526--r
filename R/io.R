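#' Read and write velocity waveforms as tidy CSV
#'
#' Columns: \code{time_ms}, \code{velocity_cms}.
#'
#' @param w a \code{velocity_waveform}.
#' @param path file path.
#' @param rr_interval RR interval in ms for reading; defaults to the
#'   spanned range plus one median frame interval.
#' @return \code{read_waveform_csv} returns a \code{velocity_waveform}.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "velocity_waveform"))
  utils::write.csv(data.frame(time_ms = w$times, velocity_cms = w$velocities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, rr_interval = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_ms", "velocity_cms")
  if (!all(need %in% names(d)))
    stopf("waveform CSV must have columns: %s", paste(need, collapse = ", "))
  if (is.null(rr_interval))
    rr_interval <- max(d$time_ms) - min(d$time_ms) +
      stats::median(diff(sort(d$time_ms)))
  structure(list(times = d$time_ms, velocities = d$velocity_cms,
                 rr_interval = rr_interval, truth = NULL),
            class = "velocity_waveform")
}

#' Read and write annulus tracks as CSV
#'
#' Columns: \code{frame}, \code{time_ms}, \code{septal_x}, \code{septal_y},
#' \code{lateral_x}, \code{lateral_y} and optionally \code{apex_x},
#' \code{apex_y} (constant per track); coordinates in mm.
#'
#' @param track an \code{annulus_track}.
#' @param path file path.
#' @return \code{read_annulus_track_csv} returns an \code{annulus_track}.
#' @export
write_annulus_track_csv <- function(track, path) {
  stopifnot(inherits(track, "annulus_track"))
  d <- data.frame(frame = seq_along(track$times) - 1L,
                  time_ms = track$times,
                  septal_x = track$septal_xy[, 1],
                  septal_y = track$septal_xy[, 2],
                  lateral_x = track$lateral_xy[, 1],
                  lateral_y = track$lateral_xy[, 2],
                  apex_x = track$apex_xy[1], apex_y = track$apex_xy[2])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annulus_track_csv
#' @param apex_xy apex reference \code{c(x, y)} in mm, required when the CSV
#'   carries no \code{apex_x}/\code{apex_y} columns.
#' @export
read_annulus_track_csv <- function(path, apex_xy = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_ms", "septal_x", "septal_y", "lateral_x", "lateral_y")
  if (!all(need %in% names(d)))
    stopf("track CSV must have columns: %s", paste(need, collapse = ", "))
  if (is.null(apex_xy)) {
    if (!all(c("apex_x", "apex_y") %in% names(d)))
      stopf("no apex columns in CSV; supply 'apex_xy'")
    apex_xy <- c(d$apex_x[1], d$apex_y[1])
  }
  structure(list(times = d$time_ms,
                 septal_xy = cbind(x = d$septal_x, y = d$septal_y),
                 lateral_xy = cbind(x = d$lateral_x, y = d$lateral_y),
                 apex_xy = apex_xy, truth = NULL),
            class = "annulus_track")
}

#' Read a per-subject diastolic panel table
#'
#' Thin wrapper over \code{read.csv} validating that at least one grading
#' input is present. Expected columns (any subset): \code{E}, \code{A},
#' \code{DT}, \code{e_septal}, \code{e_lateral}, \code{e_average},
#' \code{E_over_A}, \code{E_over_e_avg}, \code{lavi}, \code{tr_velocity},
#' \code{lvef}, \code{lvmi}, \code{modality}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_panels_csv <- function(path) {
  d <- utils::read.csv(path)
  known <- c("E", "A", "DT", "e_septal", "e_lateral", "e_average",
             "E_over_A", "E_over_e_avg", "lavi", "tr_velocity", "lvef",
             "lvmi", "modality")
  if (!any(known %in% names(d)))
    stopf("no recognised panel columns in %s", path)
  d
}

#' Read and write a grade contingency table as labelled CSV
#'
#' 5x5 counts with grade labels as header row and first column
#' (rows = TTE, columns = CMR).
#'
#' @param tab a \code{grade_contingency}.
#' @param path file path.
#' @return \code{read_contingency_csv} returns a \code{grade_contingency}.
#' @export
write_contingency_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(unclass(tab)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_contingency_csv
#' @export
read_contingency_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stopf("contingency CSV must be square")
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("TTE", "CMR")
  structure(m, n_total = sum(m), class = c("grade_contingency", "matrix"))
}
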