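#' @keywords internal
"_PACKAGE"

# internal -------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       len = 1L, finite = TRUE) {
  if (!is.numeric(x) || length(x) != len)
    stopf("'%s' must be numeric of length %d", name, len)
  if (finite && any(!is.finite(x)))
    stopf("'%s' must be finite", name)
  if (positive && any(x <= 0))
    stopf("'%s' must be > 0", name)
  if (nonneg && any(x < 0))
    stopf("'%s' must be >= 0", name)
  invisible(x)
}

# robust per-frame noise scale from successive differences
noise_sigma_est <- function(v) {
  d <- diff(v)
  if (length(d) < 2L) return(0)
  stats::mad(d, center = 0) / sqrt(2)
}
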