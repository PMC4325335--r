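#' Canonical double-gamma hemodynamic response function
#'
#' Parametric impulse response linking a neural event to the BOLD time course,
#' used both to synthesize signals and as the expected-response regressor in
#' the real-time analysis. The shape is the standard difference of two gamma
#' densities (positive response minus a delayed undershoot), normalized so the
#' continuous peak amplitude is 1.
#'
#' @param peak_delay delay of the positive response in seconds; the gamma
#'   shape parameter is `peak_delay / peak_dispersion` (SPM convention), so
#'   the continuous mode sits at `peak_delay - peak_dispersion`.
#' @param undershoot_delay delay of the undershoot in seconds.
#' @param peak_dispersion,undershoot_dispersion dispersions (gamma scale) in
#'   seconds.
#' @param undershoot_ratio relative amplitude of the undershoot (dimensionless).
#' @param duration length of the kernel support in seconds; samples are taken
#'   on `[0, duration)`.
#' @return An object of class `canonical_hrf`.
#' @examples
#' h <- canonical_hrf()
#' k <- make_hrf(h, tr_seconds = 2)
#' @export
canonical_hrf <- function(peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6, duration = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0,
            peak_dispersion > 0, undershoot_dispersion > 0,
            undershoot_ratio >= 0)
  if (duration < peak_delay) {
    stop("'duration' (", duration, " s) is shorter than 'peak_delay' (",
         peak_delay, " s)")
  }
  h <- structure(
    list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         undershoot_ratio = undershoot_ratio, duration = duration),
    class = "canonical_hrf")
  # peak normalization constant of the continuous kernel
  opt <- stats::optimize(function(t) hrf_raw(h, t), c(0, duration),
                         maximum = TRUE)
  if (opt$objective <= 0) stop("degenerate HRF: non-positive peak")
  h$peak_value <- opt$objective
  h
}

# unnormalized double-gamma
hrf_raw <- function(hrf, t) {
  pos <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion,
                       scale = hrf$peak_dispersion)
  und <- stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion,
                       scale = hrf$undershoot_dispersion)
  pos - hrf$undershoot_ratio * und
}

#' Evaluate the continuous peak-normalized HRF
#'
#' @param hrf a [canonical_hrf()] object.
#' @param t time in seconds (vectorized); values outside `[0, duration)`
#'   return 0.
#' @return numeric vector of kernel values, continuous peak = 1.
#' @export
hrf_value <- function(hrf, t) {
  stopifnot(inherits(hrf, "canonical_hrf"))
  v <- ifelse(t >= 0 & t < hrf$duration, hrf_raw(hrf, t), 0)
  v / hrf$peak_value
}

#' Sample the HRF kernel at the scan repetition time
#'
#' Returns the discrete kernel used for convolution with per-scan neural
#' input, sampled at lags `0, tr, 2 tr, ...` strictly below `duration` and
#' renormalized so that the largest sampled element equals 1 exactly.
#'
#' @param hrf a [canonical_hrf()] object.
#' @param tr_seconds scan repetition time in seconds, > 0.
#' @return numeric vector with attribute `"lags"` (seconds); max element is 1.
#' @export
make_hrf <- function(hrf, tr_seconds) {
  stopifnot(inherits(hrf, "canonical_hrf"), tr_seconds > 0)
  lags <- seq(0, hrf$duration - tr_seconds / 2, by = tr_seconds)
  lags <- lags[lags < hrf$duration]
  k <- hrf_raw(hrf, lags)
  m <- max(k)
  if (m <= 0) stop("sampled kernel has non-positive maximum")
  k <- k / m
  attr(k, "lags") <- lags
  k
}

#' @export
print.canonical_hrf <- function(x, ...) {
  cat("Canonical double-gamma HRF\n",
      "  peak delay       : ", x$peak_delay, " s (dispersion ",
      x$peak_dispersion, " s)\n",
      "  undershoot delay : ", x$undershoot_delay, " s (dispersion ",
      x$undershoot_dispersion, " s, ratio ",
      signif(x$undershoot_ratio, 4), ")\n",
      "  support          : [0, ", x$duration, ") s\n", sep = "")
  invisible(x)
}
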