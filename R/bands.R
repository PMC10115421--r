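#' Define a frequency band
#'
#' A band is analysed at a single centre frequency (the band midpoint) with
#' multitaper spectral smoothing of half the band width, so that the
#' estimate integrates the whole band.
#'
#' @param name band label, e.g. "alpha".
#' @param f_lo,f_hi band edges in Hz, 0 < f_lo < f_hi.
#' @return An object of class \code{band_spec} with fields \code{name},
#'   \code{f_lo}, \code{f_hi}, \code{center} (midpoint, Hz) and
#'   \code{smoothing} (half-width, Hz).
#' @export
#' @examples
#' band_spec("alpha", 8, 12)
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_hi > f_lo))
    stop("band edges must satisfy 0 < f_lo < f_hi")
  structure(
    list(name = name, f_lo = f_lo, f_hi = f_hi,
         center = (f_lo + f_hi) / 2, smoothing = (f_hi - f_lo) / 2),
    class = "band_spec"
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz (center %g Hz, smoothing +/- %g Hz)\n",
              x$name, x$f_lo, x$f_hi, x$center, x$smoothing))
  invisible(x)
}

#' The three analysis bands
#'
#' Alpha (8-12 Hz), beta (14-30 Hz) and gamma (60-100 Hz), each analysed at
#' its midpoint with half-width spectral smoothing.
#'
#' @return Named list of \code{\link{band_spec}} objects.
#' @export
make_bands <- function() {
  list(
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 14, 30),
    gamma = band_spec("gamma", 60, 100)
  )
}

#' Control analysis windows per band
#'
#' Shorter post-stimulus windows matching the latencies at which painful
#' stimuli typically modulate each band: alpha 0.5-0.9 s, beta 0.3-0.6 s,
#' gamma 0.15-0.35 s. The primary analysis window is 0-1 s.
#'
#' @param band band name ("alpha", "beta" or "gamma").
#' @return Numeric length-2 window in seconds.
#' @export
control_window <- function(band) {
  switch(band,
    alpha = c(0.5, 0.9),
    beta  = c(0.3, 0.6),
    gamma = c(0.15, 0.35),
    stop("no control window preset for band: ", band)
  )
}
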