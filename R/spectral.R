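#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the classic symmetric tridiagonal formulation: the DPSS of
#' length N and normalized half-bandwidth W are the eigenvectors of the
#' tridiagonal matrix with diagonal ((N-1-2t)/2)^2 cos(2 pi W) and
#' off-diagonal t(N-t)/2. The number of tapers follows the standard
#' concentration rule K = floor(2 W_hz T) - 1.
#'
#' @param window_samples window length N in samples.
#' @param rate sampling rate, Hz.
#' @param smoothing spectral smoothing half-width W in Hz.
#' @return N x K matrix of unit-energy, mutually orthogonal tapers.
#' @export
dpss_tapers <- function(window_samples, rate, smoothing) {
  N <- as.integer(window_samples)
  T <- N / rate
  K <- floor(2 * smoothing * T) - 1
  if (K < 1)
    stop(sprintf(
      "smoothing %.3g Hz too narrow for a %.3g s window; need smoothing >= %.3g Hz",
      smoothing, T, 1 / T))
  W <- smoothing / rate
  t <- 0:(N - 1)
  dg <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  M <- matrix(0, N, N)
  diag(M) <- dg
  M[cbind(1:(N - 1), 2:N)] <- od
  M[cbind(2:N, 1:(N - 1))] <- od
  ev <- eigen(M, symmetric = TRUE)
  tp <- ev$vectors[, seq_len(K), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric tapers
  # positive initial slope
  for (k in seq_len(K)) {
    s <- sum(tp[, k])
    if (abs(s) > 1e-6) { if (s < 0) tp[, k] <- -tp[, k] }
    else if (tp[2, k] - tp[1, k] < 0) tp[, k] <- -tp[, k]
  }
  tp
}

# Tapered Fourier coefficients at a single frequency.
# x: rows x samples matrix (rows = trial/channel units, demeaned here);
# returns rows x K complex matrix.
mt_coef <- function(x, tapers, freq, rate) {
  n <- ncol(x)
  x <- x - rowMeans(x)
  ph <- exp(-2i * pi * freq * (0:(n - 1)) / rate)
  x %*% (tapers * ph)
}

#' Multitaper band power per trial and condition
#'
#' Power of the band's centre frequency with spectral smoothing of half the
#' band width, so the single estimate integrates the entire band. Windows
#' are demeaned before tapering. Per trial, power is the taper-averaged
#' squared magnitude of the tapered Fourier coefficient at the band centre.
#'
#' @param epochs an \code{\link{epoch_array}}.
#' @param band a \code{\link{band_spec}}.
#' @param window analysis window in seconds (default the 1-s post-stimulus
#'   interval; see \code{\link{control_window}} for band-specific presets).
#' @return A long data frame (class \code{power_slice}) with columns trial,
#'   condition, roi, power, and the trial-by-ROI matrix in attribute
#'   \code{per_trial}.
#' @export
band_power <- function(epochs, band, window = c(0, 1)) {
  idx <- window_index(epochs, window)
  n <- dim(epochs$data)
  tp <- dpss_tapers(length(idx), epochs$rate, band$smoothing)
  x <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(3, 1, 2)),
              nrow = length(idx))
  cf <- mt_coef(t(x), tp, band$center, epochs$rate)
  pw <- rowMeans(Mod(cf)^2)
  per_trial <- matrix(pw, n[1], n[2], dimnames = list(NULL, epochs$channels))
  out <- data.frame(
    trial = rep(seq_len(n[1]), times = n[2]),
    condition = rep(epochs$labels, times = n[2]),
    roi = rep(epochs$channels, each = n[1]),
    power = as.vector(per_trial),
    stringsAsFactors = FALSE
  )
  attr(out, "per_trial") <- per_trial
  attr(out, "band") <- band$name
  class(out) <- c("power_slice", "data.frame")
  out
}

#' Per-trial cross-spectral matrices at a band centre
#'
#' Taper-wise outer products of tapered Fourier coefficients at the band's
#' centre frequency; each trial-by-taper unit is kept as one observation
#' (the pooling used by the phase-lag index). The taper-averaged diagonal
#' equals \code{\link{band_power}}'s per-trial estimate.
#'
#' @inheritParams band_power
#' @return Object of class \code{cross_spectra}: complex array
#'   \code{csd[obs, roi, roi]} plus per-observation trial index and labels.
#' @export
cross_spectra <- function(epochs, band, window = c(0, 1)) {
  n <- dim(epochs$data)
  if (n[2] < 2) stop("cross-spectra need at least 2 ROIs")
  idx <- window_index(epochs, window)
  tp <- dpss_tapers(length(idx), epochs$rate, band$smoothing)
  K <- ncol(tp)
  x <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(3, 1, 2)),
              nrow = length(idx))
  cf <- mt_coef(t(x), tp, band$center, epochs$rate)      # (trials*rois) x K
  cfa <- array(cf, c(n[1], n[2], K))                      # trial x roi x taper
  nobs <- n[1] * K
  csd <- array(0i, c(nobs, n[2], n[2]))
  for (k in seq_len(K)) {
    ck <- cfa[, , k, drop = FALSE]
    dim(ck) <- c(n[1], n[2])
    for (j in seq_len(n[2]))
      csd[((k - 1) * n[1] + 1):(k * n[1]), , j] <- ck * Conj(ck[, j])
  }
  structure(
    list(band = band, window = window,
         csd = csd,
         trial = rep(seq_len(n[1]), times = K),
         labels = rep(epochs$labels, times = K),
         rois = epochs$channels, n_tapers = K),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> band %s (%g Hz), %d ROIs, %d trials x %d tapers\n",
              x$band$name, x$band$center, length(x$rois),
              length(unique(x$trial)), x$n_tapers))
  invisible(x)
}

#' Baseline-normalized time-frequency representation
#'
#' Sliding-window single-taper (Hanning) power on a frequency grid, using
#' 500-ms windows below 30 Hz and 250-ms windows above, expressed as
#' percent change relative to the mean over a pre-stimulus baseline.
#'
#' @param epochs an \code{\link{epoch_array}}.
#' @param baseline baseline window in seconds, default c(-0.75, -0.25);
#'   must precede stimulus onset (t = 0).
#' @param freqs frequency grid in Hz.
#' @param step time step of the sliding window, seconds.
#' @return Object of class \code{tfr}: array \code{pc[roi, freq, time]} of
#'   percent change, with \code{freqs} and \code{times}.
#' @export
tfr_percent_change <- function(epochs, baseline = c(-0.75, -0.25),
                               freqs = seq(4, 100, by = 4), step = 0.05) {
  if (baseline[2] > 0) stop("baseline window must precede stimulus onset")
  n <- dim(epochs$data)
  rate <- epochs$rate
  widths <- ifelse(freqs < 30, 0.5, 0.25)
  tmin <- epochs$time[1]; tmax <- epochs$time[n[3]]
  centers <- seq(tmin + max(widths) / 2, tmax - max(widths) / 2, by = step)
  pw <- array(NA_real_, c(n[2], length(freqs), length(centers)))
  for (fi in seq_along(freqs)) {
    w <- widths[fi]
    nw <- round(w * rate)
    han <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
    han <- han / sqrt(sum(han^2))
    ph <- han * exp(-2i * pi * freqs[fi] * (0:(nw - 1)) / rate)
    for (ti in seq_along(centers)) {
      i0 <- which.min(abs(epochs$time - (centers[ti] - w / 2)))
      idx <- i0:(i0 + nw - 1)
      if (max(idx) > n[3]) next
      x <- matrix(epochs$data[, , idx], n[1] * n[2], length(idx))
      x <- x - rowMeans(x)
      cf <- x %*% ph
      p <- matrix(Mod(cf)^2, n[1], n[2])
      pw[, fi, ti] <- colMeans(p)
    }
  }
  bl <- centers >= baseline[1] & centers <= baseline[2]
  if (!any(bl)) stop("no TFR time points fall inside the baseline window")
  pc <- pw
  for (r in seq_len(n[2])) for (fi in seq_along(freqs)) {
    b <- mean(pw[r, fi, bl], na.rm = TRUE)
    pc[r, fi, ] <- (pw[r, fi, ] - b) / b * 100
  }
  structure(list(pc = pc, freqs = freqs, times = centers,
                 rois = epochs$channels, baseline = baseline),
            class = "tfr")
}

#' Band power table across subjects, conditions, ROIs and bands
#'
#' @param epoch_list list of per-subject ROI \code{\link{epoch_array}}s.
#' @param bands list of \code{\link{band_spec}}.
#' @param window analysis window, seconds.
#' @return Long data frame (class \code{power_table}) with columns subject,
#'   condition, roi, band, power (trial-averaged within condition).
#' @export
power_table <- function(epoch_list, bands = make_bands(), window = c(0, 1)) {
  out <- list()
  for (s in seq_along(epoch_list)) {
    for (b in names(bands)) {
      sl <- band_power(epoch_list[[s]], bands[[b]], window)
      agg <- stats::aggregate(power ~ condition + roi, data = sl, FUN = mean)
      agg$subject <- s
      agg$band <- b
      out[[length(out) + 1]] <- agg
    }
  }
  res <- do.call(rbind, out)[, c("subject", "condition", "roi", "band", "power")]
  class(res) <- c("power_table", "data.frame")
  res
}
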