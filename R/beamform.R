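#' Leadfield (forward model) container
#'
#' A fixed-orientation gain matrix with one column per source (ROI). A
#' free-orientation leadfield may be supplied as a list of sensors x 3
#' matrices, one per ROI, in which case \code{\link{lcmv_filter}} selects
#' the orientation maximising the filter output.
#'
#' @param gain numeric sensors x sources matrix, full column rank.
#' @param roi_labels source labels, one per column.
#' @param gain3 optional list (one element per ROI) of sensors x 3 matrices
#'   for free-orientation sources.
#' @return Object of class \code{leadfield}.
#' @export
leadfield <- function(gain, roi_labels, gain3 = NULL) {
  gain <- as.matrix(gain)
  if (any(!is.finite(gain))) stop("leadfield contains non-finite entries")
  if (qr(gain)$rank < ncol(gain)) stop("leadfield is not of full column rank")
  stopifnot(length(roi_labels) == ncol(gain))
  structure(list(gain = gain, roi_labels = roi_labels, gain3 = gain3),
            class = "leadfield")
}

#' Random toy leadfield
#'
#' Gaussian gain columns normalized to unit norm; a stand-in for a
#' geometric head model, adequate for testing source reconstruction on
#' abstract sources.
#'
#' @param n_sensors number of sensors.
#' @param roi_labels source labels.
#' @param seed RNG seed.
#' @export
random_leadfield <- function(n_sensors, roi_labels = default_rois(), seed = 1) {
  with_seed(seed, {
    G <- matrix(rnorm(n_sensors * length(roi_labels)), n_sensors)
    G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
    leadfield(G, roi_labels)
  })
}

#' Read a leadfield from a delimited text file
#'
#' Expects a one-line header of ROI labels followed by the numeric
#' sensors x sources gain matrix (whitespace- or comma-delimited).
#'
#' @param path file path.
#' @param sep field separator (default whitespace).
#' @export
read_leadfield <- function(path, sep = "") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  leadfield(as.matrix(d), colnames(d))
}

# Zero-phase band-pass of an epoch array (order-4 Butterworth design run
# forward and backward).
bandpass_epochs <- function(epochs, band) {
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (epochs$rate / 2), type = "pass")
  n <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(n[1])) for (j in seq_len(n[2]))
    out[i, j, ] <- signal::filtfilt(bf, epochs$data[i, j, ])
  epochs$data <- out
  epochs
}

#' Band-limited sensor covariance
#'
#' Covariance of the band-pass-filtered, concatenated peri-stimulus data
#' segments of all trials — the data covariance from which the
#' frequency-specific LCMV filter is built.
#'
#' @param epochs sensor-space \code{\link{epoch_array}} covering the
#'   peri-stimulus window.
#' @param band a \code{\link{band_spec}}.
#' @return Symmetric positive semidefinite sensors x sensors matrix.
#' @export
band_covariance <- function(epochs, band) {
  stopifnot(inherits(epochs, "epoch_array"))
  fe <- bandpass_epochs(epochs, band)
  n <- dim(fe$data)
  if (n[1] * n[3] < n[2])
    warning("fewer samples than sensors; regularization is essential")
  X <- matrix(aperm(fe$data, c(3, 1, 2)), n[1] * n[3], n[2])
  C <- stats::cov(X)
  (C + t(C)) / 2
}

#' Frequency-specific LCMV spatial filter
#'
#' Linearly constrained minimum-variance beamformer with Tikhonov
#' regularization: the covariance is ridged by \code{reg} times the average
#' sensor power before inversion, and each ROI's weights
#' \eqn{w = C_r^{-1} L / (L^T C_r^{-1} L)} pass its leadfield column with
#' unit gain while minimizing output variance. With a free-orientation
#' (3-column) leadfield, the fixed orientation is the generalized
#' eigenvector maximising the filter output.
#'
#' @param lf a \code{\link{leadfield}}.
#' @param covariance sensor covariance matrix (see
#'   \code{\link{band_covariance}}).
#' @param reg regularization fraction of average sensor power (default
#'   0.05).
#' @param band optional \code{\link{band_spec}} recorded on the filter.
#' @return Object of class \code{spatial_filter} with ROI x sensors
#'   \code{weights}.
#' @export
lcmv_filter <- function(lf, covariance, reg = 0.05, band = NULL) {
  C <- as.matrix(covariance)
  ns <- nrow(C)
  if (ns != nrow(lf$gain)) stop("covariance dimensions do not match sensor count")
  Cr <- C + reg * (sum(diag(C)) / ns) * diag(ns)
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop("regularized covariance is singular; increase `reg` above 0 ",
         "(the unregularized covariance is rank-deficient)"))
  G <- lf$gain
  if (!is.null(lf$gain3)) {
    # orientation maximising output power: dominant eigenvector of
    # (L^T Ci L)^{-1}, i.e. the minimal eigenvector of L^T Ci L
    for (j in seq_along(lf$gain3)) {
      L3 <- lf$gain3[[j]]
      M <- crossprod(L3, Ci %*% L3)
      u <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 3]
      G[, j] <- as.numeric(L3 %*% u)
    }
  }
  W <- matrix(0, ncol(G), ns)
  for (j in seq_len(ncol(G))) {
    L <- G[, j]
    CiL <- Ci %*% L
    W[j, ] <- CiL / as.numeric(crossprod(L, CiL))
  }
  structure(list(weights = W, band = band, reg = reg,
                 roi_labels = lf$roi_labels, gain = G),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d ROIs x %d sensors, reg = %g%s\n",
              nrow(x$weights), ncol(x$weights), x$reg,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Apply an LCMV filter to sensor epochs
#'
#' Band-passes the sensor data to the filter's band (guaranteeing
#' consistency between the covariance's and the data's frequency content)
#' and projects each trial through the spatial filter.
#'
#' @param epochs sensor-space \code{\link{epoch_array}}.
#' @param filter a \code{\link{spatial_filter}}.
#' @param band optional band to analyse; must match the filter's band.
#' @return ROI-space \code{epoch_array}; trial labels preserved.
#' @export
apply_filter <- function(epochs, filter, band = NULL) {
  stopifnot(inherits(epochs, "epoch_array"), epochs$space == "sensor")
  if (ncol(filter$weights) != dim(epochs$data)[2])
    stop("sensor counts of filter and data differ")
  if (!is.null(band) && !is.null(filter$band) &&
      !identical(band$name, filter$band$name))
    stop("band mismatch: filter built for ", filter$band$name,
         ", analysis requested ", band$name)
  fe <- if (!is.null(filter$band)) bandpass_epochs(epochs, filter$band) else epochs
  n <- dim(fe$data)
  out <- array(0, c(n[1], nrow(filter$weights), n[3]))
  for (i in seq_len(n[1]))
    out[i, , ] <- filter$weights %*% fe$data[i, , ]
  epoch_array(out, rate = epochs$rate, time = epochs$time,
              labels = epochs$labels, space = "roi",
              channels = filter$roi_labels)
}
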