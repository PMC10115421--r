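#' Debiased weighted phase lag index
#'
#' Squared phase-synchronization estimator built from the imaginary parts
#' of cross-spectra across observations (trial-by-taper units by default).
#' The debiased square estimator is
#' \deqn{dwPLI = \frac{(\sum_i Im S_i)^2 - \sum_i (Im S_i)^2}
#'                   {(\sum_i |Im S_i|)^2 - \sum_i (Im S_i)^2}}
#' It is insensitive to instantaneous (zero-lag) mixing, and under
#' independence its expectation is 0; small negative values are retained
#' (clipping would re-bias the estimator). \code{debias = FALSE} gives the
#' plain squared weighted phase lag index, which is positively biased at
#' finite samples.
#'
#' @param cs a \code{\link{cross_spectra}} object.
#' @param debias logical; use the debiased square estimator (default TRUE).
#' @param pool "taper" (every trial-by-taper cross-spectrum is one
#'   observation, the default) or "trial" (taper-averaged cross-spectra,
#'   one observation per trial).
#' @return Data frame with columns roi_a, roi_b, dwpli for the 15 unordered
#'   pairs (class \code{dwpli_table}).
#' @export
dwpli <- function(cs, debias = TRUE, pool = c("taper", "trial")) {
  pool <- match.arg(pool)
  stopifnot(inherits(cs, "cross_spectra"))
  R <- length(cs$rois)
  pairs <- utils::combn(R, 2)
  out <- data.frame(roi_a = cs$rois[pairs[1, ]], roi_b = cs$rois[pairs[2, ]],
                    dwpli = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    im <- Im(cs$csd[, i, j])
    if (pool == "trial")
      im <- as.numeric(tapply(im, cs$trial, mean))
    if (length(im) < 2) stop("dwPLI needs at least 2 observations")
    s1 <- sum(im); s2 <- sum(im^2); sa <- sum(abs(im))
    out$dwpli[p] <- if (debias) (s1^2 - s2) / (sa^2 - s2)
                    else (s1 / sa)^2
  }
  class(out) <- c("dwpli_table", "data.frame")
  out
}

#' Connectivity table across subjects, conditions, pairs and bands
#'
#' dwPLI per subject, condition cell, unordered ROI pair and band, each
#' computed from that condition's trials only.
#'
#' @param epoch_list list of per-subject ROI \code{\link{epoch_array}}s.
#' @param bands list of \code{\link{band_spec}}.
#' @param window analysis window, seconds.
#' @param pool observation pooling, see \code{\link{dwpli}}.
#' @return Long data frame (class \code{connectivity_table}) with columns
#'   subject, condition, roi_a, roi_b, band, dwpli.
#' @export
connectivity_table <- function(epoch_list, bands = make_bands(),
                               window = c(0, 1), pool = "taper") {
  out <- list()
  for (s in seq_along(epoch_list)) {
    ep <- epoch_list[[s]]
    for (b in names(bands)) {
      for (cc in unique(ep$labels)) {
        sub <- subset_epochs(ep, trials = which(ep$labels == cc))
        csd <- cross_spectra(sub, bands[[b]], window)
        dw <- dwpli(csd, pool = pool)
        dw$subject <- s; dw$condition <- cc; dw$band <- b
        out[[length(out) + 1]] <- dw
      }
    }
  }
  res <- do.call(rbind, out)[, c("subject", "condition", "roi_a", "roi_b",
                                 "band", "dwpli")]
  class(res) <- c("connectivity_table", "data.frame")
  res
}

#' Fit a bivariate autoregressive model by multi-trial least squares
#'
#' Pools the lagged regression across trials: every trial contributes its
#' samples p+1..n as responses with its own lagged predictors, and one
#' coefficient set is estimated jointly.
#'
#' @param epochs \code{\link{epoch_array}} restricted to 2 channels, or a
#'   trials x 2 x samples array.
#' @param order model order p (>= 1); samples per trial must exceed
#'   10 * order.
#' @return List with \code{A} (2 x 2 x p coefficient array), \code{sigma}
#'   (residual covariance), \code{stable} flag, class \code{mvar_fit}.
#' @export
fit_mvar <- function(epochs, order = 5) {
  x <- if (inherits(epochs, "epoch_array")) epochs$data else epochs
  stopifnot(length(dim(x)) == 3, dim(x)[2] == 2, order >= 1)
  nt <- dim(x)[1]; ns <- dim(x)[3]
  if (ns <= 10 * order)
    stop("need more than 10*order samples per trial")
  p <- order
  # design: rows = (trial, t) for t in (p+1):ns; cols = 2*p lagged values
  Y <- NULL; X <- NULL
  rows <- (ns - p) * nt
  X <- matrix(0, rows, 2 * p)
  Y <- matrix(0, rows, 2)
  for (i in seq_len(nt)) {
    xi <- t(x[i, , ])                       # samples x 2
    ridx <- ((i - 1) * (ns - p) + 1):(i * (ns - p))
    Y[ridx, ] <- xi[(p + 1):ns, ]
    for (m in seq_len(p))
      X[ridx, (2 * m - 1):(2 * m)] <- xi[(p + 1 - m):(ns - m), ]
  }
  qx <- qr(X)
  Rm <- qr.R(qx)
  cn <- tryCatch(kappa(Rm, exact = FALSE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e10)
    stop("ill-conditioned MVAR regression (condition number ", format(cn), ")")
  B <- qr.coef(qx, Y)                        # (2p) x 2
  A <- array(0, c(2, 2, p))
  for (m in seq_len(p))
    A[, , m] <- t(B[(2 * m - 1):(2 * m), ])
  res <- Y - X %*% B
  sigma <- crossprod(res) / (nrow(Y) - 2 * p)
  stable <- max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values)) < 1
  structure(list(A = A, sigma = sigma, order = p, stable = stable),
            class = "mvar_fit")
}

#' Select MVAR model order by BIC
#'
#' @param epochs as in \code{\link{fit_mvar}}.
#' @param max_order largest order tried.
#' @return Integer order minimizing BIC.
#' @export
select_mvar_order <- function(epochs, max_order = 20) {
  x <- if (inherits(epochs, "epoch_array")) epochs$data else epochs
  nt <- dim(x)[1]; ns <- dim(x)[3]
  bic <- rep(NA_real_, max_order)
  for (p in seq_len(max_order)) {
    if (ns <= 10 * p) break
    f <- fit_mvar(x, p)
    neff <- (ns - p) * nt
    bic[p] <- neff * determinant(f$sigma, logarithm = TRUE)$modulus +
      log(neff) * 4 * p
  }
  which.min(bic)
}

#' Bivariate partial directed coherence, band-averaged
#'
#' From the Fourier transform of the MVAR coefficients,
#' \eqn{\bar A(f) = I - \sum_m A_m e^{-i 2 \pi f m / rate}}, the PDC from
#' channel j to channel i is \eqn{|\bar A_{ij}(f)|} normalized by the root
#' sum of squares of column j. The band value is the mean over a 1-Hz grid
#' spanning the band.
#'
#' @param fit an \code{\link{fit_mvar}} result (must be stable).
#' @param band a \code{\link{band_spec}}.
#' @param rate sampling rate, Hz.
#' @param full if TRUE, also return the per-frequency 2 x 2 PDC matrices
#'   (element [i, j] = influence j -> i), whose columns have unit sum of
#'   squares by construction.
#' @return List with \code{pdc_ab} (1 -> 2), \code{pdc_ba} (2 -> 1), and
#'   with \code{full = TRUE} also \code{freqs} and \code{matrix}
#'   (2 x 2 x frequency).
#' @export
pdc <- function(fit, band, rate, full = FALSE) {
  if (!fit$stable) stop("unstable MVAR model; PDC undefined")
  freqs <- seq(band$f_lo, band$f_hi, by = 1)
  p <- fit$order
  v_ab <- v_ba <- numeric(length(freqs))
  pm <- if (full) array(NA_real_, c(2, 2, length(freqs))) else NULL
  for (k in seq_along(freqs)) {
    Abar <- diag(2) + 0i
    for (m in seq_len(p))
      Abar <- Abar - fit$A[, , m] * exp(-2i * pi * freqs[k] * m / rate)
    cn <- sqrt(colSums(Mod(Abar)^2))
    v_ab[k] <- Mod(Abar[2, 1]) / cn[1]   # 1 -> 2
    v_ba[k] <- Mod(Abar[1, 2]) / cn[2]   # 2 -> 1
    if (full) pm[, , k] <- sweep(Mod(Abar), 2, cn, "/")
  }
  out <- list(pdc_ab = mean(v_ab), pdc_ba = mean(v_ba))
  if (full) { out$freqs <- freqs; out$matrix <- pm }
  out
}

#' Information-flow asymmetry score
#'
#' \eqn{(PDC_{A\to B} - PDC_{B\to A}) / (PDC_{A\to B} + PDC_{B\to A})},
#' in [-1, 1]; positive means A predominantly drives B. Undefined (NA with
#' attribute \code{undefined}) when both strengths are zero.
#'
#' @param pdc_ab,pdc_ba directed strengths, >= 0.
#' @return Scalar in [-1, 1], or flagged NA.
#' @export
asymmetry_score <- function(pdc_ab, pdc_ba) {
  stopifnot(pdc_ab >= 0, pdc_ba >= 0)
  if (pdc_ab + pdc_ba == 0)
    return(structure(NA_real_, undefined = TRUE))
  (pdc_ab - pdc_ba) / (pdc_ab + pdc_ba)
}

#' Per-subject directed-connectivity analysis of one ROI pair
#'
#' Fits a bivariate MVAR per subject on the selected trials, computes
#' band-averaged PDC in both directions and the asymmetry score. The
#' \code{mismatch_only} filter restricts to cue/stimulus-mismatch trials
#' (hiLE, liHE), the selection used for pairs flagged by an interaction
#' effect.
#'
#' @param epoch_list list of per-subject ROI \code{\link{epoch_array}}s.
#' @param pair length-2 character vector (A, B) of ROI labels; positive
#'   asymmetry means A drives B.
#' @param band a \code{\link{band_spec}}.
#' @param trial_filter "all_trials" or "mismatch_only".
#' @param order MVAR order (default 5).
#' @param window analysis window, seconds.
#' @return Data frame (class \code{directed_pairs}) with per-subject
#'   pdc_ab, pdc_ba, asymmetry.
#' @export
directed_analysis <- function(epoch_list, pair, band,
                              trial_filter = c("all_trials", "mismatch_only"),
                              order = 5, window = c(0, 1)) {
  trial_filter <- match.arg(trial_filter)
  stopifnot(length(pair) == 2)
  out <- data.frame(subject = seq_along(epoch_list), pdc_ab = NA_real_,
                    pdc_ba = NA_real_, asymmetry = NA_real_)
  for (s in seq_along(epoch_list)) {
    ep <- epoch_list[[s]]
    keep <- if (trial_filter == "mismatch_only")
      which(cell_is_mismatch(ep$labels)) else seq_along(ep$labels)
    if (!length(keep)) stop("no trials left after filtering for subject ", s)
    sub <- subset_epochs(ep, trials = keep, channels = pair)
    idx <- window_index(sub, window)
    sub$data <- sub$data[, , idx, drop = FALSE]
    sub$time <- sub$time[idx]
    f <- fit_mvar(sub$data, order)
    pv <- pdc(f, band, ep$rate)
    out$pdc_ab[s] <- pv$pdc_ab
    out$pdc_ba[s] <- pv$pdc_ba
    out$asymmetry[s] <- asymmetry_score(pv$pdc_ab, pv$pdc_ba)
  }
  attr(out, "pair") <- pair
  attr(out, "band") <- band$name
  attr(out, "trial_filter") <- trial_filter
  class(out) <- c("directed_pairs", "data.frame")
  out
}
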