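#' Construct an epoch array
#'
#' The pipeline's universal signal container: a trials x channels x samples
#' array with a uniform peri-stimulus time axis and a condition label per
#' trial.
#'
#' @param data numeric array, trials x channels x samples.
#' @param rate sampling rate in Hz.
#' @param time numeric vector of sample times in seconds (length = dim 3).
#'   If missing, derived from \code{t0} and \code{rate}.
#' @param labels character vector of per-trial condition cells, one of
#'   \code{condition_cells()}.
#' @param space "roi" for source space or "sensor".
#' @param channels channel (ROI or sensor) names; defaults to dimnames or
#'   "ch1".."chK".
#' @param t0 time of the first sample (seconds), used when \code{time} is
#'   missing.
#' @return An object of class \code{epoch_array}.
#' @export
epoch_array <- function(data, rate, time = NULL, labels, space = c("roi", "sensor"),
                        channels = NULL, t0 = NULL) {
  space <- match.arg(space)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data))) stop("epoch data contains non-finite samples")
  n <- dim(data)
  if (is.null(time)) {
    if (is.null(t0)) stop("supply either `time` or `t0`")
    time <- t0 + (seq_len(n[3]) - 1) / rate
  }
  stopifnot(length(time) == n[3])
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - 1 / rate)) > 1e-9)
    stop("time axis must be strictly increasing and uniform at 1/rate")
  stopifnot(length(labels) == n[1])
  if (!all(labels %in% condition_cells()))
    stop("every trial must be labelled with one of: ",
         paste(condition_cells(), collapse = ", "))
  if (is.null(channels)) {
    channels <- dimnames(data)[[2]]
    if (is.null(channels)) channels <- paste0("ch", seq_len(n[2]))
  }
  stopifnot(length(channels) == n[2])
  structure(
    list(data = data, time = time, rate = rate,
         labels = as.character(labels), space = space, channels = channels),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  n <- dim(x$data)
  cat(sprintf("<epoch_array> %d trials x %d %s channels x %d samples @ %g Hz, t = [%g, %g] s\n",
              n[1], n[2], x$space, n[3], x$rate, x$time[1], x$time[n[3]]))
  print(table(factor(x$labels, levels = condition_cells())))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

# Subset trials (and optionally channels) of an epoch array.
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  ti <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else trials
  ci <- if (is.null(channels)) seq_len(dim(epochs$data)[2]) else channels
  if (is.character(ci)) ci <- match(ci, epochs$channels)
  if (anyNA(ci)) stop("unknown channel name")
  epoch_array(epochs$data[ti, ci, , drop = FALSE], rate = epochs$rate,
              time = epochs$time, labels = epochs$labels[ti],
              space = epochs$space, channels = epochs$channels[ci])
}

# Index of the sample window [w1, w2] (seconds) on the epoch time axis.
window_index <- function(epochs, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- which(epochs$time >= window[1] - 1e-9 & epochs$time <= window[2] + 1e-9)
  if (length(idx) < 2)
    stop(sprintf("window [%g, %g] s lies outside the epoch [%g, %g] s",
                 window[1], window[2], epochs$time[1], max(epochs$time)))
  idx
}

#' Serialize epoch containers
#'
#' Writes a list of per-subject epoch arrays (data, time axis, labels, rate
#' and space per subject) to a single container file using R's native
#' serialization.
#'
#' @param epoch_list list of \code{epoch_array} objects.
#' @param path output file path.
#' @export
write_epochs <- function(epoch_list, path) {
  stopifnot(all(vapply(epoch_list, inherits, TRUE, "epoch_array")))
  saveRDS(epoch_list, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!all(vapply(x, inherits, TRUE, "epoch_array")))
    stop("file does not contain a list of epoch arrays")
  x
}
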